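#' @include AllClasses.R phantom-params.R utils.R
NULL

## En face geometry of the ridge arc: clock-hour 12 points "up" in the
## y-down en face frame (towards slow = 0), hours increase clockwise.

## elevation of the inner surface above baseline (um), matrix slow x fast
.ridgeElevation <- function(p) {
  cx <- (p@nFast - 1) / 2
  cy <- (p@nSlow - 1) / 2
  f <- 0:(p@nFast - 1)
  s <- 0:(p@nSlow - 1)
  FX <- matrix(f, p@nSlow, p@nFast, byrow = TRUE)
  SY <- matrix(s, p@nSlow, p@nFast)
  dx <- FX - cx
  dy <- SY - cy
  radUm <- (sqrt(dx^2 + dy^2) - p@arcRadiusPx) * p@lateralPixelUm
  clock <- (atan2(dx, -dy) %% (2 * pi)) * (12 / (2 * pi))
  d <- abs(clock - p@arcCenterClock) %% 12
  dClock <- pmin(d, 12 - d)
  umPerClock <- 2 * pi * p@arcRadiusPx * p@lateralPixelUm / 12
  beyondUm <- pmax(0, dClock - p@arcExtentClock / 2) * umPerClock
  p@ridgeHeightUm * exp(-(radUm^2 + beyondUm^2) / (2 * p@ridgeSigmaUm^2))
}

## crest polyline sampled at ~1 px arc spacing, (slow, fast), 0-based
.ridgeCrest <- function(p) {
  cx <- (p@nFast - 1) / 2
  cy <- (p@nSlow - 1) / 2
  half <- p@arcExtentClock / 2
  arcLenPx <- p@arcRadiusPx * (p@arcExtentClock / 12) * 2 * pi
  n <- max(2L, ceiling(arcLenPx) + 1L)
  clocks <- seq(p@arcCenterClock - half, p@arcCenterClock + half,
    length.out = n)
  theta <- clocks * pi / 6
  cbind(slow = cy - p@arcRadiusPx * cos(theta),
        fast = cx + p@arcRadiusPx * sin(theta))
}

#' Generate a synthetic OCT volume with ground truth
#'
#' Renders a smooth retina (flat RPE plus an inner surface a baseline
#' thickness above it) carrying a fibrovascular ridge: a Gaussian-profile
#' elevation of the inner surface along a circular arc at the
#' vascular-avascular junction.  Boundaries are rendered with
#' partial-volume mixing so surface positions are meaningful at
#' sub-pixel precision; speckle is multiplicative gamma noise with unit
#' mean.  Intensities are clipped to `[0, 1]` and quantized to the
#' 16-bit grid so that volumes written with [writeVolume()] round-trip
#' bit-exactly.
#'
#' @param params a [PhantomParams-class] object.
#' @param seed integer RNG seed; identical `(params, seed)` give
#'   bit-identical volumes.
#' @return a list with elements `volume` ([OCTVolume-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantomVolume(
#'   phantomParams(nAxial = 200, nFast = 48, nSlow = 48, speckleSnr = Inf),
#'   seed = 1)
#' ph$truth
#' @export
generatePhantomVolume <- function(params, seed = 1L) {
  stopifnot(is(params, "PhantomParams"))
  validObject(params)
  p <- params

  crest <- .ridgeCrest(p)
  if (min(crest) < 0 || max(crest[, "slow"]) > p@nSlow - 1 ||
      max(crest[, "fast"]) > p@nFast - 1)
    stop("ridge arc falls outside the en face field; ",
      "reduce arcRadiusPx or arcExtentClock", call. = FALSE)

  elev <- .ridgeElevation(p)
  rpeRowPx <- p@rpeDepthUm / p@axialPixelUm
  inner <- rpeRowPx - (p@baselineRetinaUm + elev) / p@axialPixelUm
  if (min(inner) < 1)
    stop("ridge reaches the top of the volume; increase nAxial or ",
      "rpeDepthUm", call. = FALSE)
  if (rpeRowPx + p@rpeBandUm / p@axialPixelUm / 2 > p@nAxial - 1)
    stop("RPE band falls outside the axial range", call. = FALSE)

  bandPx <- p@rpeBandUm / p@axialPixelUm
  rpeTop <- rpeRowPx - bandPx / 2
  rpeBot <- rpeRowPx + bandPx / 2

  vol <- array(0, c(p@nSlow, p@nAxial, p@nFast))
  rows <- 0:(p@nAxial - 1)
  Rm <- matrix(rows, p@nAxial, p@nFast)
  for (s in seq_len(p@nSlow)) {
    Im <- matrix(inner[s, ], p@nAxial, p@nFast, byrow = TRUE)
    ft <- pmin(1, pmax(0, pmin(rpeTop, Rm + 0.5) - pmax(Im, Rm - 0.5)))
    fr <- pmin(1, pmax(0, pmin(rpeBot, Rm + 0.5) - pmax(rpeTop, Rm - 0.5)))
    fs <- pmin(1, pmax(0, (Rm + 0.5) - pmax(rpeBot, Rm - 0.5)))
    fv <- pmax(0, 1 - ft - fr - fs)
    vol[s, , ] <- p@backgroundLevel * fv + p@tissueLevel * ft +
      p@rpeLevel * fr + p@subRpeLevel * fs
  }

  if (is.finite(p@speckleSnr)) {
    shape <- p@speckleSnr^2
    vol <- withSeed(seed, {
      vol * rgamma(length(vol), shape = shape, rate = shape)
    })
  }
  vol <- array(round(pmin(1, pmax(0, vol)) * 65535) / 65535, dim(vol))

  volume <- OCTVolume(vol,
    axialPixelUm = p@axialPixelUm, lateralPixelUm = p@lateralPixelUm,
    metadata = list(seed = as.integer(seed), fov = "105")
  )
  thickness <- p@baselineRetinaUm + elev
  truth <- new("PhantomTruth",
    rpeSurface = matrix(rpeRowPx, p@nSlow, p@nFast),
    innerSurface = inner,
    trueMaxThicknessUm = max(thickness),
    trueRidgeline = RidgeTrace(crest, source = "truth"),
    axialPixelUm = p@axialPixelUm
  )
  list(volume = volume, truth = truth)
}

#' Generate noisy grader stage labels
#'
#' Emulates two independent graders assigning a continuous stage label
#' (0.1 increments, clipped to `[0, 3]`) to each exam; each grader's
#' ordinal label is their continuous label rounded to the nearest
#' integer (half up).  The grader error model is an assumption (graders
#' are not described generatively in the underlying study design): label
#' = truth + Gaussian noise, then quantized.
#'
#' @param trueContinuousStage numeric vector of true continuous stages.
#' @param noiseSd grader noise SD on the stage scale (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns `grader_a_continuous`,
#'   `grader_b_continuous`, `grader_a_ordinal`, `grader_b_ordinal`.
#' @examples
#' generateGraderLabels(c(1.8, 2.26), noiseSd = 0, seed = 1)
#' @export
generateGraderLabels <- function(trueContinuousStage, noiseSd, seed = 1L) {
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
    stop("noiseSd must be a single non-negative number", call. = FALSE)
  n <- length(trueContinuousStage)
  withSeed(seed, {
    quant <- function(x) pmin(3, pmax(0, roundHalfUp(x, 1L)))
    a <- quant(trueContinuousStage + rnorm(n, 0, noiseSd))
    b <- quant(trueContinuousStage + rnorm(n, 0, noiseSd))
    data.frame(
      grader_a_continuous = a,
      grader_b_continuous = b,
      grader_a_ordinal = as.integer(roundHalfUp(a)),
      grader_b_ordinal = as.integer(roundHalfUp(b))
    )
  })
}

#' Generate a simulated screening cohort of exam records
#'
#' Draws a nested cohort: patients contribute `eyesPerPatient` eyes, each
#' eye an ordinal stage from `stageMix` and 1..k imaging sessions.  An
#' eye's true maximum ridge thickness is stage-conditional Gaussian plus
#' a patient-level effect (shared by both eyes) and, per session, an
#' eye-level fluctuation; the recorded measurement adds capture noise.
#' Two noisy graders label every session (see
#' [generateGraderLabels()]), labels are adjudicated with
#' [adjudicate()].
#'
#' The returned table is "thickness-only": no volumes are rendered, so
#' statistical analyses run in seconds.  Set `imageMode = TRUE` to also
#' render one phantom volume per record (with ridge height chosen so the
#' true thickness matches the record) for end-to-end imaging tests.
#'
#' @param params a [CohortParams-class] object (carries its own seed).
#' @param imageMode logical; also render per-record phantom volumes.
#' @param phantomTemplate a [PhantomParams-class] used as the rendering
#'   template in image mode.
#' @return In thickness-only mode, a data.frame with one row per exam:
#'   `patient_id`, `eye`, `session_id`, `postmenstrual_week`, grader
#'   label columns, `mean_continuous`, `adjudicated_ordinal`,
#'   `max_thickness_um`, `treated`, `weeks_from_treatment`, plus
#'   simulation-truth columns prefixed `true_`.  In image mode, a list
#'   with elements `records`, `volumes`, `truths`.
#' @examples
#' rec <- generateCohort(cohortParams(nPatients = 4, seed = 11))
#' head(rec)
#' @export
generateCohort <- function(params, imageMode = FALSE,
                           phantomTemplate = phantomParams(
                             nAxial = 256L, nFast = 64L, nSlow = 64L)) {
  stopifnot(is(params, "CohortParams"))
  validObject(params)
  p <- params
  emptyRec <- data.frame(
    patient_id = character(), eye = character(), session_id = integer(),
    postmenstrual_week = numeric(),
    grader_a_continuous = numeric(), grader_b_continuous = numeric(),
    grader_a_ordinal = integer(), grader_b_ordinal = integer(),
    mean_continuous = numeric(), adjudicated_ordinal = integer(),
    max_thickness_um = numeric(), treated = logical(),
    weeks_from_treatment = numeric(),
    true_stage = integer(), true_continuous_stage = numeric(),
    true_session_um = numeric()
  )
  if (p@nPatients == 0L) {
    return(if (imageMode) list(records = emptyRec, volumes = list(),
      truths = list()) else emptyRec)
  }

  nStage <- length(p@stageMix)
  seeds <- childSeeds(p@seed, 2L)
  rec <- withSeed(seeds[1L], {
    out <- vector("list", p@nPatients)
    eyeNames <- c("OD", "OS", sprintf("E%d", seq_len(max(0, p@eyesPerPatient - 2L)) + 2L))
    for (i in seq_len(p@nPatients)) {
      bPatient <- rnorm(1, 0, p@withinPatientSdUm)
      pmaBase <- runif(1, 32, 40)
      eyes <- vector("list", p@eyesPerPatient)
      for (j in seq_len(p@eyesPerPatient)) {
        stage <- sample.int(nStage, 1L, prob = p@stageMix)
        eyeTrueUm <- rnorm(1, p@stageThicknessMeansUm[stage],
          p@stageThicknessSdUm[stage]) + bPatient
        nSess <- sample.int(length(p@sessionsPerEyeProb), 1L,
          prob = p@sessionsPerEyeProb)
        sess <- seq_len(nSess)
        trueSess <- pmax(1, eyeTrueUm + rnorm(nSess, 0, p@withinEyeSdUm))
        trueCont <- pmin(3, pmax(0, stage + runif(nSess, -0.3, 0.3)))
        eyes[[j]] <- data.frame(
          patient_id = sprintf("P%03d", i),
          eye = eyeNames[j],
          session_id = sess,
          postmenstrual_week = pmaBase + (sess - 1L) * 1.5,
          true_stage = stage,
          true_continuous_stage = trueCont,
          true_session_um = trueSess
        )
      }
      out[[i]] <- do.call(rbind, eyes)
    }
    do.call(rbind, out)
  })

  aux <- withSeed(seeds[2L], {
    labels <- generateGraderLabels(rec$true_continuous_stage,
      p@graderNoiseSd, seed = sample.int(.Machine$integer.max - 1L, 1L))
    meas <- rec$true_session_um + rnorm(nrow(rec), 0, p@measurementSdUm)
    list(labels = labels, meas = pmax(0, meas))
  })
  adj <- adjudicate(aux$labels)
  rec <- cbind(
    rec[, c("patient_id", "eye", "session_id", "postmenstrual_week")],
    aux$labels,
    mean_continuous = adj$mean_continuous,
    adjudicated_ordinal = adj$adjudicated_ordinal,
    max_thickness_um = aux$meas,
    treated = FALSE,
    weeks_from_treatment = NA_real_,
    rec[, c("true_stage", "true_continuous_stage", "true_session_um")]
  )
  rownames(rec) <- NULL

  if (!imageMode) return(rec)

  tmpl <- phantomTemplate
  volumes <- vector("list", nrow(rec))
  truths <- vector("list", nrow(rec))
  volSeeds <- childSeeds(p@seed + 1L, nrow(rec))
  for (r in seq_len(nrow(rec))) {
    height <- max(0, rec$true_session_um[r] - tmpl@baselineRetinaUm)
    pp <- tmpl
    pp@ridgeHeightUm <- height
    ph <- generatePhantomVolume(pp, seed = volSeeds[r])
    ph$volume@metadata <- c(ph$volume@metadata, list(
      patient_id = rec$patient_id[r], eye = rec$eye[r],
      session_id = rec$session_id[r]
    ))
    volumes[[r]] <- ph$volume
    truths[[r]] <- ph$truth
  }
  list(records = rec, volumes = volumes, truths = truths)
}

#' Generate a peri-treatment thickness trajectory
#'
#' Expected maximum ridge thickness rises linearly towards the treatment
#' visit (week 0) at `preSlopeUmPerWk` and falls after it at
#' `postDecayUmPerWk`, with independent Gaussian per-visit noise;
#' `baselineUm` is the expected thickness at the time of treatment.
#'
#' @param params a [TreatmentParams-class] object.
#' @param baselineUm expected thickness at week 0 (micrometres).
#' @param seed integer RNG seed.
#' @return data.frame with columns `week` and `thickness_um`.
#' @examples
#' generateTreatmentTrajectory(treatmentParams(noiseSdUm = 0), 394, seed = 1)
#' @export
generateTreatmentTrajectory <- function(params, baselineUm, seed = 1L) {
  stopifnot(is(params, "TreatmentParams"))
  validObject(params)
  stopifnotScalarPositive(baselineUm, "baselineUm")
  w <- params@observationWeeks
  mu <- ifelse(w <= 0,
    baselineUm + params@preSlopeUmPerWk * w,
    baselineUm - params@postDecayUmPerWk * w)
  y <- withSeed(seed, mu + rnorm(length(w), 0, params@noiseSdUm))
  data.frame(week = w, thickness_um = pmax(0, y))
}
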