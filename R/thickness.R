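#' @include AllClasses.R trace.R
NULL

#' SegmentationConfig: thresholds for automated surface segmentation
#'
#' Controls [segmentSurfaces()].  Thresholds are expressed as fractions
#' of the per-column dynamic range so they are invariant to intensity
#' scaling.
#'
#' @param tissueThresholdFrac fraction of the per-column dynamic range,
#'   in `(0, 1)`, above which smoothed intensity counts as tissue when
#'   searching for the inner surface from the vitreous side.
#' @param minRunPx minimum consecutive above-threshold rows required to
#'   accept a tissue entry (rejects isolated speckle spikes).
#' @param smoothPx centered running-mean window (axial rows) applied per
#'   column before thresholding; must be odd.
#' @param rpeMinOffsetPx minimum rows below the detected inner surface
#'   at which the RPE band search starts (keeps the bright inner-surface
#'   gradient from masquerading as the RPE).
#' @return a list of class `SegmentationConfig`.
#' @examples
#' segmentationConfig(tissueThresholdFrac = 0.4)
#' @export
segmentationConfig <- function(tissueThresholdFrac = 0.35, minRunPx = 4L,
                               smoothPx = 3L, rpeMinOffsetPx = 6L) {
  if (tissueThresholdFrac <= 0 || tissueThresholdFrac >= 1)
    stop("tissueThresholdFrac must be in (0, 1)", call. = FALSE)
  if (minRunPx < 1L) stop("minRunPx must be >= 1", call. = FALSE)
  if (smoothPx < 1L || smoothPx %% 2L == 0L)
    stop("smoothPx must be odd and >= 1", call. = FALSE)
  structure(
    list(
      tissueThresholdFrac = tissueThresholdFrac,
      minRunPx = as.integer(minRunPx),
      smoothPx = as.integer(smoothPx),
      rpeMinOffsetPx = as.integer(rpeMinOffsetPx)
    ),
    class = "SegmentationConfig"
  )
}

## centered running mean with truncated edges
.runMean <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## first index (1-based) starting a run of >= minRun TRUEs, or NA
.firstRun <- function(above, minRun) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= minRun)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

#' Segment the RPE and inner ridge surface on a strip
#'
#' Per strip column (working on a lightly smoothed A-scan): the inner
#' surface is the first axial position, approached from the vitreous
#' side, where intensity exceeds a fraction of the column's dynamic
#' range for a minimum run length, refined to sub-pixel by linear
#' interpolation of the threshold crossing; the RPE is the center of the
#' brightest band at or below the inner surface, refined by parabolic
#' interpolation around the peak.  Columns where either search fails are
#' flagged invalid, never guessed.  A strip that is entirely background
#' yields an all-invalid result with a warning; a strip with no dynamic
#' range at all (constant/saturated) is an error.
#'
#' Automated segmentation replaces the manual segmentation step for
#' phantom-rendered strips; manually segmented surfaces can be supplied
#' to [thicknessProfile()] directly via [SurfacePair()].
#'
#' @param strip a [RidgeStrip-class].
#' @param config a [segmentationConfig()].
#' @return a [SurfacePair-class] with one entry per strip column.
#' @examples
#' ph <- generatePhantomVolume(
#'   phantomParams(nAxial = 160, nFast = 48, nSlow = 48, speckleSnr = Inf),
#'   seed = 1)
#' strip <- extractRidgeStrip(ph$volume, ph$truth@trueRidgeline)
#' segmentSurfaces(strip)
#' @export
segmentSurfaces <- function(strip, config = segmentationConfig()) {
  stopifnot(is(strip, "RidgeStrip"))
  if (!inherits(config, "SegmentationConfig"))
    stop("config must come from segmentationConfig()", call. = FALSE)
  px <- strip@pixels
  nAx <- nrow(px)
  nCol <- ncol(px)
  if (nCol == 0L || nAx == 0L) stop("empty strip", call. = FALSE)
  if (max(px) - min(px) < 1e-9)
    stop("strip has no dynamic range (constant or saturated)",
      call. = FALSE)

  inner <- rep(NA_real_, nCol)
  rpe <- rep(NA_real_, nCol)
  for (j in seq_len(nCol)) {
    sm <- .runMean(px[, j], config$smoothPx)
    rng <- max(sm) - min(sm)
    if (rng < 1e-9) next # featureless column -> invalid
    thr <- min(sm) + config$tissueThresholdFrac * rng
    k <- .firstRun(sm >= thr, config$minRunPx)
    if (is.na(k)) next
    innerJ <- if (k == 1L) {
      0
    } else {
      ## refine to the 50% point of the vitreous-to-tissue transition
      ## (unbiased under the symmetric smoothing window), searching a
      ## small neighbourhood of the detected run start
      bgLoc <- min(sm[max(1L, k - 2L * config$smoothPx):k])
      platLoc <- stats::median(
        sm[k:min(nAx, k + config$minRunPx + config$smoothPx)])
      lvl <- (bgLoc + platLoc) / 2
      win <- max(2L, k - config$smoothPx):min(nAx, k + config$smoothPx)
      cross <- win[sm[win - 1L] < lvl & sm[win] >= lvl]
      kc <- if (length(cross)) cross[1L] else k
      step <- sm[kc] - sm[kc - 1L]
      frac <- if (step > 1e-12) (lvl - sm[kc - 1L]) / step else 1
      (kc - 2L) + min(1, max(0, frac))
    }
    lo <- min(nAx, k + config$rpeMinOffsetPx)
    seg <- sm[lo:nAx]
    m <- which.max(seg)
    kp <- lo + m - 1L
    if (kp <= 1L || kp >= nAx) next # peak at the boundary: unreliable
    y1 <- sm[kp - 1L]
    y2 <- sm[kp]
    y3 <- sm[kp + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    rpeJ <- (kp - 1L) + delta
    if (rpeJ < innerJ) next
    inner[j] <- innerJ
    rpe[j] <- rpeJ
  }
  valid <- is.finite(inner) & is.finite(rpe)
  if (!any(valid))
    warning("no measurable surfaces found on any column (background strip?)",
      call. = FALSE)
  SurfacePair(rpeRow = rpe, innerRow = inner, valid = valid)
}

#' Pixelwise axial thickness along the strip
#'
#' Maps every valid column to `(rpe_row - inner_row) * axialPixelUm`
#' micrometres; invalid columns are omitted from the profile.
#'
#' @param surfaces a [SurfacePair-class].
#' @param axialPixelUm axial pixel spacing in micrometres (> 0).
#' @param columnPositions optional matrix of en face positions, one row
#'   per surface column (e.g. `samplePositions(strip)`).
#' @return a [ThicknessProfile-class].
#' @examples
#' sp <- SurfacePair(rpeRow = c(150, 150), innerRow = c(100, 90))
#' thicknessUm(thicknessProfile(sp, 4.4))
#' @export
thicknessProfile <- function(surfaces, axialPixelUm,
                             columnPositions = NULL) {
  stopifnot(is(surfaces, "SurfacePair"))
  stopifnotScalarPositive(axialPixelUm, "axialPixelUm")
  ok <- surfaces@valid
  bad <- which(ok & surfaces@innerRow > surfaces@rpeRow + 1e-9)
  if (length(bad))
    stop(sprintf("inner surface below RPE at column %d", bad[1L]),
      call. = FALSE)
  th <- (surfaces@rpeRow[ok] - surfaces@innerRow[ok]) * axialPixelUm
  pos <- if (is.null(columnPositions)) {
    matrix(numeric(0), length(th), 2L,
      dimnames = list(NULL, c("slow", "fast")))
  } else {
    as.matrix(columnPositions)[ok, , drop = FALSE]
  }
  if (nrow(pos) != length(th))
    pos <- matrix(NA_real_, length(th), 2L,
      dimnames = list(NULL, c("slow", "fast")))
  new("ThicknessProfile", thicknessUm = th, columnPositions = pos)
}

#' Top-n maximum ridge thickness
#'
#' The exam-level biomarker: the `topN` largest per-column thickness
#' values along the traced ridge are averaged (default `topN = 10`); the
#' SD reported is the population SD of those selected values.  If fewer
#' than `topN` valid columns exist, all are averaged and `nUsed` records
#' the shortfall.
#'
#' @param profile a [ThicknessProfile-class] (non-empty).
#' @param topN number of largest values to average (>= 1).
#' @return a [MaxThickness-class].
#' @examples
#' sp <- SurfacePair(rpeRow = rep(150, 12), innerRow = 150 - (1:12) * 10)
#' maxRidgeThickness(thicknessProfile(sp, 4.4))
#' @export
maxRidgeThickness <- function(profile, topN = 10L) {
  stopifnot(is(profile, "ThicknessProfile"))
  if (!is.numeric(topN) || length(topN) != 1L || topN < 1)
    stop("topN must be a positive integer", call. = FALSE)
  th <- profile@thicknessUm
  if (!length(th))
    stop("no measurable ridge: the thickness profile is empty",
      call. = FALSE)
  sel <- sort(th, decreasing = TRUE)[seq_len(min(as.integer(topN), length(th)))]
  n <- length(sel)
  mu <- mean(sel)
  sdPop <- sqrt(sum((sel - mu)^2) / n)
  new("MaxThickness", meanUm = mu, sdUm = sdPop, nUsed = n)
}

#' Measure an exam: trace to maximum ridge thickness
#'
#' The composed measurement pipeline for one volume: extract the curved
#' strip along the trace, segment both surfaces, form the pixelwise
#' thickness profile, and summarize with the top-n maxima.  This single
#' number (plus SD and n) is what an exam record carries.
#'
#' @param volume an [OCTVolume-class].
#' @param trace a [RidgeTrace-class] along the ridge crest.
#' @param config a [segmentationConfig()].
#' @param spacingPx strip column spacing along the trace (en face px).
#' @param topN number of largest thickness values to average.
#' @return a [MaxThickness-class].
#' @examples
#' ph <- generatePhantomVolume(
#'   phantomParams(nAxial = 200, nFast = 48, nSlow = 48,
#'                 ridgeHeightUm = 300, speckleSnr = Inf), seed = 1)
#' measureExam(ph$volume, ph$truth@trueRidgeline)
#' @export
measureExam <- function(volume, trace, config = segmentationConfig(),
                        spacingPx = 1, topN = 10L) {
  strip <- tryCatch(
    extractRidgeStrip(volume, trace, spacingPx),
    error = function(e) stop("strip extraction failed: ",
      conditionMessage(e), call. = FALSE)
  )
  surfaces <- tryCatch(
    segmentSurfaces(strip, config),
    error = function(e) stop("surface segmentation failed: ",
      conditionMessage(e), call. = FALSE)
  )
  profile <- tryCatch(
    thicknessProfile(surfaces, volume@axialPixelUm,
      columnPositions = strip@samplePositions),
    error = function(e) stop("thickness profiling failed: ",
      conditionMessage(e), call. = FALSE)
  )
  tryCatch(
    maxRidgeThickness(profile, topN),
    error = function(e) stop("thickness summary failed: ",
      conditionMessage(e), call. = FALSE)
  )
}
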