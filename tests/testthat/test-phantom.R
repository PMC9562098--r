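test_that("phantom generation is deterministic and honours its geometry", {
  p <- smallPhantomParams(speckleSnr = 3)
  a <- generatePhantomVolume(p, seed = 42)
  b <- generatePhantomVolume(p, seed = 42)
  expect_identical(intensities(a$volume), intensities(b$volume))
  expect_identical(a$truth@innerSurface, b$truth@innerSurface)

  c <- generatePhantomVolume(p, seed = 43)
  expect_false(identical(intensities(a$volume), intensities(c$volume)))

  # no ridge -> flat retina at baseline thickness
  flat <- smallPhantom(ridgeHeightUm = 0)
  expect_equal(flat$truth@trueMaxThicknessUm, 200, tolerance = 4.4 / 200)

  # analytic sum: baseline 200 + ridge 300 = 500 um, within one axial pixel
  ph <- smallPhantom(ridgeHeightUm = 300)
  expect_lt(abs(ph$truth@trueMaxThicknessUm - 500), 4.4)

  # truth consistency: brute-force scan of the surface grids reproduces
  # the recorded analytic maximum
  diffs <- (ph$truth@rpeSurface - ph$truth@innerSurface) * 4.4
  bruteMax <- -Inf
  for (i in seq_len(nrow(diffs))) {
    for (j in seq_len(ncol(diffs))) bruteMax <- max(bruteMax, diffs[i, j])
  }
  expect_equal(bruteMax, ph$truth@trueMaxThicknessUm)

  # inner surface never dips below the RPE
  expect_true(all(ph$truth@innerSurface <= ph$truth@rpeSurface))
})

test_that("phantom rendering is consistent with its truth surfaces", {
  ph <- smallPhantom(ridgeHeightUm = 300)
  v <- intensities(ph$volume)
  s <- 24L
  for (f in c(5L, 24L, 40L)) {
    inner <- ph$truth@innerSurface[s, f]
    rpe <- ph$truth@rpeSurface[s, f]
    col <- v[s, , f]
    # vitreous above the inner surface, tissue between, bright RPE band
    expect_lt(max(col[seq_len(floor(inner) - 1L)]), 0.1)
    mid <- col[(ceiling(inner) + 2L):(floor(rpe) - 4L)]
    expect_true(all(abs(mid - 0.45) < 2e-4)) # 16-bit quantization
    expect_gt(col[round(rpe) + 1L], 0.8)
  }
})

test_that("phantom generator rejects invalid geometry", {
  expect_error(phantomParams(nAxial = 0), "dimensions")
  expect_error(phantomParams(ridgeHeightUm = -5), "ridgeHeightUm")
  expect_error(phantomParams(arcExtentClock = 13), "clock hours")
  expect_error(
    generatePhantomVolume(smallPhantomParams(arcRadiusPx = 60)),
    "outside the en face field"
  )
  expect_error(
    generatePhantomVolume(smallPhantomParams(ridgeHeightUm = 1100)),
    "top of the volume"
  )
})

test_that("grader labels quantize, clip and carry the requested noise", {
  # noiseless labels pass the truth through the 0.1 grid
  g <- generateGraderLabels(c(2.0, 2.26), noiseSd = 0, seed = 1)
  expect_equal(g$grader_a_continuous, c(2.0, 2.3))
  expect_equal(g$grader_b_continuous, c(2.0, 2.3))
  expect_equal(g$grader_a_ordinal, c(2L, 2L))

  # ordinal is always the half-up rounding of the continuous label
  gg <- generateGraderLabels(runif(500, 0, 3), noiseSd = 0.4, seed = 2)
  expect_true(all(gg$grader_a_ordinal == floor(gg$grader_a_continuous + 0.5)))
  expect_true(all(gg$grader_a_continuous >= 0 & gg$grader_a_continuous <= 3))
  expect_true(all(abs(gg$grader_b_continuous * 10 -
    round(gg$grader_b_continuous * 10)) < 1e-9))

  # Monte-Carlo: emitted label SD matches the configured noise SD
  n <- 4000L
  gmc <- generateGraderLabels(rep(1.5, n), noiseSd = 0.3, seed = 3)
  expect_equal(sd(gmc$grader_a_continuous), 0.3, tolerance = 0.05)
  expect_error(generateGraderLabels(1, noiseSd = -1), "non-negative")
})

test_that("cohorts respect their nesting design and stage calibration", {
  expect_equal(nrow(generateCohort(cohortParams(nPatients = 0))), 0L)

  rec <- generateCohort(cohortParams(nPatients = 25, seed = 5))
  expect_equal(length(unique(rec$patient_id)), 25L)
  expect_equal(nrow(unique(rec[c("patient_id", "eye")])), 50L)
  expect_true(all(rec$max_thickness_um >= 0))
  expect_true(all(rec$mean_continuous ==
    (rec$grader_a_continuous + rec$grader_b_continuous) / 2))

  # determinism through the params-borne seed
  rec2 <- generateCohort(cohortParams(nPatients = 25, seed = 5))
  expect_identical(rec, rec2)

  # law of large numbers on a stage-1-only cohort
  cp <- cohortParams(
    nPatients = 400, stageMix = c(1, 0, 0), seed = 9,
    sessionsPerEyeProb = 1
  )
  rec1 <- generateCohort(cp)
  totSd <- sqrt(40^2 + 40^2 + 25^2 + 25^2) # stage1 + patient + eye + capture
  se <- totSd / sqrt(nrow(rec1))
  expect_lt(abs(mean(rec1$max_thickness_um) - 264.2), 3 * se)

  expect_error(cohortParams(stageMix = c(0.5, 0.2, 0.1)), "sum to 1")
  expect_error(cohortParams(stageThicknessMeansUm = c(300, 280, 495)),
    "strictly increasing")
})

test_that("inter-eye correlation of true thickness grows with the patient effect", {
  eyeMeans <- function(wp, seed) {
    cp <- cohortParams(
      nPatients = 300, stageMix = c(1, 0, 0), withinPatientSdUm = wp,
      sessionsPerEyeProb = 1, measurementSdUm = 0, withinEyeSdUm = 0,
      seed = seed
    )
    rec <- generateCohort(cp)
    od <- rec$true_session_um[rec$eye == "OD"]
    os <- rec$true_session_um[rec$eye == "OS"]
    cor(od, os)
  }
  lo <- eyeMeans(0, 21)
  hi <- eyeMeans(80, 21)
  expect_lt(abs(lo), 0.15)
  expect_gt(hi, lo + 0.3)
})

test_that("treatment trajectories rise to week 0 and fall after", {
  flat <- generateTreatmentTrajectory(
    treatmentParams(preSlopeUmPerWk = 0, postDecayUmPerWk = 0, noiseSdUm = 0),
    baselineUm = 350, seed = 1
  )
  expect_true(all(flat$thickness_um == 350))

  tp <- treatmentParams(
    preSlopeUmPerWk = 25, postDecayUmPerWk = 40,
    observationWeeks = c(-2, -1, 0, 1), noiseSdUm = 0
  )
  tr <- generateTreatmentTrajectory(tp, baselineUm = 400, seed = 1)
  expect_equal(tr$thickness_um[tr$week == 0] - tr$thickness_um[tr$week == -2],
    50)
  expect_equal(tr$thickness_um[tr$week == 1], 360)

  expect_error(treatmentParams(observationWeeks = numeric()), "non-empty")
  expect_error(treatmentParams(preSlopeUmPerWk = -1), "preSlopeUmPerWk")
})

test_that("windowed summaries recover the rise-then-fall shape almost surely", {
  tp <- treatmentParams() # default slopes and 20 um visit noise
  hits <- 0L
  nRep <- 200L
  seeds <- withr::with_seed(77, sample.int(1e6, nRep))
  for (r in seq_len(nRep)) {
    recs <- list()
    for (i in 1:4) {
      for (eye in c("OD", "OS")) {
        traj <- generateTreatmentTrajectory(tp, 394,
          seed = seeds[r] + i * 10L + (eye == "OS"))
        recs[[length(recs) + 1L]] <- data.frame(
          patient_id = i, eye = eye,
          weeks_from_treatment = traj$week,
          max_thickness_um = traj$thickness_um
        )
      }
    }
    s <- suppressWarnings(treatmentWindowSummary(do.call(rbind, recs)))
    m <- setNames(s$mean_um, s$window)
    if (m["at"] > m["pre"] && m["post"] < m["at"]) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.95)
})

test_that("image mode renders one consistent volume per record", {
  cp <- cohortParams(nPatients = 1, sessionsPerEyeProb = 1, seed = 3)
  out <- generateCohort(cp, imageMode = TRUE,
    phantomTemplate = smallPhantomParams(nAxial = 340))
  expect_equal(length(out$volumes), nrow(out$records))
  for (r in seq_len(nrow(out$records))) {
    expect_s4_class(out$volumes[[r]], "OCTVolume")
    expect_equal(out$truths[[r]]@trueMaxThicknessUm,
      max(200, out$records$true_session_um[r]), tolerance = 0.02)
  }
})
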