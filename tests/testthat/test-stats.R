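test_that("adjudication averages continuous labels and settles disagreements", {
  lab <- function(ao, bo, ac, bc) data.frame(
    grader_a_ordinal = ao, grader_b_ordinal = bo,
    grader_a_continuous = ac, grader_b_continuous = bc
  )
  # agreement passes the agreed label through
  a1 <- adjudicate(lab(2L, 2L, 2.0, 2.2))
  expect_equal(a1$mean_continuous, 2.1)
  expect_equal(a1$adjudicated_ordinal, 2L)

  # disagreement: round the mean continuous label
  a2 <- adjudicate(lab(2L, 3L, 2.3, 2.6))
  expect_equal(a2$mean_continuous, 2.45)
  expect_equal(a2$adjudicated_ordinal, 2L)

  # exact .5 rounds up
  a3 <- adjudicate(lab(1L, 2L, 1.4, 1.6))
  expect_equal(a3$mean_continuous, 1.5)
  expect_equal(a3$adjudicated_ordinal, 2L)

  # idempotence: agreed records always keep their label, whatever the
  # continuous values say
  g <- generateGraderLabels(runif(200, 0, 3), noiseSd = 0.4, seed = 6)
  adj <- adjudicate(g)
  agreed <- g$grader_a_ordinal == g$grader_b_ordinal
  expect_true(all(adj$adjudicated_ordinal[agreed] ==
    g$grader_a_ordinal[agreed]))

  expect_error(adjudicate(data.frame(x = 1)), "missing columns")
})

test_that("the minimum-stage filter applies a strict less-than rule", {
  rec <- data.frame(mean_continuous = c(0.45, 0.5, 0.55, 2))
  suppressMessages(out <- filterMinStage(rec))
  expect_equal(out$mean_continuous, c(0.5, 0.55, 2))
  expect_equal(attr(out, "n_excluded"), 1L)

  empty <- filterMinStage(rec[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_excluded"), 0L)
})

test_that("weighted kappa agrees with the contingency-table oracle", {
  # perfect agreement
  expect_equal(weightedKappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)

  # 8 agreements + 2 one-step disagreements on labels {1, 2}
  a <- c(1, 1, 1, 1, 1, 2, 2, 2, 1, 1)
  b <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  expect_equal(weightedKappa(a, b), kappaOracle(a, b))

  # randomized small tables, linear and quadratic weights
  set.seed(19)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- pmin(3, pmax(0, x + sample(-1:1, n, replace = TRUE,
      prob = c(0.2, 0.6, 0.2))))
    expect_equal(weightedKappa(x, y), kappaOracle(x, y))
    expect_equal(weightedKappa(x, y, weights = "quadratic"),
      kappaOracle(x, y, quadratic = TRUE))
  }

  # independent graders: kappa indistinguishable from zero
  set.seed(23)
  reps <- replicate(60, {
    weightedKappa(sample(0:3, 400, replace = TRUE),
      sample(0:3, 400, replace = TRUE))
  })
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))

  # with observed agreement fixed, marginal imbalance lowers kappa
  balanced <- list(
    a = rep(0:3, each = 11), b = c(rep(0:3, each = 11))
  )
  balanced$b[c(1, 12, 23)] <- balanced$a[c(1, 12, 23)] + 1
  skewed <- list(
    a = c(rep(0, 41), 1, 2, 3), b = c(rep(0, 41), 1, 2, 3)
  )
  skewed$b[1:3] <- skewed$a[1:3] + 1
  agree <- function(l) mean(l$a == l$b)
  expect_equal(agree(balanced), agree(skewed))
  expect_lt(weightedKappa(skewed$a, skewed$b),
    weightedKappa(balanced$a, balanced$b))
})

test_that("grader agreement bundles percent, kappa and Pearson r", {
  g <- generateGraderLabels(rep(1:3, each = 30), noiseSd = 0, seed = 2)
  res <- graderAgreement(g)
  expect_equal(res@percentAgreement, 100)
  expect_equal(res@weightedKappa, 1)
  expect_equal(res@pearsonR, 1)

  gn <- generateGraderLabels(runif(300, 0.5, 3), noiseSd = 0.3, seed = 4)
  rn <- graderAgreement(gn)
  expect_lt(rn@percentAgreement, 100)
  expect_lt(rn@weightedKappa, 1)
  expect_equal(rn@pearsonR,
    cor(gn$grader_a_continuous, gn$grader_b_continuous))

  const <- data.frame(
    grader_a_ordinal = c(2L, 2L), grader_b_ordinal = c(2L, 2L),
    grader_a_continuous = c(2, 2), grader_b_continuous = c(2, 2.1)
  )
  expect_warning(rc <- graderAgreement(const), "constant")
  expect_true(is.na(rc@pearsonR))
})

test_that("Spearman correlation handles monotonicity, ties and transforms", {
  rec <- data.frame(
    mean_continuous = c(1, 1.5, 2, 2.5, 3),
    max_thickness_um = c(200, 250, 300, 400, 500)
  )
  expect_equal(spearmanStageThickness(rec)$rho, 1)
  rec$max_thickness_um <- rev(rec$max_thickness_um)
  expect_equal(spearmanStageThickness(rec)$rho, -1)

  # tie case against the brute-force average-rank formula
  tied <- data.frame(
    mean_continuous = c(1, 2, 2, 3, 4),
    max_thickness_um = c(150, 220, 260, 240, 380)
  )
  r1 <- rank(tied$mean_continuous)
  r2 <- rank(tied$max_thickness_um)
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(spearmanStageThickness(tied)$rho, oracle)

  # invariance under strictly monotone transforms of thickness
  tf <- tied
  tf$max_thickness_um <- log(tf$max_thickness_um)^3
  expect_equal(spearmanStageThickness(tf)$rho,
    spearmanStageThickness(tied)$rho)

  const <- data.frame(mean_continuous = c(1, 2, 3),
    max_thickness_um = c(5, 5, 5))
  expect_warning(rc <- spearmanStageThickness(const), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearmanStageThickness(tied[1:2, ]), "at least 3")
})

test_that("repeatability reports ICC and mean CoV over repeated captures", {
  # identical duplicates: perfect repeatability, exactly
  dup <- data.frame(
    patient_id = rep(1:10, each = 2), eye = "OD", session_id = 1L,
    max_thickness_um = rep(seq(250, 475, by = 25), each = 2)
  )
  r <- repeatability(dup)
  expect_identical(r@icc, 1)
  expect_identical(r@meanCovPercent, 0)
  expect_equal(r@nEyes, 10L)
  expect_equal(r@nMeasurements, 20L)

  # known variance components: ICC ~ sb^2 / (sb^2 + sw^2)
  simIcc <- function(sb, sw, nEyes, seed) {
    set.seed(seed)
    b <- rnorm(nEyes, 320, sb)
    data.frame(
      patient_id = rep(seq_len(nEyes), each = 2), eye = "OD",
      session_id = 1L,
      max_thickness_um = rep(b, each = 2) + rnorm(2 * nEyes, 0, sw)
    )
  }
  r99 <- repeatability(simIcc(100, 10, 20, 13))
  expect_equal(r99@icc, 100^2 / (100^2 + 10^2), tolerance = 0.05)

  # components chosen for a true ICC of 0.87
  sw <- 25
  sb <- sw * sqrt(0.87 / 0.13)
  r87 <- repeatability(simIcc(sb, sw, 200, 17))
  expect_equal(r87@icc, 0.87, tolerance = 0.05)

  # eyes with single captures are excluded with a warning
  mix <- rbind(dup[1:2, ], data.frame(
    patient_id = 90:94, eye = "OD", session_id = 1L,
    max_thickness_um = seq(300, 400, length.out = 5)
  ))
  warns <- capture_warnings(rx <- repeatability(mix))
  expect_match(warns, "fewer than 2 captures", all = FALSE)
  expect_equal(rx@nEyes, 1L)
})

test_that("treatment windows are assigned, averaged across eyes, and compared", {
  mk <- function(weeks, vals, pid = "A") {
    do.call(rbind, lapply(c("OD", "OS"), function(e) data.frame(
      patient_id = pid, eye = e, weeks_from_treatment = weeks,
      max_thickness_um = vals
    )))
  }
  # noise-free rise then fall across two infants
  rec <- rbind(
    mk(c(-2, -1, 0, 1, 2), c(330, 365, 400, 340, 280), "A"),
    mk(c(-2, -1, 0, 1, 2), c(310, 345, 380, 320, 260), "B")
  )
  s <- treatmentWindowSummary(rec)
  m <- setNames(s$mean_um, s$window)
  expect_gt(m["at"], m["pre"])
  expect_lt(m["post"], m["at"])
  expect_equal(attr(s, "n_excluded"), 0L)

  # boundary weeks: -1 is pre, +1 is post, -0.5 is at; 3 weeks is outside
  rec2 <- rbind(
    mk(c(-1, -0.5, 1, 3), c(300, 340, 280, 250), "A"),
    mk(c(-1, -0.5, 1, 3), c(320, 360, 300, 260), "B")
  )
  s2 <- treatmentWindowSummary(rec2)
  expect_equal(attr(s2, "n_excluded"), 2L) # one excluded visit per infant
  expect_equal(s2$n_visits, c(2L, 2L, 2L))
  expect_equal(s2$mean_um[s2$window == "pre"], 310)

  # single infant: falls back to simple means with a warning
  warns <- capture_warnings(s3 <- treatmentWindowSummary(
    mk(c(-1.5, 0, 1.5), c(330, 390, 300))))
  expect_match(warns, "single infant", all = FALSE)
  expect_equal(s3$mean_um, c(330, 390, 300))

  # an empty window is an error
  expect_error(
    suppressWarnings(treatmentWindowSummary(
      mk(c(0, 1.5), c(390, 300)))),
    "window 'pre' has no observations"
  )
})

test_that("cohort CSVs round-trip the exam-record table", {
  rec <- generateCohort(cohortParams(nPatients = 3, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(rec, f)
  back <- readCohortCsv(f)
  expect_equal(back$patient_id, rec$patient_id)
  expect_equal(back$max_thickness_um, rec$max_thickness_um)
  expect_equal(names(back), names(rec))
  expect_error(readCohortCsv("nope.csv"), "not found")
})
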