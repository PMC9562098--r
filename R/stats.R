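#' @include AllClasses.R gee.R utils.R
NULL

#' Adjudicate paired grader labels
#'
#' Combines two graders' labels for each exam: the continuous label is
#' the mean of the two continuous gradings; the adjudicated ordinal
#' label is the agreed ordinal when the graders agree and otherwise the
#' mean continuous label rounded to the nearest integer.  Halves round
#' up (1.5 becomes 2); the choice matters only on exact .5 means.
#'
#' @param labels data.frame with columns `grader_a_ordinal`,
#'   `grader_b_ordinal`, `grader_a_continuous`, `grader_b_continuous`
#'   (as produced by [generateGraderLabels()]).
#' @return data.frame with columns `mean_continuous` and
#'   `adjudicated_ordinal`.
#' @examples
#' adjudicate(data.frame(
#'   grader_a_ordinal = 2L, grader_b_ordinal = 3L,
#'   grader_a_continuous = 2.3, grader_b_continuous = 2.6))
#' @export
adjudicate <- function(labels) {
  req <- c("grader_a_ordinal", "grader_b_ordinal",
           "grader_a_continuous", "grader_b_continuous")
  missing <- setdiff(req, names(labels))
  if (length(missing))
    stop("labels is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  meanCont <- (labels$grader_a_continuous + labels$grader_b_continuous) / 2
  agreed <- labels$grader_a_ordinal == labels$grader_b_ordinal
  adj <- ifelse(agreed, labels$grader_a_ordinal,
    as.integer(roundHalfUp(meanCont)))
  data.frame(mean_continuous = meanCont,
    adjudicated_ordinal = as.integer(adj))
}

#' Exclude exams below the minimum perceptible stage
#'
#' Drops records whose mean continuous stage label is strictly below the
#' threshold (default 0.5) -- exams with no perceptible ridge to trace.
#' Records at exactly the threshold are retained.  The number excluded
#' is attached as attribute `n_excluded` and reported via a message.
#'
#' @param records exam-record data.frame with a `mean_continuous` column.
#' @param threshold exclusion threshold on the stage scale.
#' @return the filtered data.frame, with attribute `n_excluded`.
#' @export
filterMinStage <- function(records, threshold = 0.5) {
  if (!"mean_continuous" %in% names(records))
    stop("records must have a 'mean_continuous' column", call. = FALSE)
  keep <- records$mean_continuous >= threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  if (sum(!keep) > 0)
    message(sprintf("filterMinStage: excluded %d of %d records below %.2f",
      sum(!keep), length(keep), threshold))
  out
}

#' Weighted Cohen's kappa for ordinal labels
#'
#' Chance-corrected agreement with disagreement weights growing with the
#' category distance: linear weights `|i - j| / (k - 1)` by default,
#' quadratic `(i - j)^2 / (k - 1)^2` behind the `weights` flag.
#' Categories are the sorted union of the labels observed in either
#' rater.
#'
#' @param a,b equal-length vectors of ordinal labels.
#' @param weights `"linear"` or `"quadratic"`.
#' @return the weighted kappa (1 = perfect agreement).
#' @examples
#' weightedKappa(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
weightedKappa <- function(a, b, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  lev <- sort(union(a, b))
  k <- length(lev)
  if (k == 1L) return(1) # a single category: trivially perfect
  O <- table(factor(a, levels = lev), factor(b, levels = lev))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  W <- if (weights == "linear") d else d^2
  1 - sum(W * O) / sum(W * E)
}

#' Intergrader agreement on stage labels
#'
#' Percent exact agreement and weighted kappa on the ordinal labels,
#' and Pearson correlation on the continuous labels.  Pearson r is
#' reported as `NA` (with a warning) when either grader's continuous
#' labels have zero variance.
#'
#' @param records exam-record data.frame with the four grader label
#'   columns.
#' @param weights kappa weighting, `"linear"` (default) or
#'   `"quadratic"`.
#' @return an [AgreementResult-class].
#' @export
graderAgreement <- function(records, weights = "linear") {
  req <- c("grader_a_ordinal", "grader_b_ordinal",
           "grader_a_continuous", "grader_b_continuous")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 graded records", call. = FALSE)
  pct <- 100 * mean(records$grader_a_ordinal == records$grader_b_ordinal)
  kap <- weightedKappa(records$grader_a_ordinal, records$grader_b_ordinal,
    weights = weights)
  r <- if (stats::sd(records$grader_a_continuous) == 0 ||
           stats::sd(records$grader_b_continuous) == 0) {
    warning("Pearson r undefined: a grader's continuous labels are constant",
      call. = FALSE)
    NA_real_
  } else {
    stats::cor(records$grader_a_continuous, records$grader_b_continuous)
  }
  new("AgreementResult",
    percentAgreement = pct, weightedKappa = kap, pearsonR = r,
    n = as.integer(n)
  )
}

#' Stage-conditional thickness means by GEE
#'
#' Regresses maximum ridge thickness on adjudicated ordinal stage as a
#' categorical factor without intercept (so coefficients are the
#' per-stage marginal means directly), by Gaussian GEE with
#' exchangeable working correlation clustered on patient -- eyes and
#' repeat sessions of one patient are treated as exchangeable within the
#' cluster, which is how inter-eye and inter-examination correlation is
#' absorbed.  Standard errors are robust (sandwich); p-values are
#' two-sided Wald tests of each stage mean against zero.
#'
#' @param records exam-record data.frame with `max_thickness_um`,
#'   `adjudicated_ordinal` and `patient_id` columns.
#' @param stageCol name of the stage column (default adjudicated).
#' @return a [GEEStageResult-class].
#' @examples
#' rec <- generateCohort(cohortParams(nPatients = 15, seed = 3))
#' geeStageMeans(filterMinStage(rec))
#' @export
geeStageMeans <- function(records, stageCol = "adjudicated_ordinal") {
  req <- c("max_thickness_um", stageCol, "patient_id")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  stage <- factor(records[[stageCol]])
  counts <- table(stage)
  thin <- names(counts)[counts < 2L]
  if (length(thin))
    stop("stage level(s) with fewer than 2 records: ",
      paste(thin, collapse = ", "), call. = FALSE)
  if (length(unique(records$patient_id)) < 2L)
    stop("GEE needs at least 2 clusters; fit an independent model instead",
      call. = FALSE)
  X <- stats::model.matrix(~ 0 + stage)
  colnames(X) <- levels(stage)
  fit <- geeFit(records$max_thickness_um, X, records$patient_id)
  z <- fit$coefficients / fit$robust_se
  est <- data.frame(
    stage = levels(stage),
    estimate_um = unname(fit$coefficients),
    se_um = unname(fit$robust_se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    n = as.integer(counts)
  )
  new("GEEStageResult",
    estimates = est, alpha = fit$alpha,
    clusterVar = "patient_id", nClusters = as.integer(fit$n_clusters)
  )
}

#' Spearman correlation of continuous stage and thickness
#'
#' Rank correlation (average ranks for ties) between the mean continuous
#' stage label and maximum ridge thickness, with the usual two-sided
#' test.
#'
#' @param records exam-record data.frame with `mean_continuous` and
#'   `max_thickness_um`.
#' @return list with elements `rho` and `p` (both `NA` with a warning
#'   if either variable is constant).
#' @export
spearmanStageThickness <- function(records) {
  req <- c("mean_continuous", "max_thickness_um")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(records$mean_continuous) == 0 ||
      stats::sd(records$max_thickness_um) == 0) {
    warning("Spearman rho undefined: constant variable", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(records$mean_continuous,
    records$max_thickness_um, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Test-retest repeatability of the thickness biomarker
#'
#' For eyes with two or more captures of the same ridge in the same
#' session: the intraclass correlation from a one-way random-effects
#' decomposition over eyes (single-measurement form), and the mean
#' across eyes of the per-eye coefficient of variation (SD/mean of the
#' eye's repeats, percent).  Eyes contributing fewer than two captures
#' are excluded with a warning.  With identical repeats for every eye
#' the ICC is exactly 1 and the CoV exactly 0.
#'
#' @param records data.frame with `max_thickness_um` and the grouping
#'   columns named in `eyeCols` (defaults identify one eye-session).
#' @param eyeCols character vector of columns whose interaction defines
#'   a repeated-capture unit.
#' @return a [RepeatabilityResult-class].
#' @export
repeatability <- function(records,
                          eyeCols = c("patient_id", "eye", "session_id")) {
  eyeCols <- intersect(eyeCols, names(records))
  if (!length(eyeCols) || !"max_thickness_um" %in% names(records))
    stop("records must have 'max_thickness_um' and eye-identifying columns",
      call. = FALSE)
  unit <- interaction(records[eyeCols], drop = TRUE)
  sizes <- table(unit)
  keepUnits <- names(sizes)[sizes >= 2L]
  if (length(keepUnits) < length(sizes))
    warning(sprintf("excluding %d eye(s) with fewer than 2 captures",
      length(sizes) - length(keepUnits)), call. = FALSE)
  if (!length(keepUnits))
    stop("no eye has 2 or more captures", call. = FALSE)
  keep <- unit %in% keepUnits
  y <- records$max_thickness_um[keep]
  g <- droplevels(unit[keep])

  icc <- if (nlevels(g) < 2L) {
    warning("ICC undefined with a single eye; reporting NA", call. = FALSE)
    NA_real_
  } else {
    # only the mean squares are needed; the F-test (and its perfect-fit
    # warning on identical repeats) is irrelevant here
    ms <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
    msb <- ms$`Mean Sq`[1L]
    msw <- ms$`Mean Sq`[2L]
    ni <- as.numeric(table(g))
    N <- sum(ni)
    k <- nlevels(g)
    n0 <- (N - sum(ni^2) / N) / (k - 1) # average group size, unbalanced form
    if (msw == 0) 1 else (msb - msw) / (msb + (n0 - 1) * msw)
  }

  covs <- tapply(y, g, function(v) {
    if (mean(v) == 0) {
      warning("CoV undefined for a zero-mean eye; skipped", call. = FALSE)
      NA_real_
    } else {
      100 * stats::sd(v) / mean(v)
    }
  })
  new("RepeatabilityResult",
    icc = icc,
    meanCovPercent = mean(covs, na.rm = TRUE),
    nEyes = nlevels(g),
    nMeasurements = length(y)
  )
}

#' Peri-treatment thickness by time window
#'
#' Compares maximum ridge thickness across three windows around
#' treatment at week 0: pre (`[-2, -1]` weeks), at (`(-1, +1)`), and
#' post (`[+1, +2]`).  Right and left eye values of one infant are
#' averaged per visit first; each window mean then comes from an
#' intercept-only Gaussian GEE clustered by patient with robust SEs
#' (falling back to a simple mean with a warning when only one infant
#' contributes).  Records outside all windows are excluded and counted.
#'
#' @param records data.frame of treated-eye exams with `patient_id`,
#'   `weeks_from_treatment` and `max_thickness_um` (an `eye` column, if
#'   present, is averaged out per visit).
#' @return data.frame with one row per window: `window`, `mean_um`,
#'   `se_um`, `p_value`, `n_visits`, `n_patients`; attribute
#'   `n_excluded` counts records outside all windows.
#' @export
treatmentWindowSummary <- function(records) {
  req <- c("patient_id", "weeks_from_treatment", "max_thickness_um")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  ## average the two eyes of an infant at each visit
  visits <- stats::aggregate(
    max_thickness_um ~ patient_id + weeks_from_treatment,
    data = records, FUN = mean
  )
  w <- visits$weeks_from_treatment
  win <- rep(NA_character_, length(w))
  win[w >= -2 & w <= -1] <- "pre"
  win[w > -1 & w < 1] <- "at"
  win[w >= 1 & w <= 2] <- "post"
  nExcluded <- sum(is.na(win))
  visits <- visits[!is.na(win), , drop = FALSE]
  win <- win[!is.na(win)]

  rows <- lapply(c("pre", "at", "post"), function(label) {
    sub <- visits[win == label, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("window '%s' has no observations", label), call. = FALSE)
    nPat <- length(unique(sub$patient_id))
    if (nPat >= 2L) {
      fit <- geeFit(sub$max_thickness_um,
        matrix(1, nrow(sub), 1L, dimnames = list(NULL, "mean")),
        sub$patient_id)
      mu <- unname(fit$coefficients)
      se <- unname(fit$robust_se)
    } else {
      warning(sprintf(
        "window '%s': single infant; reporting a simple mean", label),
        call. = FALSE)
      mu <- mean(sub$max_thickness_um)
      se <- stats::sd(sub$max_thickness_um) / sqrt(nrow(sub))
    }
    data.frame(
      window = label, mean_um = mu, se_um = se,
      p_value = if (is.finite(se) && se > 0)
        2 * stats::pnorm(-abs(mu / se)) else NA_real_,
      n_visits = nrow(sub), n_patients = nPat
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- nExcluded
  out
}

#' Write / read a cohort table as CSV
#'
#' Fixed, documented column layout (the columns produced by
#' [generateCohort()]); plain `utils::write.csv` underneath.
#'
#' @param records exam-record data.frame.
#' @param path CSV path.
#' @return `readCohortCsv` returns the data.frame; `writeCohortCsv` the
#'   path, invisibly.
#' @export
writeCohortCsv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
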