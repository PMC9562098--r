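#' @include AllClasses.R
NULL

## cumulative arc length at each vertex of a polyline (n x 2 matrix)
.cumArcLength <- function(p) {
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

## point on the polyline at arc-length position t (vectorized over t)
.pointAt <- function(p, cum, t) {
  i <- findInterval(t, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(p) - 1L)
  segLen <- cum[i + 1L] - cum[i]
  w <- ifelse(segLen > 0, (t - cum[i]) / segLen, 0)
  p[i, , drop = FALSE] * (1 - w) + p[i + 1L, , drop = FALSE] * w
}

#' Resample a ridge trace at uniform arc-length spacing
#'
#' Places `floor(L / spacing) + 1` points along the input polyline at
#' uniform arc-length steps, then snaps the final point to the original
#' endpoint, so both endpoints are preserved and total arc length is
#' exact.  Resampling an already-uniform trace at its own spacing is an
#' identity (to numerical precision).
#'
#' @param trace a [RidgeTrace-class].
#' @param spacingPx arc-length spacing in en face pixels (> 0).
#' @return the resampled [RidgeTrace-class] (same `source`).
#' @examples
#' tr <- RidgeTrace(cbind(c(0, 0), c(0, 10)))
#' nrow(tracePoints(resampleTrace(tr, 1)))  # 11
#' @export
resampleTrace <- function(trace, spacingPx = 1) {
  stopifnot(is(trace, "RidgeTrace"))
  stopifnotScalarPositive(spacingPx, "spacingPx")
  p <- trace@points
  cum <- .cumArcLength(p)
  L <- cum[length(cum)]
  if (L <= 0) stop("degenerate zero-length trace", call. = FALSE)
  n <- floor(L / spacingPx) + 1L
  targets <- (seq_len(n) - 1L) * spacingPx
  targets[n] <- L
  out <- .pointAt(p, cum, targets)
  ## collapse a duplicated endpoint when L is an exact multiple of spacing
  if (n > 1L && sqrt(sum((out[n, ] - out[n - 1L, ])^2)) < 1e-12)
    out <- out[-n, , drop = FALSE]
  RidgeTrace(out, source = trace@source)
}

#' Extract the curved B-scan strip along a trace
#'
#' Resamples the trace at uniform arc-length spacing and, for each
#' sample position, interpolates a full A-scan column bilinearly between
#' the four neighbouring lateral positions of the volume.  The result is
#' the curved cross-section ("resultant B-scan") on which ridge surfaces
#' are segmented; columns are ordered along the trace.
#'
#' @param volume an [OCTVolume-class].
#' @param trace a [RidgeTrace-class] in 0-based en face pixel
#'   coordinates.
#' @param spacingPx arc-length spacing between strip columns (en face
#'   pixels); the default 1 preserves native lateral sampling.
#' @return a [RidgeStrip-class].
#' @examples
#' ph <- generatePhantomVolume(
#'   phantomParams(nAxial = 160, nFast = 48, nSlow = 48, speckleSnr = Inf),
#'   seed = 1)
#' strip <- extractRidgeStrip(ph$volume, ph$truth@trueRidgeline)
#' @export
extractRidgeStrip <- function(volume, trace, spacingPx = 1) {
  stopifnot(is(volume, "OCTVolume"), is(trace, "RidgeTrace"))
  rs <- resampleTrace(trace, spacingPx)
  pts <- rs@points
  v <- volume@intensities
  d <- dim(v)
  nSlow <- d[1L]
  nAxial <- d[2L]
  nFast <- d[3L]
  bad <- which(pts[, 1L] < 0 | pts[, 1L] > nSlow - 1 |
               pts[, 2L] < 0 | pts[, 2L] > nFast - 1)
  if (length(bad))
    stop(sprintf(
      "trace exits the volume lateral bounds at resampled column %d (slow=%.2f, fast=%.2f)",
      bad[1L], pts[bad[1L], 1L], pts[bad[1L], 2L]), call. = FALSE)
  n <- nrow(pts)
  strip <- matrix(0, nAxial, n)
  for (j in seq_len(n)) {
    s <- pts[j, 1L]
    f <- pts[j, 2L]
    s0 <- min(floor(s), nSlow - 2)
    f0 <- min(floor(f), nFast - 2)
    if (nSlow == 1L) s0 <- 0
    if (nFast == 1L) f0 <- 0
    ws <- s - s0
    wf <- f - f0
    s1 <- min(s0 + 1, nSlow - 1)
    f1 <- min(f0 + 1, nFast - 1)
    strip[, j] <-
      (1 - ws) * (1 - wf) * v[s0 + 1, , f0 + 1] +
      (1 - ws) * wf       * v[s0 + 1, , f1 + 1] +
      ws       * (1 - wf) * v[s1 + 1, , f0 + 1] +
      ws       * wf       * v[s1 + 1, , f1 + 1]
  }
  new("RidgeStrip",
    pixels = strip, samplePositions = pts,
    arcSpacingPx = spacingPx, axialPixelUm = volume@axialPixelUm
  )
}

#' Read / write ridge traces as CSV
#'
#' Traces are stored as a two-column CSV `slow,fast` (0-based en face
#' pixel coordinates, y-down); a header row is tolerated on read and
#' always written.
#'
#' @param path CSV path.
#' @param source trace provenance label for the loaded object.
#' @return `loadTrace` returns a [RidgeTrace-class]; `saveTrace` returns
#'   the path invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' saveTrace(RidgeTrace(cbind(c(1, 2, 3), c(5, 6, 8))), f)
#' loadTrace(f)
#' @export
loadTrace <- function(path, source = "manual") {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = hasHeader,
    col.names = c("slow", "fast"), colClasses = "character")
  m <- suppressWarnings(cbind(slow = as.numeric(df$slow),
    fast = as.numeric(df$fast)))
  if (anyNA(m))
    stop("trace file contains non-numeric cells", call. = FALSE)
  if (nrow(m) < 2L)
    stop("a trace needs at least 2 points", call. = FALSE)
  if (min(m) < 0)
    stop("trace contains negative (out-of-bounds) coordinates", call. = FALSE)
  RidgeTrace(m, source = source)
}

#' @rdname loadTrace
#' @param trace a [RidgeTrace-class] to write.
#' @export
saveTrace <- function(trace, path) {
  stopifnot(is(trace, "RidgeTrace"))
  utils::write.csv(as.data.frame(trace@points), path, row.names = FALSE,
    quote = FALSE)
  invisible(path)
}
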