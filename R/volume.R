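#' @include AllClasses.R utils.R
NULL

#' En face projection of an OCT volume
#'
#' Collapses the axial axis: pixel `(s, f)` of the result is the mean or
#' the maximum of the A-scan column `(s, ., f)`.  The full axial depth
#' is projected.
#'
#' @param volume an [OCTVolume-class].
#' @param kind `"mean"` or `"max"`.
#' @return an [EnFaceImage-class] of dimensions `(slow x fast)`.
#' @examples
#' vol <- OCTVolume(array(runif(2 * 8 * 3), c(2, 8, 3)))
#' enfaceProjection(vol, "max")
#' @export
enfaceProjection <- function(volume, kind = c("mean", "max")) {
  stopifnot(is(volume, "OCTVolume"))
  kind <- match.arg(kind)
  v <- volume@intensities
  px <- if (kind == "mean") {
    apply(v, c(1L, 3L), mean)
  } else {
    apply(v, c(1L, 3L), max)
  }
  new("EnFaceImage", pixels = px, kind = kind)
}

#' Average adjacent B-scans
#'
#' Replaces every B-scan by the mean of the `k` nearest scans along the
#' slow axis (the scan itself plus `(k-1)/2` neighbours on each side),
#' with the window truncated at the volume edges rather than reflected.
#' `k = 1` is the identity.  Scans are assumed already aligned; no
#' registration is applied.
#'
#' @param volume an [OCTVolume-class].
#' @param k odd window width, `1 <= k <= n_slow`.
#' @return the smoothed [OCTVolume-class].
#' @examples
#' vol <- OCTVolume(array(runif(6 * 8 * 3), c(6, 8, 3)))
#' sm <- averageAdjacentBscans(vol, 3L)
#' @export
averageAdjacentBscans <- function(volume, k) {
  stopifnot(is(volume, "OCTVolume"))
  nSlow <- dim(volume@intensities)[1L]
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k))
    stop("k must be a single integer", call. = FALSE)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  if (k < 1L || k > nSlow)
    stop(sprintf("k must be in [1, %d]", nSlow), call. = FALSE)
  if (k == 1L) return(volume)
  h <- (k - 1L) %/% 2L
  v <- volume@intensities
  out <- v
  for (s in seq_len(nSlow)) {
    lo <- max(1L, s - h)
    hi <- min(nSlow, s + h)
    out[s, , ] <- colMeans(v[lo:hi, , , drop = FALSE], dims = 1L)
  }
  volume@intensities <- out
  volume
}

#' Percentile contrast rescale for display
#'
#' Linearly maps the intensity range between the `lower` and `upper`
#' quantiles onto `[0, 1]`, clipping outside.  Display aid only; it
#' never feeds thickness measurement.
#'
#' @param image an [EnFaceImage-class] or numeric matrix.
#' @param lower,upper quantile bounds (defaults 1st and 99th percentile).
#' @return same type as the input, rescaled to `[0, 1]`.
#' @export
rescaleContrast <- function(image, lower = 0.01, upper = 0.99) {
  if (lower < 0 || upper > 1 || lower >= upper)
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  px <- if (is(image, "EnFaceImage")) image@pixels else image
  q <- stats::quantile(px, c(lower, upper), names = FALSE)
  scaled <- if (q[2L] > q[1L]) {
    out <- (px - q[1L]) / (q[2L] - q[1L])
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  } else {
    px * 0
  }
  if (is(image, "EnFaceImage")) {
    image@pixels <- scaled
    image
  } else {
    scaled
  }
}

#' Convert an imaging range in air to depth in tissue
#'
#' OCT ranging measures optical path length; a geometric range of
#' `range_mm_air` millimetres in air corresponds to
#' `range_mm_air / group_index` millimetres inside tissue.  With the
#' device's 6 mm air range and a retinal group index of 1.333 this gives
#' the 4.5 mm tissue imaging depth.
#'
#' @param rangeMmAir imaging range in air, millimetres (> 0).
#' @param groupIndex group refractive index of the tissue (> 0);
#'   default 1.333.
#' @return depth in tissue, millimetres.
#' @examples
#' airToTissueDepth(6, 1.333)  # ~4.5 mm
#' @export
airToTissueDepth <- function(rangeMmAir, groupIndex = 1.333) {
  stopifnotScalarPositive(rangeMmAir, "rangeMmAir")
  stopifnotScalarPositive(groupIndex, "groupIndex")
  rangeMmAir / groupIndex
}

#' Axial pixel size from tissue range and sample count
#'
#' @param rangeTissueMm axial imaging range in tissue, millimetres (> 0).
#' @param nAxial number of axial samples per A-scan (>= 1).
#' @return micrometres per axial pixel, `1000 * rangeTissueMm / nAxial`.
#' @examples
#' axialPixelSizeUm(4.5, 1024)  # ~4.4 um
#' @export
axialPixelSizeUm <- function(rangeTissueMm, nAxial) {
  stopifnotScalarPositive(rangeTissueMm, "rangeTissueMm")
  if (!is.numeric(nAxial) || length(nAxial) != 1L || nAxial < 1 ||
      nAxial != as.integer(nAxial))
    stop("nAxial must be a positive integer", call. = FALSE)
  1000 * rangeTissueMm / nAxial
}
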