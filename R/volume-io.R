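#' @include AllClasses.R
NULL

.sidecarPath <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write an OCT volume as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit TIFF page per B-scan (`axial x fast`), slow axis in page
#' order, plus a JSON sidecar (same basename, `.json`) recording pixel
#' spacing, dimensions and acquisition metadata.  Intensities must lie
#' in `[0, 1]`; values already on the 16-bit grid (as produced by
#' [generatePhantomVolume()]) round-trip bit-exactly, anything else to
#' within one part in 131070.
#'
#' @param volume an [OCTVolume-class].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return the TIFF path, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "OCTVolume"))
  v <- volume@intensities
  if (max(v) > 1)
    stop("writeVolume stores 16-bit intensities; values must be in [0, 1]",
      call. = FALSE)
  d <- dim(v)
  pages <- lapply(seq_len(d[1L]), function(s) v[s, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
    reduce = FALSE)
  sidecar <- c(
    list(
      axial_pixel_um = volume@axialPixelUm,
      lateral_pixel_um = volume@lateralPixelUm,
      n_slow = d[1L], n_axial = d[2L], n_fast = d[3L]
    ),
    volume@metadata
  )
  jsonlite::write_json(sidecar, .sidecarPath(path),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OCT volume written by [writeVolume()]
#'
#' Requires the JSON sidecar next to the stack and validates it against
#' the TIFF: page count must equal `n_slow`, page dimensions
#' `n_axial x n_fast`, and spacings must be positive.
#'
#' @param path path of the TIFF stack.
#' @return an [OCTVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume stack not found: %s", path), call. = FALSE)
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop(sprintf("missing JSON sidecar: %s", sc), call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  req <- c("axial_pixel_um", "lateral_pixel_um", "n_slow", "n_axial", "n_fast")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop("sidecar is missing fields: ", paste(missing, collapse = ", "),
      call. = FALSE)
  if (meta$axial_pixel_um <= 0 || meta$lateral_pixel_um <= 0)
    stop("sidecar declares non-positive pixel spacing", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_slow)
    stop(sprintf(
      "stack has %d pages but sidecar declares n_slow = %d",
      length(pages), meta$n_slow), call. = FALSE)
  dims <- vapply(pages, function(pg) dim(pg)[1:2], integer(2L))
  if (any(dims[1L, ] != meta$n_axial) || any(dims[2L, ] != meta$n_fast))
    stop(sprintf(
      "page dimensions %dx%d do not match sidecar %dx%d (axial x fast)",
      dims[1L, 1L], dims[2L, 1L], meta$n_axial, meta$n_fast), call. = FALSE)
  v <- array(0, c(meta$n_slow, meta$n_axial, meta$n_fast))
  for (s in seq_along(pages)) v[s, , ] <- pages[[s]]
  extra <- meta[setdiff(names(meta), req)]
  OCTVolume(v,
    axialPixelUm = meta$axial_pixel_um,
    lateralPixelUm = meta$lateral_pixel_um,
    metadata = extra
  )
}

#' Write an en face image as PNG or TIFF
#'
#' @param image an [EnFaceImage-class].
#' @param path output path ending in `.png` or `.tif(f)`.
#' @param rescale apply [rescaleContrast()] before writing (display
#'   convenience; measurement never reads these files).
#' @return the path, invisibly.
#' @export
writeEnFace <- function(image, path, rescale = TRUE) {
  stopifnot(is(image, "EnFaceImage"))
  px <- if (rescale) pixels(rescaleContrast(image)) else image@pixels
  px[px < 0] <- 0
  px[px > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    writePNGMatrix(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

## minimal grayscale PNG writer via grDevices raster device
writePNGMatrix <- function(px, path) {
  grDevices::png(path, width = ncol(px), height = nrow(px))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(px), 0, 0, 1, 1,
    interpolate = FALSE)
  invisible(path)
}
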