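#' @include AllClasses.R
NULL

#' Accessors for ridgemetry objects
#'
#' Small accessor generics so downstream code never touches slots
#' directly: `intensities()`, `axialPixelUm()`, `lateralPixelUm()`,
#' `volMetadata()` for volumes; `pixels()` and `projectionKind()` for en
#' face images and strips; `tracePoints()`, `traceSource()` and
#' `traceLength()` for traces; `samplePositions()` and `arcSpacingPx()`
#' for strips; `rpeRow()`, `innerRow()`, `validColumns()` for surface
#' pairs; `thicknessUm()` for profiles; `meanUm()`, `sdUm()`, `nUsed()`
#' for the top-n summary.
#'
#' @param object a ridgemetry S4 object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases intensities axialPixelUm lateralPixelUm volMetadata pixels
#'   projectionKind tracePoints traceSource traceLength samplePositions
#'   arcSpacingPx rpeRow innerRow validColumns thicknessUm meanUm sdUm
#'   nUsed
#' @examples
#' vol <- OCTVolume(array(0.2, c(2, 8, 2)))
#' axialPixelUm(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("axialPixelUm", function(object) standardGeneric("axialPixelUm"))
#' @rdname accessors
#' @export
setGeneric("lateralPixelUm", function(object) standardGeneric("lateralPixelUm"))
#' @rdname accessors
#' @export
setGeneric("volMetadata", function(object) standardGeneric("volMetadata"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("projectionKind", function(object) standardGeneric("projectionKind"))
#' @rdname accessors
#' @export
setGeneric("tracePoints", function(object) standardGeneric("tracePoints"))
#' @rdname accessors
#' @export
setGeneric("traceSource", function(object) standardGeneric("traceSource"))
#' @rdname accessors
#' @export
setGeneric("traceLength", function(object) standardGeneric("traceLength"))
#' @rdname accessors
#' @export
setGeneric("samplePositions", function(object) standardGeneric("samplePositions"))
#' @rdname accessors
#' @export
setGeneric("arcSpacingPx", function(object) standardGeneric("arcSpacingPx"))
#' @rdname accessors
#' @export
setGeneric("rpeRow", function(object) standardGeneric("rpeRow"))
#' @rdname accessors
#' @export
setGeneric("innerRow", function(object) standardGeneric("innerRow"))
#' @rdname accessors
#' @export
setGeneric("validColumns", function(object) standardGeneric("validColumns"))
#' @rdname accessors
#' @export
setGeneric("thicknessUm", function(object) standardGeneric("thicknessUm"))
#' @rdname accessors
#' @export
setGeneric("meanUm", function(object) standardGeneric("meanUm"))
#' @rdname accessors
#' @export
setGeneric("sdUm", function(object) standardGeneric("sdUm"))
#' @rdname accessors
#' @export
setGeneric("nUsed", function(object) standardGeneric("nUsed"))

setMethod("intensities", "OCTVolume", function(object) object@intensities)
setMethod("axialPixelUm", "OCTVolume", function(object) object@axialPixelUm)
setMethod("axialPixelUm", "RidgeStrip", function(object) object@axialPixelUm)
setMethod("axialPixelUm", "PhantomTruth", function(object) object@axialPixelUm)
setMethod("lateralPixelUm", "OCTVolume", function(object) object@lateralPixelUm)
setMethod("volMetadata", "OCTVolume", function(object) object@metadata)
setMethod("pixels", "EnFaceImage", function(object) object@pixels)
setMethod("pixels", "RidgeStrip", function(object) object@pixels)
setMethod("projectionKind", "EnFaceImage", function(object) object@kind)
setMethod("tracePoints", "RidgeTrace", function(object) object@points)
setMethod("traceSource", "RidgeTrace", function(object) object@source)
setMethod("traceLength", "RidgeTrace", function(object) {
  p <- object@points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
})
setMethod("samplePositions", "RidgeStrip", function(object) object@samplePositions)
setMethod("arcSpacingPx", "RidgeStrip", function(object) object@arcSpacingPx)
setMethod("rpeRow", "SurfacePair", function(object) object@rpeRow)
setMethod("innerRow", "SurfacePair", function(object) object@innerRow)
setMethod("validColumns", "SurfacePair", function(object) object@valid)
setMethod("thicknessUm", "ThicknessProfile", function(object) object@thicknessUm)
setMethod("meanUm", "MaxThickness", function(object) object@meanUm)
setMethod("sdUm", "MaxThickness", function(object) object@sdUm)
setMethod("nUsed", "MaxThickness", function(object) object@nUsed)

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "OCTVolume: %d B-scans x %d axial x %d fast (%.2f um axial, %.2f um lateral)\n",
    d[1L], d[2L], d[3L], object@axialPixelUm, object@lateralPixelUm
  ))
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
      sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EnFaceImage", function(object) {
  cat(sprintf(
    "EnFaceImage (%s projection): %d slow x %d fast, range [%.3g, %.3g]\n",
    object@kind, nrow(object@pixels), ncol(object@pixels),
    min(object@pixels), max(object@pixels)
  ))
})

setMethod("show", "RidgeTrace", function(object) {
  cat(sprintf(
    "RidgeTrace (%s): %d points, arc length %.1f px\n",
    object@source, nrow(object@points), traceLength(object)
  ))
})

setMethod("show", "RidgeStrip", function(object) {
  cat(sprintf(
    "RidgeStrip: %d axial x %d columns, arc spacing %.2f px\n",
    nrow(object@pixels), ncol(object@pixels), object@arcSpacingPx
  ))
})

setMethod("show", "SurfacePair", function(object) {
  cat(sprintf(
    "SurfacePair: %d columns, %d valid\n",
    length(object@valid), sum(object@valid)
  ))
})

setMethod("show", "ThicknessProfile", function(object) {
  n <- length(object@thicknessUm)
  if (n) {
    cat(sprintf(
      "ThicknessProfile: %d columns, %.1f-%.1f um (median %.1f)\n",
      n, min(object@thicknessUm), max(object@thicknessUm),
      stats::median(object@thicknessUm)
    ))
  } else {
    cat("ThicknessProfile: empty (no valid columns)\n")
  }
})

setMethod("show", "MaxThickness", function(object) {
  cat(sprintf(
    "MaxThickness: %.1f um (SD %.1f, n=%d)\n",
    object@meanUm, object@sdUm, object@nUsed
  ))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d x %d field, true max thickness %.1f um\n",
    nrow(object@rpeSurface), ncol(object@rpeSurface),
    object@trueMaxThicknessUm
  ))
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf(
    "Grader agreement (n=%d): %.1f%% exact, weighted kappa %.3f, Pearson r %.3f\n",
    object@n, object@percentAgreement, object@weightedKappa, object@pearsonR
  ))
})

setMethod("show", "GEEStageResult", function(object) {
  cat(sprintf(
    "GEE stage means (cluster = %s, %d clusters, alpha = %.3f):\n",
    object@clusterVar, object@nClusters, object@alpha
  ))
  print(object@estimates, row.names = FALSE)
})

setMethod("show", "RepeatabilityResult", function(object) {
  cat(sprintf(
    "Repeatability: ICC %.3f, mean CoV %.2f%% (%d eyes, %d measurements)\n",
    object@icc, object@meanCovPercent, object@nEyes, object@nMeasurements
  ))
})
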