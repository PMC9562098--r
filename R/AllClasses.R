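#' @import methods
NULL

## Coordinate conventions used throughout the package
## ---------------------------------------------------
## Volumes are indexed (slow, axial, fast).  Axial row 0 is the vitreous
## side (top of a B-scan); rows increase towards the choroid.  All
## user-facing pixel coordinates and surface row indices are 0-based and
## real-valued (sub-pixel positions are meaningful).  En face images are
## (slow x fast), y-down: slow is the vertical (y) axis, fast the
## horizontal (x) axis.

#' OCTVolume: a volumetric OCT scan
#'
#' A 3-D intensity volume indexed `(slow, axial, fast)` together with its
#' axial and lateral pixel spacing and acquisition metadata.  Intensities
#' are linear-scale, finite and non-negative; the phantom generator and
#' the TIFF writer additionally keep them in `[0, 1]`.
#'
#' @slot intensities 3-D numeric array, dimensions `(n_slow, n_axial, n_fast)`.
#' @slot axialPixelUm axial pixel spacing in micrometres.
#' @slot lateralPixelUm lateral (en face) pixel spacing in micrometres.
#' @slot metadata named list: `patient_id`, `eye`, `session_id`, `fov`
#'   (field-of-view label, e.g. `"105"` or `"140"`), `seed`.
#'
#' @seealso [OCTVolume()], [readVolume()], [enfaceProjection()]
#' @export
setClass("OCTVolume",
  representation(
    intensities = "array",
    axialPixelUm = "numeric",
    lateralPixelUm = "numeric",
    metadata = "list"
  )
)

setValidity("OCTVolume", function(object) {
  v <- object@intensities
  if (length(dim(v)) != 3L)
    return("intensities must be a 3-D array (slow, axial, fast)")
  if (any(dim(v) < 1L))
    return("all volume dimensions must be >= 1")
  if (!all(is.finite(v)))
    return("intensities must be finite")
  if (min(v) < 0)
    return("intensities must be non-negative")
  if (length(object@axialPixelUm) != 1L || object@axialPixelUm <= 0)
    return("axialPixelUm must be a single positive number")
  if (length(object@lateralPixelUm) != 1L || object@lateralPixelUm <= 0)
    return("lateralPixelUm must be a single positive number")
  TRUE
})

#' Construct an OCTVolume
#'
#' @param intensities 3-D numeric array `(slow, axial, fast)`.
#' @param axialPixelUm axial spacing, micrometres per pixel.
#' @param lateralPixelUm lateral spacing, micrometres per pixel.
#' @param metadata named list of acquisition metadata.
#' @return an [OCTVolume-class] object.
#' @examples
#' vol <- OCTVolume(array(0.5, c(4, 16, 4)), axialPixelUm = 4.4)
#' dim(intensities(vol))
#' @export
OCTVolume <- function(intensities, axialPixelUm = 4.4, lateralPixelUm = 10,
                      metadata = list()) {
  new("OCTVolume",
    intensities = intensities,
    axialPixelUm = as.numeric(axialPixelUm),
    lateralPixelUm = as.numeric(lateralPixelUm),
    metadata = metadata
  )
}

#' EnFaceImage: an axial projection of an OCT volume
#'
#' @slot pixels 2-D numeric matrix `(slow x fast)`.
#' @slot kind projection kind, `"mean"` or `"max"`.
#' @seealso [enfaceProjection()]
#' @export
setClass("EnFaceImage",
  representation(pixels = "matrix", kind = "character")
)

setValidity("EnFaceImage", function(object) {
  if (!object@kind %in% c("mean", "max"))
    return("kind must be 'mean' or 'max'")
  if (!all(is.finite(object@pixels)))
    return("pixels must be finite")
  TRUE
})

#' RidgeTrace: a traced ridgeline in en face coordinates
#'
#' An ordered open polyline marking the peak of the fibrovascular ridge
#' on the en face projection.  Points are `(slow, fast)` en face pixel
#' coordinates, 0-based, real-valued, y-down.
#'
#' @slot points numeric matrix with columns `slow`, `fast`; at least two
#'   rows; consecutive points distinct.
#' @slot source `"manual"` for operator traces, `"truth"` for phantom
#'   ground-truth ridgelines.
#' @seealso [RidgeTrace()], [resampleTrace()], [extractRidgeStrip()]
#' @export
setClass("RidgeTrace",
  representation(points = "matrix", source = "character")
)

setValidity("RidgeTrace", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (slow, fast)")
  if (nrow(p) < 2L) return("a trace needs at least 2 points")
  if (!all(is.finite(p))) return("trace points must be finite")
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) return("consecutive trace points must be distinct")
  if (!object@source %in% c("manual", "truth"))
    return("source must be 'manual' or 'truth'")
  TRUE
})

#' Construct a RidgeTrace
#'
#' @param points two-column numeric matrix (or data.frame) of `(slow, fast)`
#'   en face pixel coordinates, 0-based.
#' @param source `"manual"` or `"truth"`.
#' @return a [RidgeTrace-class].
#' @examples
#' tr <- RidgeTrace(cbind(slow = c(0, 0), fast = c(0, 10)))
#' traceLength(tr)
#' @export
RidgeTrace <- function(points, source = "manual") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("slow", "fast")
  new("RidgeTrace", points = points, source = source)
}

#' RidgeStrip: a curved B-scan reformatted along a trace
#'
#' One interpolated A-scan column per resampled trace position, ordered
#' along the trace.  This is the curved cross-section on which the ridge
#' surfaces are segmented.
#'
#' @slot pixels numeric matrix `(n_axial x n_columns)`.
#' @slot samplePositions matrix of `(slow, fast)` en face coordinates of
#'   each column.
#' @slot arcSpacingPx spacing between adjacent columns along the curve,
#'   in en face pixels.
#' @slot axialPixelUm axial spacing inherited from the source volume.
#' @seealso [extractRidgeStrip()], [segmentSurfaces()]
#' @export
setClass("RidgeStrip",
  representation(
    pixels = "matrix",
    samplePositions = "matrix",
    arcSpacingPx = "numeric",
    axialPixelUm = "numeric"
  )
)

setValidity("RidgeStrip", function(object) {
  if (ncol(object@pixels) != nrow(object@samplePositions))
    return("one sample position per strip column is required")
  if (object@arcSpacingPx <= 0) return("arcSpacingPx must be positive")
  if (object@axialPixelUm <= 0) return("axialPixelUm must be positive")
  TRUE
})

#' SurfacePair: per-column RPE and inner-surface rows
#'
#' Axial row indices (0-based, sub-pixel) of the retinal pigment
#' epithelium and of the inner ridge surface (tissue-vitreous interface)
#' for each strip column, with a per-column validity flag.  Columns where
#' either surface could not be located are flagged invalid rather than
#' guessed.
#'
#' @slot rpeRow numeric vector of RPE rows (NA where invalid).
#' @slot innerRow numeric vector of inner-surface rows (NA where invalid).
#' @slot valid logical vector, one flag per column.
#' @seealso [segmentSurfaces()], [thicknessProfile()]
#' @export
setClass("SurfacePair",
  representation(rpeRow = "numeric", innerRow = "numeric", valid = "logical")
)

setValidity("SurfacePair", function(object) {
  n <- length(object@valid)
  if (length(object@rpeRow) != n || length(object@innerRow) != n)
    return("rpeRow, innerRow and valid must have equal length")
  ok <- object@valid
  if (any(ok & (is.na(object@rpeRow) | is.na(object@innerRow))))
    return("valid columns must have both surfaces")
  bad <- which(ok & object@innerRow > object@rpeRow + 1e-9)
  if (length(bad))
    return(sprintf("inner surface below RPE at column %d", bad[1L]))
  TRUE
})

#' Construct a SurfacePair
#' @param rpeRow,innerRow numeric vectors of 0-based axial rows.
#' @param valid logical vector; defaults to both surfaces being present.
#' @return a [SurfacePair-class].
#' @export
SurfacePair <- function(rpeRow, innerRow,
                        valid = is.finite(rpeRow) & is.finite(innerRow)) {
  new("SurfacePair",
    rpeRow = as.numeric(rpeRow), innerRow = as.numeric(innerRow),
    valid = as.logical(valid)
  )
}

#' ThicknessProfile: per-column axial thickness along the ridge
#'
#' @slot thicknessUm per-column `(rpe - inner) * axialPixelUm` in
#'   micrometres, valid columns only.
#' @slot columnPositions en face `(slow, fast)` coordinates of the
#'   retained columns.
#' @seealso [thicknessProfile()], [maxRidgeThickness()]
#' @export
setClass("ThicknessProfile",
  representation(thicknessUm = "numeric", columnPositions = "matrix")
)

setValidity("ThicknessProfile", function(object) {
  if (length(object@thicknessUm) &&
      (!all(is.finite(object@thicknessUm)) || min(object@thicknessUm) < 0))
    return("thickness values must be finite and non-negative")
  if (nrow(object@columnPositions) != length(object@thicknessUm))
    return("one position per thickness value is required")
  TRUE
})

#' MaxThickness: the top-n maximum ridge thickness summary
#'
#' The single-number biomarker attached to an exam: the mean of the
#' `n` largest per-column thickness values along the traced ridge,
#' with the SD of those selected values and the count actually used.
#'
#' @slot meanUm mean of the selected top-n thickness values (micrometres).
#' @slot sdUm population SD of the selected values.
#' @slot nUsed number of values averaged (may fall short of the request
#'   on short traces).
#' @seealso [maxRidgeThickness()], [measureExam()]
#' @export
setClass("MaxThickness",
  representation(meanUm = "numeric", sdUm = "numeric", nUsed = "integer")
)

#' PhantomTruth: ground truth for a synthetic volume
#'
#' @slot rpeSurface matrix `(slow x fast)` of 0-based RPE axial rows.
#' @slot innerSurface matrix `(slow x fast)` of 0-based inner-surface rows.
#' @slot trueMaxThicknessUm analytic maximum of
#'   `(rpe - inner) * axialPixelUm` over the field.
#' @slot trueRidgeline [RidgeTrace-class] along the ridge crest.
#' @slot axialPixelUm axial spacing used to express thickness.
#' @seealso [generatePhantomVolume()]
#' @export
setClass("PhantomTruth",
  representation(
    rpeSurface = "matrix",
    innerSurface = "matrix",
    trueMaxThicknessUm = "numeric",
    trueRidgeline = "RidgeTrace",
    axialPixelUm = "numeric"
  )
)

setValidity("PhantomTruth", function(object) {
  if (!identical(dim(object@rpeSurface), dim(object@innerSurface)))
    return("surface matrices must share dimensions")
  if (any(object@innerSurface > object@rpeSurface + 1e-9))
    return("inner surface must lie at or above the RPE (row 0 is vitreous)")
  TRUE
})

## ---- statistical result containers ----------------------------------

#' AgreementResult: intergrader agreement summary
#'
#' @slot percentAgreement exact ordinal agreement, percent in `[0, 100]`.
#' @slot weightedKappa chance-corrected weighted kappa (linear weights by
#'   default).
#' @slot pearsonR Pearson correlation of the two graders' continuous
#'   labels (`NA` when a grader's labels have zero variance).
#' @slot n number of graded exams.
#' @seealso [graderAgreement()]
#' @export
setClass("AgreementResult",
  representation(
    percentAgreement = "numeric", weightedKappa = "numeric",
    pearsonR = "numeric", n = "integer"
  )
)

#' GEEStageResult: stage-conditional thickness means from a GEE fit
#'
#' Per-stage mean maximum ridge thickness estimated by a generalized
#' estimating equation with identity link and exchangeable working
#' correlation, clustered by patient, with robust (sandwich) standard
#' errors.
#'
#' @slot estimates data.frame with columns `stage`, `estimate_um`,
#'   `se_um`, `p_value`, `n`.
#' @slot alpha estimated working exchangeable correlation.
#' @slot clusterVar name of the clustering variable.
#' @slot nClusters number of clusters used.
#' @seealso [geeStageMeans()]
#' @export
setClass("GEEStageResult",
  representation(
    estimates = "data.frame", alpha = "numeric",
    clusterVar = "character", nClusters = "integer"
  )
)

#' RepeatabilityResult: test-retest precision of the thickness biomarker
#'
#' @slot icc one-way random-effects intraclass correlation.
#' @slot meanCovPercent mean across eyes of the per-eye coefficient of
#'   variation (SD/mean of the eye's repeats, percent).
#' @slot nEyes number of eyes with at least two captures.
#' @slot nMeasurements total captures used.
#' @seealso [repeatability()]
#' @export
setClass("RepeatabilityResult",
  representation(
    icc = "numeric", meanCovPercent = "numeric",
    nEyes = "integer", nMeasurements = "integer"
  )
)
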