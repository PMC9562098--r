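#' @include AllClasses.R
NULL

#' PhantomParams: geometry and optics of a synthetic OCT volume
#'
#' Parameters of the synthetic retina rendered by
#' [generatePhantomVolume()]: a flat RPE at a fixed depth, an inner
#' retinal surface a baseline thickness above it, and a localized
#' fibrovascular ridge modeled as a Gaussian-profile elevation of the
#' inner surface along a circular arc in the en face plane (the
#' vascular-avascular junction).  Intensities are rendered in `[0, 1]`
#' with partial-volume (anti-aliased) boundaries, optionally multiplied
#' by gamma-distributed speckle.
#'
#' @slot nAxial,nFast,nSlow volume dimensions in pixels.  The default
#'   `nAxial = 1024` over a 4.5 mm tissue imaging range gives the
#'   device's 4.4 um axial pixel.
#' @slot axialPixelUm,lateralPixelUm pixel spacing, micrometres.
#' @slot baselineRetinaUm baseline inner-surface-to-RPE thickness away
#'   from the ridge.
#' @slot ridgeHeightUm peak ridge elevation above baseline (>= 0).
#' @slot arcCenterClock,arcExtentClock,arcRadiusPx ridge arc: clock-hour
#'   position of its center (12 = up, clockwise), angular extent in
#'   clock hours (0-12], and radius in en face pixels of the circle it
#'   lies on (NA = 0.35 x the smaller lateral dimension).
#' @slot ridgeSigmaUm transverse Gaussian width of the ridge bump
#'   (micrometres); the axial extent of the bump is its height.
#' @slot speckleSnr signal-to-noise ratio of the multiplicative speckle
#'   (gamma with unit mean, SD = 1/SNR; `speckleSnr = 1` is the fully
#'   developed exponential case, `Inf` disables noise).
#' @slot backgroundLevel,tissueLevel,rpeLevel,subRpeLevel mean rendered
#'   intensities of vitreous, inner retina/ridge, RPE band, and the
#'   tissue below the RPE.
#' @slot rpeDepthUm depth of the RPE below the volume top (NA = 60% of
#'   the axial range).
#' @slot rpeBandUm full axial width of the bright RPE band.
#' @seealso [phantomParams()], [generatePhantomVolume()]
#' @export
setClass("PhantomParams",
  representation(
    nAxial = "integer", nFast = "integer", nSlow = "integer",
    axialPixelUm = "numeric", lateralPixelUm = "numeric",
    baselineRetinaUm = "numeric", ridgeHeightUm = "numeric",
    arcCenterClock = "numeric", arcExtentClock = "numeric",
    arcRadiusPx = "numeric", ridgeSigmaUm = "numeric",
    speckleSnr = "numeric",
    backgroundLevel = "numeric", tissueLevel = "numeric",
    rpeLevel = "numeric", subRpeLevel = "numeric",
    rpeDepthUm = "numeric", rpeBandUm = "numeric"
  )
)

setValidity("PhantomParams", function(object) {
  if (object@nAxial < 1L || object@nFast < 1L || object@nSlow < 1L)
    return("all dimensions must be >= 1")
  if (object@axialPixelUm <= 0 || object@lateralPixelUm <= 0)
    return("pixel spacings must be positive")
  if (object@ridgeHeightUm < 0) return("ridgeHeightUm must be >= 0")
  if (object@baselineRetinaUm <= 0) return("baselineRetinaUm must be positive")
  if (!(object@tissueLevel > object@backgroundLevel))
    return("tissueLevel must exceed backgroundLevel")
  if (!(object@rpeLevel > object@tissueLevel))
    return("rpeLevel must exceed tissueLevel")
  if (object@arcExtentClock <= 0 || object@arcExtentClock > 12)
    return("arcExtentClock must be in (0, 12] clock hours")
  if (object@ridgeSigmaUm <= 0) return("ridgeSigmaUm must be positive")
  if (object@speckleSnr <= 0) return("speckleSnr must be positive (Inf = off)")
  if (object@rpeBandUm <= 0) return("rpeBandUm must be positive")
  TRUE
})

#' Construct PhantomParams
#'
#' @param nAxial,nFast,nSlow volume dimensions (pixels).
#' @param axialPixelUm,lateralPixelUm pixel spacing (micrometres).
#' @param baselineRetinaUm baseline retina thickness (micrometres).
#' @param ridgeHeightUm peak ridge elevation above baseline (micrometres).
#' @param arcCenterClock,arcExtentClock,arcRadiusPx ridge arc geometry
#'   (clock hours, clock hours, en face pixels).
#' @param ridgeSigmaUm transverse Gaussian width of the ridge (micrometres).
#' @param speckleSnr multiplicative speckle SNR (`Inf` = noise-free).
#' @param backgroundLevel,tissueLevel,rpeLevel,subRpeLevel rendered
#'   intensity levels in `[0, 1]`.
#' @param rpeDepthUm RPE depth below the volume top (micrometres).
#' @param rpeBandUm axial width of the RPE band (micrometres).
#' @return a validated [PhantomParams-class] object.
#' @examples
#' p <- phantomParams(nAxial = 256, nFast = 64, nSlow = 64,
#'                    ridgeHeightUm = 300, speckleSnr = Inf)
#' @export
phantomParams <- function(nAxial = 1024L, nFast = 128L, nSlow = 128L,
                          axialPixelUm = 4.4, lateralPixelUm = 15,
                          baselineRetinaUm = 200, ridgeHeightUm = 150,
                          arcCenterClock = 9, arcExtentClock = 3,
                          arcRadiusPx = NA_real_, ridgeSigmaUm = 150,
                          speckleSnr = 3,
                          backgroundLevel = 0.05, tissueLevel = 0.45,
                          rpeLevel = 0.85, subRpeLevel = 0.25,
                          rpeDepthUm = NA_real_, rpeBandUm = 22) {
  if (is.na(arcRadiusPx)) arcRadiusPx <- 0.35 * min(nFast, nSlow)
  if (is.na(rpeDepthUm)) rpeDepthUm <- 0.6 * nAxial * axialPixelUm
  new("PhantomParams",
    nAxial = as.integer(nAxial), nFast = as.integer(nFast),
    nSlow = as.integer(nSlow),
    axialPixelUm = axialPixelUm, lateralPixelUm = lateralPixelUm,
    baselineRetinaUm = baselineRetinaUm, ridgeHeightUm = ridgeHeightUm,
    arcCenterClock = arcCenterClock, arcExtentClock = arcExtentClock,
    arcRadiusPx = arcRadiusPx, ridgeSigmaUm = ridgeSigmaUm,
    speckleSnr = speckleSnr,
    backgroundLevel = backgroundLevel, tissueLevel = tissueLevel,
    rpeLevel = rpeLevel, subRpeLevel = subRpeLevel,
    rpeDepthUm = rpeDepthUm, rpeBandUm = rpeBandUm
  )
}

#' CohortParams: structure of a simulated ROP screening cohort
#'
#' Defines the nested sampling design (sessions within eyes within
#' patients), the stage-conditional distribution of true maximum ridge
#' thickness, the variance components that induce inter-eye and
#' inter-session correlation, and the grader noise model.  Defaults
#' mirror the study design this biomarker was validated on: 25 patients,
#' two eyes each, 1-4 sessions per eye (about 128 volumes), stage mix
#' close to 50/65/13 over stages 1-3, and stage-conditional mean
#' thicknesses of 264.2, 334.2 and 495.0 um.
#'
#' @slot nPatients number of patients.
#' @slot eyesPerPatient eyes sampled per patient (default 2).
#' @slot sessionsPerEyeProb probability vector over 1..k sessions per eye.
#' @slot stageMix probabilities of ordinal stages 1, 2, 3 (sums to 1).
#' @slot stageThicknessMeansUm,stageThicknessSdUm per-stage mean and SD
#'   of eye-level true maximum thickness (micrometres); means must be
#'   strictly increasing with stage.
#' @slot withinPatientSdUm SD of the patient-level random effect shared
#'   by both eyes (drives inter-eye correlation).
#' @slot withinEyeSdUm SD of the session-level biological fluctuation
#'   within an eye.
#' @slot measurementSdUm SD of capture-to-capture measurement noise
#'   (drives test-retest repeatability).
#' @slot graderNoiseSd SD of each grader's continuous-label error on the
#'   0-3 stage scale.
#' @slot seed RNG seed used by [generateCohort()].
#' @seealso [cohortParams()], [generateCohort()]
#' @export
setClass("CohortParams",
  representation(
    nPatients = "integer", eyesPerPatient = "integer",
    sessionsPerEyeProb = "numeric", stageMix = "numeric",
    stageThicknessMeansUm = "numeric", stageThicknessSdUm = "numeric",
    withinPatientSdUm = "numeric", withinEyeSdUm = "numeric",
    measurementSdUm = "numeric", graderNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortParams", function(object) {
  if (object@nPatients < 0L) return("nPatients must be >= 0")
  if (object@eyesPerPatient < 1L) return("eyesPerPatient must be >= 1")
  if (abs(sum(object@stageMix) - 1) > 1e-6)
    return("stageMix must sum to 1")
  if (any(object@stageMix < 0)) return("stageMix must be non-negative")
  if (length(object@stageThicknessMeansUm) != length(object@stageMix) ||
      length(object@stageThicknessSdUm) != length(object@stageMix))
    return("per-stage means/SDs must match the number of stages in stageMix")
  if (any(diff(object@stageThicknessMeansUm) <= 0))
    return("per-stage mean thickness must be strictly increasing with stage")
  sds <- c(object@stageThicknessSdUm, object@withinPatientSdUm,
           object@withinEyeSdUm, object@measurementSdUm, object@graderNoiseSd)
  if (any(sds < 0)) return("all SDs must be >= 0")
  if (any(object@sessionsPerEyeProb < 0) ||
      abs(sum(object@sessionsPerEyeProb) - 1) > 1e-6)
    return("sessionsPerEyeProb must be a probability vector")
  TRUE
})

#' Construct CohortParams
#'
#' @param nPatients,eyesPerPatient cohort size.
#' @param sessionsPerEyeProb probabilities of 1..k sessions per eye.
#' @param stageMix stage probabilities over stages 1..3.
#' @param stageThicknessMeansUm,stageThicknessSdUm stage-conditional
#'   thickness distribution (micrometres).
#' @param withinPatientSdUm,withinEyeSdUm,measurementSdUm variance
#'   components (micrometres).
#' @param graderNoiseSd grader continuous-label noise SD (stage units).
#' @param seed RNG seed.
#' @return a validated [CohortParams-class] object.
#' @examples
#' cp <- cohortParams(nPatients = 10, seed = 7)
#' @export
cohortParams <- function(nPatients = 25L, eyesPerPatient = 2L,
                         sessionsPerEyeProb = c(0.2, 0.3, 0.3, 0.2),
                         stageMix = c(50, 65, 13) / 128,
                         stageThicknessMeansUm = c(264.2, 334.2, 495.0),
                         stageThicknessSdUm = c(40, 50, 80),
                         withinPatientSdUm = 40, withinEyeSdUm = 25,
                         measurementSdUm = 25, graderNoiseSd = 0.22,
                         seed = 1L) {
  new("CohortParams",
    nPatients = as.integer(nPatients),
    eyesPerPatient = as.integer(eyesPerPatient),
    sessionsPerEyeProb = sessionsPerEyeProb, stageMix = stageMix,
    stageThicknessMeansUm = stageThicknessMeansUm,
    stageThicknessSdUm = stageThicknessSdUm,
    withinPatientSdUm = withinPatientSdUm, withinEyeSdUm = withinEyeSdUm,
    measurementSdUm = measurementSdUm, graderNoiseSd = graderNoiseSd,
    seed = as.integer(seed)
  )
}

#' TreatmentParams: shape of the peri-treatment thickness trajectory
#'
#' Maximum ridge thickness rises linearly up to the treatment visit
#' (week 0) and falls linearly after it, with independent per-visit
#' noise.  Defaults give a peri-treatment course comparable in scale to
#' observed anti-VEGF responses (a rise of roughly 35 um/week before and
#' a fall of roughly 60 um/week after treatment).
#'
#' @slot preSlopeUmPerWk rise rate before treatment (um/week, >= 0).
#' @slot postDecayUmPerWk fall rate after treatment (um/week, >= 0).
#' @slot observationWeeks visit times relative to treatment at week 0.
#' @slot noiseSdUm per-visit measurement noise SD (micrometres).
#' @seealso [treatmentParams()], [generateTreatmentTrajectory()]
#' @export
setClass("TreatmentParams",
  representation(
    preSlopeUmPerWk = "numeric", postDecayUmPerWk = "numeric",
    observationWeeks = "numeric", noiseSdUm = "numeric"
  )
)

setValidity("TreatmentParams", function(object) {
  if (object@preSlopeUmPerWk < 0) return("preSlopeUmPerWk must be >= 0")
  if (object@postDecayUmPerWk < 0) return("postDecayUmPerWk must be >= 0")
  if (!length(object@observationWeeks))
    return("observationWeeks must be non-empty")
  if (object@noiseSdUm < 0) return("noiseSdUm must be >= 0")
  TRUE
})

#' Construct TreatmentParams
#'
#' @param preSlopeUmPerWk,postDecayUmPerWk trajectory slopes (um/week).
#' @param observationWeeks visit schedule relative to treatment (weeks).
#' @param noiseSdUm per-visit noise SD (micrometres).
#' @return a validated [TreatmentParams-class] object.
#' @examples
#' tp <- treatmentParams(noiseSdUm = 0)
#' @export
treatmentParams <- function(preSlopeUmPerWk = 35, postDecayUmPerWk = 60,
                            observationWeeks = seq(-2, 2, by = 0.5),
                            noiseSdUm = 20) {
  new("TreatmentParams",
    preSlopeUmPerWk = preSlopeUmPerWk, postDecayUmPerWk = postDecayUmPerWk,
    observationWeeks = observationWeeks, noiseSdUm = noiseSdUm
  )
}
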