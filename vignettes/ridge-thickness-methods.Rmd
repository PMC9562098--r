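---
title: "Measuring fibrovascular ridge thickness from volumetric OCT: models, parameters and validation"
author: "ridgemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fibrovascular ridge thickness from volumetric OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgemetry)
```

# The measurement model

In retinopathy of prematurity (ROP), abnormal vascularization forms a
ridge of fibrovascular tissue at the junction between vascularized and
avascular retina. `ridgemetry` quantifies that ridge from a volumetric
OCT scan as an **axial thickness**: along a ridgeline traced on the en
face projection, the distance between the retinal pigment epithelium
(RPE) and the inner surface of the ridge (the tissue–vitreous
interface), measured pixelwise in depth and summarized per exam.

The chain is:

1. **En face visualization** (`enfaceProjection`,
   `averageAdjacentBscans`, `rescaleContrast`): full-depth mean or
   maximum projection along the axial axis; optional averaging of the
   `k` nearest B-scans (truncated window, no registration — phantom
   scans are aligned by construction, and registration of real scans
   is an extension point); percentile contrast rescale for display
   only.
2. **Ridgeline trace** (`RidgeTrace`): an ordered open polyline in en
   face pixel coordinates, `(slow, fast)`, 0-based, y-down. Traces are
   manual in practice; phantom ground-truth crest lines stand in for
   them in every test. Clinically the trace follows the vascular side
   of the junction; the package treats that as a labeling guideline,
   not enforced geometry.
3. **Curved strip extraction** (`extractRidgeStrip`): the trace is
   resampled at uniform arc-length spacing (default 1 px, preserving
   native lateral sampling) and one full A-scan column is interpolated
   **bilinearly** at each sample. Bilinear rather than
   nearest-neighbour interpolation matters because manual traces are
   sub-pixel; snapping to the lattice would alias thickness where the
   trace crosses the crest obliquely. Whether clinical readers measure
   on native B-scans or curved reformats is not standardized; the
   curved reformat is implemented as the general case (a native scan
   is the special case of a straight trace along a scan line).
4. **Surface segmentation** (`segmentSurfaces`): per strip column, on a
   lightly smoothed A-scan, the inner surface is the first depth at
   which intensity exceeds a threshold for a minimum run length,
   refined to sub-pixel at the 50% point of the local
   background-to-tissue transition; the RPE is the centre of the
   brightest band below it, refined by parabolic interpolation around
   the peak. Columns where either search fails are flagged invalid and
   excluded — never guessed. Clinical segmentation of these surfaces
   is manual; the automated routine substitutes for it on
   phantom-rendered strips and is fully verifiable against phantom
   truth, while manually segmented surfaces can enter the same pipeline
   through `SurfacePair()` + `thicknessProfile()`.
5. **The exam statistic** (`maxRidgeThickness`, `measureExam`):
   per-column thickness is `(rpe_row − inner_row) × axialPixelUm`
   micrometres; the exam-level maximum ridge thickness is the mean of
   the **10 largest** per-column values, reported with the population
   SD of those selected values and the count actually used. Two
   interpretations are deliberate here: the sampling unit of "top 10"
   is the A-scan column of the profile (the natural pixelwise reading;
   no spatial-separation constraint is imposed between the selected
   columns), and on traces with fewer than 10 valid columns all are
   averaged with `nUsed` recording the shortfall, rather than erroring.

## Device scale

The target device images 6 mm in air; with a retinal group index of
1.333 (the index itself is a package default — only the 6 mm ≈ 4.5 mm
relation is device-documented) that is 4.5 mm in tissue, and at 1024
axial samples per A-scan gives 4.4 μm per axial pixel
(`airToTissueDepth`, `axialPixelSizeUm`). 1024 is the package's choice
of sample count consistent with that per-pixel scale. All thickness
outputs scale linearly in `axialPixelUm`.

# The synthetic phantom

Patient images are not public, so validation rests on synthetic
volumes with analytic ground truth (`generatePhantomVolume`).

**Geometry.** A flat RPE at depth `rpeDepthUm` (default 60% of the
axial range) with a bright band of width `rpeBandUm` (22 μm); an inner
retinal surface `baselineRetinaUm` (200 μm) above it; and a ridge
modeled as a **Gaussian-profile elevation of the inner surface along a
circular arc** — the en face circle models the vascular–avascular
junction, positioned by clock-hour centre and extent
(`arcCenterClock = 9`, `arcExtentClock = 3` clock hours,
`arcRadiusPx` defaulting to 0.35× the smaller lateral dimension). The
elevation is `ridgeHeightUm · exp(−(d² + b²)/2σ²)` where `d` is the
radial distance to the circle and `b` the along-arc distance beyond the
arc ends (so the crest is at full height along the whole arc, with
smooth tapers); `σ = ridgeSigmaUm` (150 μm) is the transverse width.
A Gaussian-bump crest is the fewest-parameter shape that reproduces the
dome-like ridge cross-sections seen on B-scans. Because the bump is an
elevation of a surface, only its transverse width is a free parameter —
its axial extent *is* the height field.

**Rendering.** Axial row 0 is the vitreous (top of a B-scan); all
indices are 0-based; boundaries are rendered with partial-volume
mixing (a row's intensity is the coverage-weighted mix of the regions
it straddles), which is what makes sub-pixel surface recovery
meaningful. Intensity levels (vitreous 0.05, retina 0.45, RPE 0.85,
sub-RPE 0.25) are linear-scale fractions of full scale. Speckle is
multiplicative gamma noise with unit mean and SD `1/speckleSnr`
(default SNR 3, typical of averaged clinical B-scans); at SNR 1 this is
exactly the fully developed exponential speckle model, and `Inf`
disables noise. Volumes are clipped to `[0, 1]` and quantized to the
16-bit grid, so TIFF round-trips are bit-exact.

**Truth.** `PhantomTruth` carries the real-valued surface grids, the
crest polyline, and the analytic maximum thickness
`baselineRetinaUm + ridgeHeightUm` (up to grid sampling of the
Gaussian, well under one axial pixel). The suite verifies, noise-free,
that the full chain lands within **one axial pixel (4.4 μm)** of this
truth across ridge heights 0–600 μm, and that a brute-force scan of
the truth grids reproduces the recorded maximum.

## The simulated cohort

`generateCohort` draws the nested design the clustered statistics
assume, in a thickness-only mode that skips rendering so statistical
simulations run in seconds (image mode renders one phantom per record
when the full chain is wanted). Defaults mirror the validation study's
design: 25 patients × 2 eyes × 1–4 sessions (≈128 exams), ordinal
stage per eye with mix 50/65/13 over stages 1–3, and stage-conditional
mean thickness 264.2 / 334.2 / 495.0 μm (SDs 40/50/80 μm, chosen as
realistic between-eye dispersions). True thickness decomposes as

`stage mean + patient effect (SD 40 μm, shared by both eyes)
+ session fluctuation (SD 25 μm) + capture noise (SD 25 μm)`,

so inter-eye and inter-session correlation arise exactly as a
patient-clustered exchangeable GEE assumes, and repeat same-session
captures differ only by capture noise (giving ICC ≈ 0.93–0.95 and mean
CoV ≈ 7%). Two graders label each exam with continuous stage = truth +
Gaussian error, quantized to 0.1 and clipped to `[0, 3]`; ordinal
labels are the half-up rounding of each continuous label. Graders are
not described generatively in the underlying study, so this noise
model is an assumption; its SD (0.22) was calibrated once so that
simulated percent agreement matches the reported ≈87%. The model is
deliberately unbiased — it reproduces agreement and correlation levels
but **not** the lower weighted κ observed between real graders, which
reflects marginal imbalance, systematic bias and drift that the
generator does not emulate. Passing tests therefore demonstrate the
statistical machinery on data with the assumed correlation structure,
not robustness to real grader pathologies.

`generateTreatmentTrajectory` models the peri-treatment course as a
linear rise (`preSlopeUmPerWk`, 35 μm/wk) to the treatment visit at
week 0 and a linear fall after it (`postDecayUmPerWk`, 60 μm/wk), with
20 μm per-visit noise over weeks −2…+2 — a minimal rise-then-fall
shape at the scale of observed anti-VEGF responses; the slopes
themselves are package choices, not measured quantities.

# Statistical methods

**Adjudication and exclusion.** The exam's continuous stage is the
mean of the two graders' continuous labels; when ordinal labels
disagree the adjudicated stage is that mean rounded to the nearest
integer. Rounding is half-**up** (1.5 → 2); no real .5 case is
documented, so the tie-break is stated prominently rather than
silently inherited from banker's rounding. Exams with mean continuous
label **< 0.5** (strictly) are excluded — no perceptible ridge to
trace.

**Agreement.** Percent exact ordinal agreement; Cohen's weighted κ
with **linear** weights by default (quadratic behind a flag — the
choice of weights is not standardized and linear penalizes one-step
disagreements proportionally); Pearson r on continuous labels, with a
zero-variance grader reported as undefined rather than silently
dropped.

**Stage means by GEE.** `geeStageMeans` fits thickness on stage as a
no-intercept categorical design (coefficients are the per-stage
marginal means) by Gaussian GEE, identity link, **exchangeable**
working correlation, **clustered on patient**, with robust sandwich
SEs and two-sided Wald tests. A single cluster level is used even
though the data have eyes within patients and sessions within eyes:
exchangeability within patient subsumes both correlations at the cost
of assuming them equal, and with one observation per cluster the
estimator reduces exactly to OLS (verified to 1e-8). The fitter is
implemented in the package (moment estimators for dispersion and
working correlation with `N − p` / `n_pairs − p` corrections) and is
cross-checked in the suite against an external reference
implementation's frozen results on a fixed fixture. SEs are reported
as robust SEs; published tables of comparable estimates label such
uncertainties inconsistently as SD or SE, and this package does not
attempt to resolve that — its outputs are robust SEs, always.

**Spearman.** Rank correlation with average-rank ties between mean
continuous stage and thickness (two-sided, exact test disabled so tied
data are handled uniformly).

**Repeatability.** For eyes with ≥2 same-session captures: the
**one-way random-effects, single-measurement ICC** (the variant
consistent with repeated captures of the same eye by the same
pipeline; no rater structure), computed from the one-way mean squares
with the unbalanced-design average group size; and the coefficient of
variation computed **per eye** (SD/mean of that eye's repeats × 100)
then averaged across eyes. Identical repeats give exactly ICC 1 and
CoV 0. Eyes with a single capture are excluded with a warning.

**Treatment windows.** Visits are averaged across the two eyes of an
infant first, then assigned to pre `[−2, −1]`, at `(−1, +1)`, post
`[+1, +2]` weeks (closed outer intervals; the stated resolution is
whole weeks, so boundaries sit with the pre/post windows). Each window
mean is an intercept-only patient-clustered GEE with robust SE,
degrading to a simple mean with a warning when only one infant
contributes. Two-sided tests at α = 0.05 throughout; no
multiple-testing correction is applied anywhere in the battery.

# Orchestration and provenance

`runFullStudy` drives cohort → exclusion → all analyses from one
config (R list or YAML), with a seed hierarchy derived from a single
global seed so runs are byte-identical, per-analysis failure isolation
(a failing analysis is reported as `failed` without aborting the
rest), CSV/JSON outputs, and a provenance manifest
(`versionAndProvenance`: package version, seed, MD5 of the
canonicalized config). Figures are optional artifacts; every number
consumed downstream comes from the CSV/JSON, never from a plot. The
package's interface is its functions and this document; the
orchestration layer is callable from `Rscript` one-liners, so no
separate shell executable is shipped.

# Numerical choices and degenerate inputs

* Segmentation thresholds are fractions of the per-column dynamic
  range (`tissueThresholdFrac` 0.35, minimum run 4 rows, smoothing
  window 3 rows), making them invariant to intensity scaling; the
  sub-pixel refinements (50% transition point; parabolic peak) are
  unbiased under the symmetric smoothing window. Accuracy is still
  validated only at the 1-pixel level.
* A strip that is entirely featureless per column yields an
  all-invalid surface pair with a warning; a strip with no dynamic
  range at all is an error (nothing to segment).
* Trace resampling places `floor(L/s) + 1` points and snaps the last
  to the original endpoint, so endpoints and total arc length are
  exact; degenerate zero-length traces are rejected.
* The exchangeable working correlation is clamped to its
  positive-definite range; with fewer residual pairs than parameters
  it is set to 0 (independence).
* The ICC denominator uses the unbalanced-design average group size;
  a zero within-group mean square (identical repeats) short-circuits
  to ICC = 1 exactly.
* Validation problem sizes are package choices that keep the suite
  fast while leaving headroom above every tolerance: phantoms of
  340 × 48 × 48 voxels for accuracy sweeps, 50 speckled phantoms for
  segmentation robustness, 100 replicates of 100-patient cohorts for
  GEE recovery, 200-eye simulations for ICC closed forms.

# Known limitations

* No B-scan registration, no motion artifacts, no field-of-view
  dewarping, no depth-windowed projections (full depth is always
  projected); real acquisitions would need registration before
  adjacent-scan averaging.
* The phantom's ridge is a single smooth bump on a circular arc; it
  does not emulate retinoschisis, detachment, popcorn
  neovascularization, vessel shadows, or image-quality variation.
* The grader model is unbiased Gaussian noise: it reproduces agreement
  percentages but not the marginal imbalance that depresses κ between
  real graders.
* Automated segmentation is validated on phantom-rendered strips;
  real B-scans with pathology-dependent reflectivity will need the
  manual-surface input path.
* The GEE assumes a single exchangeable cluster level (patient); truly
  nested eye/session correlation structures are approximated, not
  modeled.
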