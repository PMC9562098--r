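# ridgemetry

Quantification of the fibrovascular ridge in retinopathy of prematurity
(ROP) from volumetric optical coherence tomography (OCT).

## The problem

ROP stage — the severity of abnormal vascularization at the junction
between vascularized and avascular retina — is classified ordinally
(stage 1 demarcation line, stage 2 ridge, stage 3 extraretinal
fibrovascular proliferation), yet the underlying pathology is
continuous and graders disagree in the middle of the spectrum.
Ultra-widefield OCT can see the peripheral retina of premature infants
and resolve the ridge in depth, which makes its **axial thickness** a
candidate objective biomarker of stage.

`ridgemetry` implements the full measurement and analysis chain for
this biomarker, for imaging scientists and biostatisticians working
with volumetric OCT of the infant retina:

* **Measurement.** From a volume indexed `(slow, axial, fast)`: en face
  mean/max projections and adjacent B-scan averaging to visualize the
  ridgeline; extraction of the curved B-scan strip of A-scan columns
  along a traced ridgeline (bilinear lateral interpolation at uniform
  arc-length spacing); segmentation of the retinal pigment epithelium
  (RPE) and the inner ridge surface per column; and the exam statistic

  `T_max = mean of the 10 largest values of (r_RPE − r_inner) · Δz`

  where `r_RPE`, `r_inner` are per-column axial surface rows and
  `Δz` is the axial pixel size (4.4 μm for the target device: 6 mm
  range in air / group index 1.333 ≈ 4.5 mm in tissue over 1024
  samples).

* **Statistics for clustered exams.** Grader-label adjudication
  (mean of two continuous labels; disagreements resolved by rounding),
  the <0.5 minimum-stage exclusion, percent agreement / linearly
  weighted κ / Pearson r between graders, stage-conditional thickness
  means by Gaussian GEE with exchangeable working correlation clustered
  on patient (robust sandwich SEs), Spearman stage–thickness
  correlation, test–retest repeatability (one-way random-effects ICC
  and mean per-eye coefficient of variation), and pre/at/post-treatment
  window comparisons.

* **Synthetic phantoms with ground truth.** Patient scans are not
  public, so the package ships a first-class generator: a smooth
  retina (flat RPE + inner surface) carrying a Gaussian-profile ridge
  along a circular arc at the vascular-avascular junction, rendered
  with partial-volume boundaries and multiplicative gamma speckle,
  plus nested cohorts (eyes within patients, sessions within eyes),
  noisy graders, and peri-treatment trajectories. Every phantom comes
  with analytic truth surfaces, so the whole measurement chain is
  validated against a known answer.

## Worked example

```r
library(ridgemetry)

## a synthetic volume: 200 um baseline retina + 300 um ridge
params <- phantomParams(nAxial = 340, nFast = 64, nSlow = 64,
                        ridgeHeightUm = 300, speckleSnr = 3)
ph <- generatePhantomVolume(params, seed = 7)
ph$volume
#> OCTVolume: 64 B-scans x 340 axial x 64 fast (4.40 um axial, 15.00 um lateral)
#>   metadata: seed=7, fov=105
ph$truth
#> PhantomTruth: 64 x 64 field, true max thickness 500.0 um

## measure it along the (here: ground-truth) ridgeline trace
measureExam(ph$volume, ph$truth@trueRidgeline)
#> MaxThickness: 503.1 um (SD 1.0, n=10)
```

The measured 503.1 μm is the mean of the 10 largest per-column
thickness values along the traced crest; it sits within one axial
pixel (4.4 μm) of the analytic truth of 500 μm despite speckle at
SNR 3.

```r
## a full simulated cohort and the stage analysis
rec <- generateCohort(cohortParams(seed = 7))    # 25 patients, 50 eyes
fit <- geeStageMeans(filterMinStage(rec))
#> filterMinStage: excluded 1 of 123 records below 0.50
fit
#> GEE stage means (cluster = patient_id, 25 clusters, alpha = 0.397):
#>  stage estimate_um    se_um       p_value  n
#>      1    255.2561 17.56614  7.692245e-48 43
#>      2    332.0651 15.20484 9.794830e-106 55
#>      3    489.4781 30.56642  1.027118e-57 24
```

Thickness rises monotonically with adjudicated stage, with robust SEs
that honour the two-eyes-per-patient, repeated-session clustering.
`runFullStudy(list(seed = 7, out_dir = "run"))` orchestrates the whole
battery (agreement, stage GEE, Spearman, repeatability, treatment
windows) and writes CSV/JSON outputs with a provenance manifest.

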