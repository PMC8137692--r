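# ctsarco

CT body-composition quantification and sarcopenia survival analysis in R.

## The problem

Low skeletal muscle mass (the quantitative face of sarcopenia) is a strong
prognostic factor in oncology. It is measured on the CT of routine PET/CT:
either on a single slice at the third lumbar vertebra (L3), where the
skeletal muscle index `SMI = SMA / height²` (cm²/m²) is classified against
the Prado sex-specific cut-offs (< 52.4 men, < 38.5 women), or over every
acquired slice, converting tissue voxel counts to whole-body masses.

`ctsarco` implements both measurement routes and the downstream prognostic
workflow, for methodologists and imaging scientists who need a tested,
reproducible reference implementation with ground truth attached:

* **Tissue classification** by Hounsfield-unit bands — fat −190…−30,
  skeletal muscle −29…+150 (inclusive integer bands) — inside three masks
  (body shape, abdominal cavity, muscle compartment); fat splits into
  visceral (inside the cavity) and subcutaneous (outside it).
* **L3 anthropometry**: areas averaged over two adjacent slices, SMI,
  low-muscle-mass classification.
* **Multi-slice body composition** with field-of-view extrapolation:
  `mass = N · V_voxel · ρ` (ρ = 1.06 g/ml muscle, 0.923 g/ml fat), scaled
  by factors `k_muscle`, `k_fat` — the mean whole-body/in-window voxel
  ratios over whole-body reference volumes — to estimate muscle (MBM),
  fat (FBM), lean (LBM), visceral-fat (VFM) and subcutaneous-fat (SCFM)
  body mass in kg and kg/m².
* **Synthetic ground truth**: a labeled CT phantom generator (nested
  elliptic cylinders, exact per-class masses) and a survival-cohort
  simulator with planted proportional-hazards effects.
* **Prognostic analysis**: BMI / weight-loss % / Buzby NRI, χ²-Fisher and
  t-Wilcoxon group comparisons, Kaplan–Meier + log-rank, ROC with
  Youden-optimal dichotomization (threshold emitted only when AUC > 0.5
  significantly), univariate Cox (continuous and dichotomized), and
  deterministic forward–backward stepwise Cox selection.

Volumes are read/written as NIfTI (`RNifti`) with JSON sidecars; cohorts as
CSV. A thin CLI (`inst/cli/ctsarco.R`) wraps the pipeline
(`phantom`, `cohort`, `calibrate-k`, `anthro`, `survival` subcommands).

## Worked example

```r
library(ctsarco)

vol <- generate_phantom(phantom_spec(seed = 42))   # 256 x 128 x 128 voxels
map <- classify_voxels(vol, vol$masks)
measure_l3(map, height = vol$height_m, sex = vol$sex)
#> L3 measurements (slices 140+141, mean of two):
#>   SMA  90.7 cm^2   VFA 117.3 cm^2   SCFA 123.8 cm^2
#>   SMI  29.62 cm^2/m^2 (male) -> LOW skeletal muscle mass

compute_body_composition(map, vol$masks, extrapolation_factors(1, 1),
                         vol$height_m)
#> whole-body composition estimates:
#>                  MBM   FBM    LBM   VFM  SCFM
#> mass (kg)      4.426 9.909 15.984 4.579 5.329
#> index (kg/m^2) 1.445 3.235  5.219 1.495 1.740
```

The phantom's ground truth (`vol$truth_masses`) is 4.426 kg muscle,
9.909 kg fat (4.579 visceral + 5.329 subcutaneous): the measured masses
recover it, and `FBM = VFM + SCFM` holds exactly.

A prognostic-marker analysis on a simulated cohort (400 patients, a
muscle-mass-like marker with a protective effect, 36-month follow-up):

```r
d <- simulate_cohort(cohort_spec(n = 400,
  markers = list(mbm_kgm2 = list(dist = "normal", mean = 9, sd = 1.6)),
  betas = c(mbm_kgm2 = -0.5), lambda0 = log(2) / 24 * exp(0.5 * 9),
  admin_censor_time = 36, seed = 42))

roc_optimal_threshold(d$mbm_kgm2, d$event)
#> ROC: AUC = 0.784 (one-sided p vs 0.5: 5.63e-21), 263 cases / 137 controls
#>   optimal threshold (youden, low marker adverse): 8.64; sens 0.56, spec 0.86

fit_cox(d, "mbm_kgm2", dichotomize = c(mbm_kgm2 = 8.64))
#> Cox fit (Breslow ties): n = 400, events = 263, dropped = 0
#>      term coef   HR lower95 upper95        p
#>  mbm_kgm2 1.21 3.35    2.61    4.29 2.11e-21
```

Patients below the data-driven 8.64 kg/m² threshold (coded 1) die at 3.4
times the hazard of the others; the log-rank test on the same split gives
χ² = 100.3.

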