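# perfquant

Quantitative analysis of first-pass myocardial perfusion imaging in R.

Stress perfusion cardiovascular MR estimates myocardial blood flow (MBF,
mL/min/g) from the transit of a contrast bolus: an arterial input function
(AIF) sampled in the blood pool and dynamic tissue curves sampled in the
myocardium, once per heart beat, at hyperemia and at rest. `perfquant`
implements the full quantitative chain for studies built on such data — for
example, comparing perfusion between patients in atrial fibrillation and
sinus rhythm:

* **Kinetics** — Fermi-constrained deconvolution. The tissue curve is
  modelled as the AIF convolved with a Fermi impulse response
  `h(t) = A / (1 + exp[(t − t_d − w) k])` (t ≥ t_d), and blood flow is the
  initial height of the response: `MBF = 60 · h(t_d) = 60A / (1 + e^{−wk})`.
  `fermi_fit()` estimates `(A, k, w, t_d)` by bounded multi-start nonlinear
  least squares and returns a classed fit with `print`, `summary`, `coef`,
  `predict`, `residuals`, `plot` and `simulate` methods; `map_mbf()` fits
  every pixel of a masked slice into an MBF map.
* **Sampling** — contoured maps are resampled on the standard transmural
  polar grid: 60 spokes × 10 layers = 600 points per slice (1800 per
  three-slice study), labelled with AHA 17-segment ids (apical cap absent),
  and aggregated to global, endocardial (inner half), epicardial (outer
  half) and per-segment means, plus endo/epi ratios.
* **Hemodynamics** — MAP = DBP + (SBP − DBP)/3, RPP = HR × SBP,
  MPR = stress MBF / rest MBF, CVR = MAP / MBF, vasodilator adequacy
  (HR increase ≥ 10 bpm or splenic switch-off), age categories, and
  eligibility/subgroup rules for cohort tables.
* **Statistics** — median [IQR] summaries, Mann–Whitney U, Wilcoxon
  signed-rank, Kruskal–Wallis, Pearson/point-biserial correlation, and OLS
  with standardized coefficients, assembled by `run_cohort_analyses()` into
  the standard baseline / hemodynamics / perfusion / subgroup / transmural /
  regression report.
* **Synthetic data** — `phantom_slice()` generates annular perfusion
  phantoms (gamma-variate AIF, Fermi forward model, configurable transmural
  profile, Gaussian noise, sinus or AF beat-gated timing) with known ground
  truth, and `make_cohort()` draws two-group cohorts calibrated to published
  group medians/IQRs, so the whole pipeline is testable without patient
  data.
* **I/O + CLI** — curves as CSV, maps as NIfTI (plain-text fallback),
  contours as JSON, cohorts as CSV, per-patient study bundles, and a
  `perfquant` command-line wrapper (`inst/cli/perfquant`) with
  `simulate` / `quantify` / `sample` / `cohort` / `pipeline` subcommands.

## Worked example

Simulate a graded phantom (endocardial 1.5 → epicardial 2.5 mL/min/g),
quantify it pixelwise, and sample the map on the polar grid:

```r
library(perfquant)

times <- seq(0, 60, by = 1)                    # beat-gated frames, 1 s apart
aif   <- make_aif(aif_model(), times)
fit   <- fermi_fit(times, aif, tissue_curve(aif, times, true_mbf = 2))
fit
#> Fermi-constrained deconvolution fit
#>   MBF: 2.000 mL/min/g
#>   params: A = 0.04077, k = 0.5 1/s, w = 3 s, td = 0 s
#>   first-pass window: frames 1-36 of 61, RSS = 2.835e-32

geom <- phantom_geometry(grid_size = 64, endo_radius = 10, epi_radius = 15)
ph   <- phantom_slice(geom, function(d) 1.5 + d, aif, times)
map  <- map_mbf(times, aif, ph$curves, ph$truth$mask)
grid <- sample_map(map, build_sampling_grid(ph$contours))
aggregate_grids(list(grid))
#> Perfusion summary (stress), 600 points
#>   global 2.010 | endo 1.806 | epi 2.213 mL/min/g | endo/epi 0.816
```

The recovered global flow matches the phantom's mean (the profile averages
to 2.0 across the wall) and the endo/epi ratio below 1 reflects the imposed
subendocardial hypoperfusion. A synthetic two-group cohort reproduces the
expected group contrast:

```r
co  <- make_cohort(cohort_spec(), seed = 1)     # 379 sinus / 63 AF
rep <- run_cohort_analyses(apply_eligibility(co)$analyzed)
rep$perfusion
#>                       variable                sinus                    af        p
#> 1        Stress MBF (mL/min/g)     2.40 [1.99-2.85]      1.81 [1.55-2.18] 2.70e-12
#> 2          Rest MBF (mL/min/g)     0.98 [0.80-1.16]      0.88 [0.74-1.07] 2.37e-02
#> 3                          MPR     2.44 [2.09-2.84]      2.03 [1.74-2.41] 1.56e-06
#> 4 Stress CVR (mmHg/(mL/min/g))  38.47 [31.30-47.09]   52.95 [43.76-67.23] 2.03e-14
#> 5   Rest CVR (mmHg/(mL/min/g)) 94.75 [77.02-116.47] 113.00 [97.77-133.41] 8.80e-05
```

Hyperemic MBF and MPR are markedly lower in the AF group while the rest
difference is small — the contrast the generator is calibrated to.

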