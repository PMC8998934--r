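# t2flux

Quantitative follow-up of orthotopic brain-tumor xenografts combines two
modalities: multi-slice multi-echo (MSME) MRI, from which pixel-wise T2
relaxation times and tumor volumes are derived, and bioluminescence imaging
(BLI), whose total flux tracks viable, luciferase-expressing tumor burden.
t2flux is an R package for the analysis chain that connects them, aimed at
preclinical imaging groups who want the computations — not the scanners —
to be reproducible and testable:

* **T2 relaxometry** — per-pixel nonlinear least-squares fits of the decay
  `S(TE) = S0 · exp(−TE/T2)` over a 10-echo train, producing T2 maps
  (tumor ≈ 68 ms vs healthy brain ≈ 47 ms, CSF ≈ 125 ms) and noise-reduced
  T2-average contrast images;
* **tumor volumetry** — per-ROI banded thresholding, largest 8-connected
  component, pixel counts × voxel volume (0.0048828125 mm³ for the default
  20 × 20 mm / 256 × 256 / 0.8 mm geometry);
* **method comparison** — Bland-Altman limits of agreement and paired
  t-test between the two contrast methods;
* **photometry** — background-subtracted, best-of-three-exposure,
  week-1-normalized total flux series;
* **cross-modality calibration** — the power law `flux = a · V^b` fitted as
  OLS on decadic logs (default coefficients
  `log10(flux) = 5.81 + 1.04 · log10(V)`), with R², Spearman ρ and
  absolute/relative residuals;
* **survival analysis** — Kaplan-Meier curves, first-crossing medians,
  log-rank and Mann-Whitney tests, percent median-survival enhancement.

A digital-phantom generator renders synthetic multi-echo cohorts, flux
tables and survival cohorts with known ground truth, so the whole pipeline
runs and is tested without any animal data.

## Worked example

```r
library(t2flux)

# a mid-study imaging session of the digital phantom (1% intensity noise)
spec  <- phantom_spec(matrix_size = c(64, 64), n_slices = 6, noise_sd = 1)
lab   <- build_label_map(spec, session_week = 5)
stack <- render_echo_stack(lab, spec, seed = 42)
lab
#> Tissue label map, week 5: background=16240, brain=7308, csf=952, tumor=76
#>   ground-truth tumor volume 5.9375 mm3 (voxel 0.0781250000 mm3)

# relaxometry: the T2 median is brain-dominated, as most defined pixels are brain
compute_t2_map(stack)
#> T2 map: 64 x 64 x 6 slices; 8336/24576 pixels defined
#>   T2 median 47.2 ms (IQR 46.5-48.0); display clamp 120 ms

# volumetry from the T2-average contrast recovers the ground truth exactly
avg   <- compute_t2_average(stack)
bands <- default_bands(spec)
vox   <- voxel_volume(20, 20, 64, 64, 0.8)
measure_image_volume(avg$pixels,
                     auto_tumor_rois(avg$pixels, bands$t2_average[1],
                                     bands$t2_average[2]),
                     vox, method = "t2_average")
#> Tumor volume: 5.9375 mm3 (76 pixels x 0.0781250000 mm3/voxel) [t2_average]

# flux-volume calibration across weeks 1-8 of the growth curve
v <- tumor_volume_at_week(spec, 1:8)
loglog_fit(v, simulate_flux(v, seed = 7))
#> Flux-volume calibration (n = 8): log10(flux) = 5.81 + 1.02 * log10(V)
#>   power law: flux = 6.51e+05 * V^1.02 p/s
#>   R^2 = 0.993 (F-test p = 1.14e-07); Spearman rho = 1.000 (p = 0)

# survival arm: 8 animals per group, medians 44 vs 66 days
tab <- simulate_survival_cohort(c(sham = 44, treated = 66),
                                n_per_group = 8, seed = 7)
survival_report(tab, "sham")$tests
#>     group n km_median logrank_chisq logrank_p mw_U      mw_p pct_enhancement
#> 1 treated 8  50.77682     0.1057456 0.7450407   44 0.2344988              29
```

The fitted slope (1.02) scatters around the generating exponent 1.04
because the simulated fluxes carry log-normal residuals; at 8 animals per
group the survival tests are, as expected, far from significant even for a
true 50% median benefit.

`run_pipeline()` (or the thin CLI in `inst/cli/t2flux.R`) chains every
stage — phantom → NIfTI stacks → T2 maps/averages → volumes → Bland-Altman
→ flux processing → calibration → survival report — from a single YAML
config, writing CSV/JSON outputs plus a checksummed, seed-reproducible run
report.

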