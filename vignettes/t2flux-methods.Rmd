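---
title: "Quantitative T2 relaxometry, tumor volumetry and flux calibration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2 relaxometry, tumor volumetry and flux calibration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2flux)
```

# What the package computes

t2flux implements the quantitative chain used to follow orthotopic
brain-tumor xenografts longitudinally with two modalities:

1. **T2 relaxometry.** A multi-slice multi-echo (MSME) spin-echo
   acquisition samples the transverse-magnetization decay of every pixel at
   a train of echo times TE. The signal follows the mono-exponential model

   $$S(TE) = S_0 \, e^{-TE/T_2},$$

   and fitting $(S_0, T_2)$ per pixel produces a *T2 map* — an image whose
   values are relaxation times in ms rather than scanner intensities.
   Free-water-rich tissue relaxes slowly, so tumor (T2 around 68 ms) stands
   out against healthy brain (around 47 ms), with cerebrospinal fluid far
   above both (around 125 ms). A complementary *T2-average* contrast image
   is formed by pixel-wise averaging of three mid-train echoes
   (45.8, 62.5, 79.2 ms), trading quantification for lower noise.

2. **Volumetry.** Tumor cross-sections are segmented slice by slice:
   rectangular regions of interest, an intensity band (closed on both
   ends), 8-connected component labeling, and retention of the largest
   component per ROI. Pixel counts are summed over ROIs and slices and
   multiplied by the voxel volume. With the default geometry
   (20 × 20 mm field of view, 256 × 256 matrix, 0.8 mm slices) the voxel
   volume is $\left(\tfrac{20}{256}\right)^2 \times 0.8 = 0.0048828125$
   mm³ — often quoted truncated as 0.0048 mm³/voxel. All internal
   arithmetic uses the full-precision value; `format_voxel_volume()`
   reproduces the truncated print style. Which of the two a given
   historical analysis used is generally not recoverable from a printed
   constant, so both paths are exposed.

3. **Method agreement.** Volumes from the two contrasts are compared by
   Bland-Altman analysis (differences against pair means, reference lines
   at mean ± 1.96 × sample SD) and a paired t-test with $n-1$ degrees of
   freedom. The SD divisor is $n-1$; no normality pre-test is run (for the
   cohort sizes involved the t-test relies on the central limit theorem).
   Pairing is per imaging session, not per slice.

4. **Photometry.** Bioluminescence total flux (photons/s) is processed per
   timepoint as: net flux = ROI flux − caudal background flux (clamped
   below at 1 p/s with a warning, so logs stay defined); the best of the up
   to three exposures (60 s, 30 s, auto) is kept, total flux being
   exposure-normalized; each animal's series is normalized to its week-1
   value. A missing week 1 is an error, never a silent re-baselining.

5. **Calibration.** Flux and volume are related by the power law
   $y = a\,x^{b}$, fitted as ordinary least squares on the decadic-log
   scale: $\log_{10} y = \log_{10} a + b \log_{10} x$. The package reports
   the fit, $R^2$, an overall-fit F-test p (for one predictor this equals
   the slope t-test), Spearman's ρ with midranks, and absolute
   (observed − expected) and relative (absolute/observed) residuals of the
   back-transformed predictions.

6. **Survival.** Time from tumor-cell injection to endpoint is summarized
   by the Kaplan-Meier product-limit estimator; the median is the first
   time the estimated survival fraction reaches 0.5 or below ("half the
   animals still alive"), including at an exact 0.5 plateau. Groups are
   compared by the two-group log-rank test and by a two-sided Mann-Whitney
   test on the recorded days; treatment effect is reported as percent
   enhancement of the median, rounded to the nearest integer with halves
   away from zero. Long-term survivors euthanized symptom-free at study
   end are encoded as censored at that day.

# The digital phantom

No animal data ship with the package; every downstream stage is exercised
on a synthetic cohort with known ground truth.

* **Geometry.** Defaults mirror the MSME protocol above; tests and examples
  shrink the in-plane matrix (32–64 pixels) while keeping the anisotropic
  voxel (thick slices), which is what makes volumetric discretization
  non-trivial.
* **Anatomy.** A centered brain ellipsoid, two lateral-ventricle CSF
  regions, and one tumor blob. The tumor is *not* rasterized from an
  analytic ellipsoid: with 0.8 mm slices, counting voxel centers inside a
  sub-millimeter sphere can miss the requested volume by several voxels.
  Instead the blob takes exactly `round(V/voxel_volume)` brain voxels
  nearest a posterior seed point, so the recorded ground truth is within
  half a voxel of the growth model's request and is exactly
  count × voxel volume. A request exceeding the available brain volume is
  an error naming the week and both volumes.
* **Growth.** $V(w) = V_0 e^{k(w-1)}$ with $V_0 = 0.5$ mm³ and
  $k = \ln(38/0.5)/7 \approx 0.619$ per week, anchoring week 8 at 38 mm³ —
  the scale of maximal tumor burden in this model system.
* **Signal.** Forward evaluation of the decay model per tissue class plus
  additive Gaussian noise (a high-SNR approximation to Rician magnitude
  noise; the approximation degrades below roughly SNR 3, which only
  affects air).
* **Flux.** $\log_{10}(\text{flux})$ is linear in $\log_{10}(V)$ with
  intercept 5.81 and slope 1.04 by default and Gaussian log-residuals.
  The implied week-1 baseline (about $9 \times 10^4$ p/s at 0.5 mm³,
  consistent with a week-8 relative flux of 245 at
  $2.2 \times 10^7$ p/s absolute) is a default, not ground truth.
* **Survival.** Times are log-logistic — heavy right tail resembling
  occasional long-term survivors — sampled via the exact identity
  $T = \exp(L)$, $L \sim \text{Logistic}(\log m, 1/\beta)$, whose median
  is the requested $m$ for any shape $\beta$. The default $\beta = 6$ puts
  the sample-median standard error near $2m/(\beta\sqrt{n})$, a realistic
  spread for cohorts of 6–10 animals. Any distribution with a controllable
  median would serve; the choice is a documented convention.
* **Determinism.** Every stochastic operation takes an integer seed and
  restores the caller's RNG state; identical seeds give bit-identical
  stacks, tables and pipeline outputs (checksummed in the run report).

What the phantom deliberately omits: partial-volume effects, B1/coil
inhomogeneity, motion, k-space artifacts, luciferin pharmacokinetics, and
ventricle infiltration by tumor. Passing recovery tests on the phantom
therefore demonstrates the correctness of the *computations*, not the
field performance of segmentation on real, textured tumors — where ROI
placement and threshold choice remain analyst decisions.

# Numerical choices

* **Decay fitting.** Derivative-free Nelder-Mead simplex minimization of
  the SSE (mirroring an unconstrained `fminsearch`-style search), with a
  relative SSE tolerance of 1e-10 and a 10,000-iteration cap per pixel.
  Initialization is the log-linear regression of $\log S$ on TE over
  positive intensities, which is already exact on noiseless data. A fitted
  T2 outside the validity window (0, 2000] ms, a non-positive amplitude,
  or a degenerate input (all non-positive, or non-decaying/constant — T2
  unbounded) yields an explicit undefined flag, never an exception and
  never a silent zero. Unconstrained SSE minimization can drift to
  negative T2 on very noisy pixels; the window plus flag policy converts
  those to undefined rather than reporting them.
* **Noise floor.** Pixels are fitted only if their maximum echo intensity
  exceeds 3 × the median maximum-across-echoes intensity of the corner
  patches of the image (assumed air). Using the typical background pixel's
  *max-over-echoes* — rather than a per-echo noise SD — keeps the
  false-positive rate across a whole volume near zero, which matters
  because a single spurious in-band fit on a tumor-free slice would
  otherwise be counted as a (false) largest component.
* **Averaging subset.** TE matching for the T2-average subset is exact to
  1e-6 ms; a missing TE is an error listing the available train.
* **Segmentation.** The threshold band is closed on both ends; 8-connected
  labeling is in-plane only (no 3-D linking across slices, matching the
  slice-wise procedure); ties for largest component break by smallest
  centroid distance to the box center, then lowest label — fully
  deterministic. Boxes are 0-based, (row, col), half-open. Overlapping
  ROIs on a slice are unioned with a warning, so no pixel counts twice.
* **Auto-ROI.** Interactive ROI placement is replaced by a declarative
  rule (`auto_tumor_rois()`): one ROI per slice containing in-band pixels,
  its box the padded bounding box of the in-band region. Default bands
  bracket the tumor class midway toward brain (below) and CSF (above) in
  the relevant contrast units.
* **Statistics.** Mann-Whitney p is exact by enumeration for combined
  n ≤ 20 without ties, otherwise a tie-corrected normal approximation
  without continuity correction; censoring is ignored by this test (a
  documented limitation of comparing raw days). The log-rank test is the
  standard 1-df two-group statistic. Both KM and sample medians of event
  times are computed; the KM median is primary.

# Problem sizes

Package tests run phantoms of 32–64 pixels in-plane with 4–8 slices —
large enough that brain, ventricles and a growing tumor coexist and
segmentation faces real discretization, small enough that the whole suite
fits in about a minute. Statistical property checks (limit coverage,
median convergence) use n = 10,000 draws; calibration recovery uses 20
seeded cohorts of n = 74 flux-volume pairs spanning weeks 1–8 with
log-residual SD 0.05.

# Known limitations

* Single-compartment T2 only; no multi-exponential or partial-volume
  modeling.
* Volumetry has no automatic tumor detection and no
  ventricle/hydrocephalus exclusion logic; those remain analyst choices
  expressed through ROI files.
* The Bland-Altman analysis fits no proportional-bias regression.
* The calibration pools all sessions (no per-animal random effects) and
  the survival analysis applies no multiplicity correction across arms.
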