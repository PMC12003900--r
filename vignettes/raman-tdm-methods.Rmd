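---
title: "Methods: chemometric pipeline for Raman-based drug monitoring in urine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric pipeline for Raman-based drug monitoring in urine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramantdm)
```

# Scope

`ramantdm` implements the data-analysis side of deep-UV resonance Raman
therapeutic drug monitoring (TDM) of piperacillin in human urine: spectral
conditioning, PLS calibration, a closed-form estimator of the concentration
loss caused by clinical sample preparation (freezing, filtration,
centrifugation), univariate marker-band quantification with ICH detection
limits against alternative urine reference matrices, and donor-sex
classification. A seeded synthetic spectrum generator supplies test data
with the statistical structure the analysis assumes; everything in the
package is exercised end to end on that generator.

# The spectral conditioning chain

Raw spectra pass through, in order:

1. **Wavenumber calibration** (`fit_wavenumber_calibration()`,
   `apply_calibration()`): a least-squares polynomial mapping measured peak
   positions of standards (acetonitrile, Teflon, toluene) to reference
   positions, followed by linear resampling. The synthetic generator emits
   calibrated axes, so the pipeline runs this step as the identity; the
   functions are tested standalone.
2. **Truncation** to the 800–1800 cm⁻¹ region of interest
   (`truncate_spectra()`, closed interval).
3. **Savitzky–Golay smoothing** with polynomial degree 2 in a 5-point
   window (`savgol_smooth()`, via `signal::sgolayfilt`). Edges are handled
   by evaluating the terminal-window polynomial fits, so any quadratic
   passes through unchanged, edges included. For white noise the interior
   variance shrinks by the sum of squared filter weights,
   595/1225 ≈ 0.486.
4. **EMSC scatter correction** (`emsc_correct()`, degree 6): each spectrum
   is decomposed by least squares as
   `x = b·reference + Σ a_k P_k + e`, with `P_k` orthogonal polynomials of
   degree 0–6 on the axis rescaled to [−1, 1], and corrected as
   `(x − Σ a_k P_k)/b`. Dividing by `b` (the standard EMSC convention) makes
   the output invariant to per-spectrum affine distortion; contamination
   inside the polynomial span is removed exactly. The default reference is
   the channel-wise median of each sample's replicates — correction
   relative to the sample's own median — with a `reference` argument to
   override with a common spectrum, since the grand-median variant is also
   defensible.
5. **SNIP baseline removal** (`snip_baseline()`, 20 iterations): iterative
   peak clipping with the log-log-square-root compression transform.
   `order` follows the filter-order naming of the classic implementations,
   where **2 denotes the plain two-point neighbour average** (the default
   here) and 4 the four-point filter. The two conventions differ
   materially: on a σ = 8 cm⁻¹ Gaussian the two-point filter retains
   ≈ 99% of the band height after 20 iterations, while the four-point
   filter cuts it to ≈ 59% because its inner-neighbour term tracks band
   curvature. Since the analysis depends on quantitative band amplitudes,
   the band-preserving reading is the default and the other is available
   for sensitivity analysis.
6. **Task-specific truncation and normalization**: 1150–1750 cm⁻¹ plus
   vector normalization for PLS; maxima normalization at the ~1605 cm⁻¹
   urea C=O band (window ± 15 cm⁻¹) for difference-spectrum
   quantification; vector normalization for classification.

All steps are pure functions of their inputs and parameters.

# PLS calibration and component selection

`fit_pls()` is PLS1 by NIPALS with X-deflation; X is column-centered and y
standardized internally, predictions return in µM. At full rank the fit
coincides with ordinary least squares (tested against a normal-equation
oracle). `select_ncomp()` compares 3–5 components by repeated
cross-validation. Because the calibration series has far fewer samples
than 50, "50-fold cross-validation" is implemented as 50 repeated random
splits holding out 20% of the *sample groups*: replicate spectra of one
physical sample never straddle a split, and the extreme concentration
levels always stay in training so every model spans the calibration range.
Ties go to the smaller component count. All splits are seed-controlled.

# The treatment correction factor

The concentration loss `f` of a preparation step is defined as the value
minimizing the RMSEP between set concentrations and rescaled predictions
`c_pred/(1−f)`. Substituting `s = 1/(1−f)` turns this into a
through-origin regression with the closed-form optimum
`s* = Σ c_set·c_pred / Σ c_pred²`, so `estimate_factor()` computes
`f = 1 − 1/s*` directly; a brute-force grid minimizer exists in the test
suite as an independent oracle. `factor_cv()` repeats the estimate on 10
random 80% subsets and reports the median and the raw median absolute
deviation (MAD with scale constant 1, matching the few-hundredths-of-a-
percent dispersions this estimator shows). RMSEP before/after correction is
evaluated on the full data. Sequential treatments compose multiplicatively,
`1 − f_total = (1 − f₁)(1 − f₂)`; at few-percent magnitudes this is
numerically indistinguishable from addition (0.0236 and 0.0280 compose to
0.0509).

# Marker-band quantification and detection limits

For the reference-matrix study, per-sample median spectra are maxima
normalized, differenced against a reference urine median
(`difference_spectrum()`, which *enforces* that both inputs are normalized
— the apex in the 1605 ± 15 window must be 1 within 1e-9), and the
piperacillin marker at ~1485 cm⁻¹ is fitted with a Gaussian plus constant
offset (`fit_marker_band()`, window ± 30 cm⁻¹, center bounded to the
window, σ ∈ [1, 30]). The offset absorbs residual baseline; the ± 30
window excludes the creatinine 1525 band. Fits start at the nominal marker
position over a deterministic grid of start widths — starting at the
in-window argmax is kept only as a fallback, because under strong matrix
mismatch the argmax can sit on a residual shoulder and pull the optimizer
into a spurious optimum. Non-convergence is flagged, never silent.

`build_calibration()` regresses amplitude on concentration by OLS;
`σ_n` is the classical intercept standard error and the ICH limits are
`LoD = 3.3 σ_n/m`, `LoQ = 10 σ_n/m`, so `LoQ/LoD = 10/3.3` identically.
Percent deviation of a pool reference is `100·(LoD_pool − LoD_own)/
LoD_pool`. Two molar masses are in play for mg/L conversion: the sodium
salt (539.5 g/mol, default, consistent with published LoD tables) and the
free acid (517.55 g/mol, used for clinical-range figures); both are
exposed rather than silently picking one.

# Classification

Vector-normalized spectra are reduced by centered PCA (`pca_reduce()`,
deterministic sign convention; 5 components by default, or the smallest
number covering 95% variance), then classified by LDA (`MASS::lda`), a
linear SVM (cost 1000) or a radial SVM (cost 10 000, γ = 1), all via
`e1071::svm` with its default feature standardization. Decision scores —
the LD1 projection for LDA, the signed margin for SVM, both oriented so
the positive (female) class scores high — feed a threshold-averaged ROC:
each of 20 repeated donor-grouped 80/20 splits is evaluated at the pooled
union of decision thresholds, (FPR, TPR) points are averaged across
repeats per threshold, and the AUC is computed per repeat by the trapezoid
rule and summarized as mean ± sd. Donor grouping prevents replicate
leakage; 20 "folds" on 17 donors necessarily means repeated splits, not
disjoint folds. `discriminant_weighting()` maps LDA coefficients back
through the PCA loadings to wavenumber space and reports the extrema of
the absolute weights above their 90th percentile, attributing the
discrimination to chemical bands.

# The synthetic generator

`synth_config()` fixes every generative choice; all randomness flows
through named substreams of one master seed, so regeneration is
bit-reproducible.

**Forward model.** A spectrum is a sum of concentration-weighted Gaussian
bands (σ = 8 cm⁻¹) for urea, creatinine, uric acid and two minor
sex-neutral components, plus piperacillin bands (marker 1485 cm⁻¹) whose
amplitude is exactly linear in concentration (2 × 10⁻⁴ a.u./µM), a smooth
baseline (linear tilt plus a broad fluorescence-like hump), per-spectrum
affine scatter distortion (gain sd 0.10, offset sd 0.02) and additive
white noise (sd 0.001 a.u.). The grid is 600–1900 cm⁻¹ at 1 cm⁻¹, so
truncation to 800–1800 is a real operation. The field publishes no
absolute urine band intensities, so the composition means are
order-of-magnitude choices, exposed in the config rather than claimed as
measurements.

**Measurement regime.** The noise and drug-response defaults deserve a
note. The loss-factor study compares a model's predictions *between*
calibration nodes, so any concentration-nonlinearity of the processed
spectra (vector normalization is mildly nonlinear in composition, and
SNIP's clipping interacts with noise) bends the calibration manifold and
biases the recovered factor. The defaults put the experiment in the
high-signal-to-noise, near-linear regime that deep-UV resonance Raman
with 60 s integration can reach — marker amplitude at 100 µM is ≈ 20
noise standard deviations — where the estimator's dispersion
(MAD ≈ 0.05–0.15 percentage points) matches what the method reports and
recovery is unbiased to within ≈ 0.2 points. At five times the noise the
estimator acquires a systematic ≈ −0.5-point bias; that regime is
reachable through the config for robustness studies but is not the
default condition.

**Treatment model.** Treatment scales the effective spiked concentration
by (1 − f) and nothing else — exactly the assumption of the correction
statistic. Default factors are the published freezing (8.42%), filtration
(2.36%), centrifugation (2.80%) and combined (5.05%) losses, which the
pipeline is expected to recover.

**Donors and pools.** Plain donors draw each component from a log-normal
with sex-specific mean and 15% CV; pools average donor compositions
component-wise (equal-volume mixing).

**The classification cohort** realizes sex differences through
composition means *and* a nonlinear geometry: in the plane of the
creatinine/urea and uric-acid/urea intensity ratios, female donors occupy
a bounded ring (radius 0.95–1.05 in latent units, linear offsets about
the cross-sex mean composition at scale 0.35) and male donors its
complement — a central core (≈ 55% of males) plus an outer shell
(radius 1.8–2.0) clustered in one angular sector. No linear boundary
separates the classes, a radial one does. Several choices here are forced
by how the classifier stack behaves under donor-grouped cross-validation
with the SVM's internal feature standardization:

* every principal component fed to the classifier must carry *consistent*
  donor-level structure — any dimension dominated by independent
  per-donor draws or replicate noise is inflated to unit scale by the
  standardization and destroys the radial kernel's locality at γ = 1;
  the minor components therefore co-vary with the squared ring radius
  rather than varying independently;
* only **one** independent radial coordinate may be exposed: adding a
  second (e.g. both r and r²) hands linear classifiers a polynomial
  feature basis in which the middle ring *is* linearly separable — the
  classical polynomial-kernel effect in disguise;
* the outer-shell males cluster in one sector and replicates drift
  tangentially along the ring (θ jitter sd 0.55 rad), so no donor is ever
  isolated from its own class in a training split — an isolated donor is
  memorized locally by the SVM and falls back to an uncontrolled decision
  baseline when held out;
* urea varies little in this cohort (CV 2%, common mean, 2.5% sex gap),
  giving linear classifiers partial — not perfect — separation, the
  pattern the real study shows.

**What the generator does not emulate:** absolute photon counts and
detector response, cosmic-ray spikes, photodegradation, the dozens of
further urine metabolites, pH- or concentration-dependent band shifts,
and any matrix effect of treatment beyond concentration scaling. Passing
tests therefore demonstrate the *statistical machinery* — they do not
certify performance on clinical spectra, whose matrix variability is
richer than five components.

# Numerical choices and degenerate inputs

* Wavenumber axes compare as identical at relative tolerance 1e-9;
  readers sort channels and never clip negative intensities.
* Channel-wise medians of an even replicate count average the central
  pair.
* EMSC aborts when the reference coefficient falls below 1e-8 or the
  reference is constant; normalization aborts on zero norm or a
  non-positive window maximum; `estimate_factor()` aborts when
  predictions anti-correlate with set values (`s* ≤ 0`).
* An all-zero difference spectrum yields amplitude 0 with a low-signal
  flag, not an error.
* PLS component selection breaks ties toward fewer components; the CV
  split generator excludes the extreme concentration groups from holdout.
* Classification CV re-draws donors per class, so every training
  partition contains both classes by construction.

# Problem sizes

The default experiments are sized to run comfortably on one CPU: the
loss-factor study uses 8 concentration levels × 3 replicates per series
(48 spectra per treatment, ~1000 channels), component selection uses 50
repeated splits, and the cohort is 17 donors × 20 spectra with 20 CV
repeats. A full four-treatment factor study runs in a few seconds; the
classification experiment in under ten.

# Worked example

```{r example, eval = FALSE}
config <- synth_config(seed = 1)
factors <- run_factor_experiment(config, treatments = c("froz", "filt"))
factors
#> treatment, factor_pct, factor_mad_pct, rmsep_before_uM, rmsep_after_uM ...

cohort <- run_classification_experiment(config)
cohort$summary
autoplot(cohort$roc$svm_radial)
```

# Known limitations

* The correction-factor estimator inherits a small negative bias from any
  concentration-nonlinearity of the processed spectra; at the default
  regime this is ≲ 0.2 percentage points but it grows with noise.
* The threshold-averaged ROC follows the standard vertical-averaging
  construction; other averaging conventions (e.g. ROC convex hulls) give
  slightly different dispersion bands.
* `read_spectra()` supports the two documented text dialects only; vendor
  binary formats are out of scope.
* The LoD comparison across reference matrices is a *directional*
  statement under the generator's conditions; absolute LoD values depend
  on the (unpublished) absolute intensity scale and are not comparable to
  clinical numbers.
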