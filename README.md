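# ramantdm

Chemometrics for therapeutic drug monitoring (TDM) of the β-lactam
antibiotic piperacillin in human urine by deep-UV resonance Raman
spectroscopy.

Clinical urine samples are routinely frozen, centrifuged and/or filtered
before analysis, and each of those steps removes a few percent of the
drug. Quantification also depends on which urine is used as the
spectroscopic reference matrix: the patient's own urine, a sex-specific
pool, or a mixed pool. This package implements the full analysis chain
needed to measure both effects, for spectroscopists and chemometricians
working on Raman-based TDM:

* **Spectral conditioning** — wavenumber calibration, truncation
  (800–1800 cm⁻¹), Savitzky–Golay smoothing (p = 2, n = 5), extended
  multiplicative signal correction (EMSC, degree 6, per-sample median
  reference), SNIP baseline removal (20 iterations), vector and maxima
  normalization.
* **PLS calibration** — NIPALS PLS1 with 3–5 components chosen by 50
  repeated cross-validation splits (replicates grouped, range-spanning).
* **Treatment correction factor** — the loss `f` of a preparation step is
  the minimizer of

  ```
  argmin_f sqrt( 1/n · Σᵢ ( c_set,i − c_pred,i / (1 − f) )² )
  ```

  solved in closed form (`f = 1 − Σc_pred²/Σc_set·c_pred`), with a
  cross-validated median ± MAD over 10 random 80% subsets.
* **Marker-band quantification** — difference spectra against a
  maxima-normalized reference urine, Gaussian fit of the piperacillin
  marker at ~1485 cm⁻¹, OLS calibration curves and ICH detection limits
  `LoD = 3.3·σₙ/m`, `LoQ = 10·σₙ/m`.
* **Donor-sex classification** — PCA (5 PCs), LDA and linear/radial SVMs
  (cost 1000 / cost 10 000, γ = 1), 20 repeated donor-grouped splits,
  threshold-averaged ROC curves, and discriminant weighting vectors
  mapped back to wavenumber space.
* **A seeded synthetic urine-spectrum generator** (`synth_config()` and
  friends) that emulates the statistical structure these analyses assume,
  so every pipeline is exercisable and tested end to end without
  instrument data.

## Worked example

```r
library(ramantdm)

config <- synth_config(seed = 1)

# How much drug does freezing remove? The generator spikes a calibration
# series before/after a simulated treatment; the pipeline preprocesses,
# fits PLS on the untreated references and recovers the loss factor.
run_factor_experiment(config, treatments = c("froz", "filt"))
#> # A tibble: 2 x 8
#>   treatment      f factor_pct factor_mad_pct rmsep_before_uM rmsep_after_uM     n n_components
#> 1 froz      0.0833       8.33         0.0245            84.3           2.92    24            5
#> 2 filt      0.0242       2.42         0.0111            24.5           2.48    24            5
```

The freezing row reads: predictions of the treated series fall 8.33%
below the set concentrations (the generator's ground truth is 8.42%),
with a cross-validation dispersion of 0.02 percentage points; rescaling
by 1/(1 − f) drops the prediction error from ≈ 84 µM to ≈ 3 µM over the
0–2000 µM series.

```r
# Does the choice of urine reference matter for detection limits?
run_reference_experiment(config)[, c("reference", "lod_uM", "loq_uM", "deviation_pct")]
#> # A tibble: 4 x 4
#>   reference   lod_uM loq_uM deviation_pct
#> 1 own            8.44   25.6          0
#> 2 pool_female   11.2    33.9         24.5
#> 3 pool_male    195.    592.          95.7
#> 4 pool_mixed   117.    355.          92.8

# Can donor sex be read off a urine spectrum?
cls <- run_classification_experiment(config)
cls$summary
#> # A tibble: 3 x 3
#>   classifier auc_mean auc_sd
#> 1 lda           0.825 0.149
#> 2 svm_linear    0.859 0.126
#> 3 svm_radial    0.994 0.0187
autoplot(cls$roc$svm_radial)
```

The LoD table shows the qualitative pattern that matters in practice:
the patient's own urine gives the lowest detection limit, a sex-matched
pool is the best substitute, and a compositionally distant (male) pool is
the worst. The classification table shows the sex structure is nonlinear:
only the radial-kernel SVM separates the classes, the linear classifiers
do not.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; see the methods vignette
(`vignettes/raman-tdm-methods.Rmd`) for the models, their assumptions and
the generator's design.

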