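#' Closed-form treatment correction factor
#'
#' The concentration loss caused by a sample-preparation step is the
#' factor `f` minimizing `sqrt(1/n * sum((c_set - c_pred/(1-f))^2))`.
#' Substituting `s = 1/(1-f)` makes the objective a through-origin
#' least-squares problem with optimum `s* = sum(c_set*c_pred) /
#' sum(c_pred^2)`, so `f = 1 - 1/s*` in closed form (the objective is
#' strictly convex in `s`). Predictions that anti-correlate with the set
#' values (`s* <= 0`) have no meaningful loss factor and raise an error.
#'
#' @param c_set Set (nominal) concentrations, micromolar.
#' @param c_pred Predicted concentrations, micromolar.
#' @param treatment Treatment code stored on the estimate.
#' @return A `treatment_factor` object: `f` (dimensionless loss fraction),
#'   `rmsep_before`/`rmsep_after` (micromolar, after can only improve or
#'   tie), `n`, `treatment`; `f_mad` is `NA` until [factor_cv()].
#' @export
estimate_factor <- function(c_set, c_pred, treatment = "none") {
  if (length(c_set) != length(c_pred) || length(c_set) < 2) {
    rlang::abort("c_set and c_pred must have equal length >= 2",
                 class = "ramantdm_domain")
  }
  if (all(c_pred == 0)) {
    rlang::abort("all predictions are zero; factor undefined",
                 class = "ramantdm_degenerate")
  }
  s_star <- sum(c_set * c_pred) / sum(c_pred^2)
  if (s_star <= 0) {
    rlang::abort("predictions anti-correlated with set concentrations",
                 class = "ramantdm_sign")
  }
  f <- 1 - 1 / s_star
  structure(list(f = f, f_mad = NA_real_,
                 rmsep_before = rmsep(c_set, c_pred),
                 rmsep_after = rmsep(c_set, c_pred / (1 - f)),
                 n = length(c_set), treatment = treatment,
                 cv_estimates = NULL),
            class = "treatment_factor")
}

#' Cross-validated correction factor
#'
#' Repeats [estimate_factor()] on `repeats` random subsets holding
#' `train_fraction` of the points, then reports the median factor and its
#' raw median absolute deviation across subsets. The before/after RMSEPs
#' are evaluated on the full data at the median factor.
#'
#' @inheritParams estimate_factor
#' @param repeats Number of random subsets (default 10).
#' @param train_fraction Fraction of points per subset (default 0.8).
#' @param seed Optional seed for the subsampling.
#' @return A `treatment_factor` with `f_mad` and per-subset `cv_estimates`.
#' @export
factor_cv <- function(c_set, c_pred, repeats = 10, train_fraction = 0.8,
                      seed = NULL, treatment = "none") {
  n <- length(c_set)
  m <- floor(train_fraction * n)
  if (m < 2) {
    rlang::abort("subsets would have fewer than 2 points",
                 class = "ramantdm_domain")
  }
  run <- function() {
    vapply(seq_len(repeats), function(i) {
      idx <- sample(n, m)
      estimate_factor(c_set[idx], c_pred[idx])$f
    }, numeric(1))
  }
  fs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  f_med <- stats::median(fs)
  structure(list(f = f_med, f_mad = stats::mad(fs, constant = 1),
                 rmsep_before = rmsep(c_set, c_pred),
                 rmsep_after = rmsep(c_set, c_pred / (1 - f_med)),
                 n = n, treatment = treatment, cv_estimates = fs),
            class = "treatment_factor")
}

#' Rescale predictions by a correction factor
#'
#' Inverts the treatment loss: `c_pred / (1 - f)`.
#'
#' @param c_pred Predicted concentrations, micromolar.
#' @param f Loss factor in (-1, 1), `f != 1`.
#' @return Corrected concentrations, micromolar.
#' @export
apply_correction <- function(c_pred, f) {
  if (any(f == 1)) {
    rlang::abort("f = 1 would divide by zero", class = "ramantdm_domain")
  }
  c_pred / (1 - f)
}

#' Compose sequential treatment factors
#'
#' Sequential losses compound multiplicatively on concentration:
#' `1 - f_total = (1 - f1)(1 - f2)`. At the few-percent magnitudes seen in
#' practice this is indistinguishable from simple addition.
#'
#' @param f1,f2 Loss factors in (-1, 1).
#' @return The combined loss factor.
#' @export
compose_factors <- function(f1, f2) {
  stopifnot(all(f1 > -1 & f1 < 1), all(f2 > -1 & f2 < 1))
  1 - (1 - f1) * (1 - f2)
}

#' @export
print.treatment_factor <- function(x, ...) {
  cat(sprintf("Treatment correction factor (%s)\n", x$treatment))
  cat(sprintf("  f = %.2f %%", 100 * x$f))
  if (!is.na(x$f_mad)) cat(sprintf(" +/- %.2f %% (MAD, %d CV subsets)",
                                   100 * x$f_mad, length(x$cv_estimates)))
  cat("\n")
  cat(sprintf("  RMSEP before / after: %.1f / %.1f uM  (n = %d)\n",
              x$rmsep_before, x$rmsep_after, x$n))
  invisible(x)
}

#' @export
tidy.treatment_factor <- function(x, ...) {
  tibble::tibble(treatment = x$treatment, f = x$f,
                 factor_pct = 100 * x$f,
                 factor_mad_pct = 100 * x$f_mad,
                 rmsep_before_uM = x$rmsep_before,
                 rmsep_after_uM = x$rmsep_after, n = x$n)
}

#' @export
glance.treatment_factor <- function(x, ...) tidy(x)
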