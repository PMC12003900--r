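#' Root-mean-square error of prediction
#'
#' @param y_true,y_pred Set and predicted concentrations, micromolar.
#' @return RMSEP in micromolar.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1) {
    rlang::abort("y_true and y_pred must have equal length >= 1",
                 class = "ramantdm_domain")
  }
  sqrt(mean((y_true - y_pred)^2))
}

# NIPALS PLS1 with X-deflation; y centered and scaled internally.
# Returns enough to build regression vectors for any 1..A components.
.pls_nipals <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y) || n < A + 1) {
    rlang::abort("need rows(X) == length(y) >= n_components + 1",
                 class = "ramantdm_domain")
  }
  x_means <- colMeans(X)
  Ec <- sweep(X, 2, x_means)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  f <- (y - y_mean) / y_sd
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  E <- Ec
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      rlang::abort("n_components exceeds the effective rank of X",
                   class = "ramantdm_rank")
    }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    P[, a] <- drop(crossprod(E, t_)) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, P[, a])
    f <- f - q[a] * t_
    W[, a] <- w
  }
  list(W = W, P = P, q = q, x_means = x_means, y_mean = y_mean, y_sd = y_sd)
}

.pls_coef <- function(core, a) {
  W <- core$W[, seq_len(a), drop = FALSE]
  P <- core$P[, seq_len(a), drop = FALSE]
  q <- core$q[seq_len(a)]
  B <- W %*% solve(crossprod(P, W), q) * core$y_sd
  intercept <- core$y_mean - sum(core$x_means * B)
  list(coefficients = drop(B), intercept = intercept)
}

#' Fit a PLS1 calibration model
#'
#' Deterministic NIPALS partial least squares regression of concentration
#' on spectra. X is column-centered and y standardized internally;
#' predictions are returned in micromolar. At `n_components` equal to the
#' rank of centered X the fit coincides with ordinary least squares.
#'
#' @param x Spectra-by-channels matrix.
#' @param y Concentrations, micromolar.
#' @param n_components Number of latent components.
#' @return A `ramantdm_pls` model.
#' @export
fit_pls <- function(x, y, n_components) {
  core <- .pls_nipals(x, y, n_components)
  cf <- .pls_coef(core, n_components)
  structure(list(n_components = n_components, core = core,
                 coefficients = cf$coefficients, intercept = cf$intercept,
                 training_range = range(y), n = length(y),
                 cv_rmsep_by_ncomp = NULL),
            class = "ramantdm_pls")
}

#' Predict concentrations from a PLS model
#'
#' @param object A `ramantdm_pls` model.
#' @param newdata Matrix with the training channel count.
#' @param ... Unused.
#' @return A tibble with `.pred` (micromolar) and `extrapolated`, flagging
#'   predictions outside the training concentration range (never clipped).
#' @export
predict.ramantdm_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    rlang::abort("channel count does not match the training matrix",
                 class = "ramantdm_domain")
  }
  pred <- drop(newdata %*% object$coefficients) + object$intercept
  tibble::tibble(.pred = pred,
                 extrapolated = pred < object$training_range[1] |
                   pred > object$training_range[2])
}

# stratified, group-aware random 80/20 split of sample groups;
# extreme-concentration groups stay in training so the calibration
# range is always spanned
.cv_splits <- function(group_y, folds, train_fraction) {
  n_g <- length(group_y)
  n_hold <- max(1, round((1 - train_fraction) * n_g))
  ord <- order(group_y)
  eligible <- ord[-c(1, n_g)]
  if (length(eligible) < n_hold) eligible <- ord
  lapply(seq_len(folds), function(i) sort(sample(eligible, n_hold)))
}

#' Select the number of PLS components by cross-validated RMSEP
#'
#' Cross-validation is `folds` repeated random splits holding out
#' `1 - train_fraction` of the sample groups (replicate spectra of one
#' sample always stay together), stratified so the training partition
#' spans the calibration range. The candidate with the smallest mean
#' CV-RMSEP wins; ties go to fewer components.
#'
#' @param x Spectra-by-channels matrix.
#' @param y Concentrations, micromolar.
#' @param groups Sample-group labels, one per row of `x` (replicates of a
#'   sample share a label). Default: one group per row.
#' @param candidates Component counts to compare (default 3:5).
#' @param folds Number of repeated splits (default 50).
#' @param train_fraction Fraction of groups used for training.
#' @param seed Optional seed for the split randomness.
#' @return A list: `n_components` (selected), `cv_rmsep_by_ncomp`.
#' @export
select_ncomp <- function(x, y, groups = NULL, candidates = 3:5, folds = 50,
                         train_fraction = 0.8, seed = NULL) {
  x <- as.matrix(x)
  groups <- groups %||% as.character(seq_len(nrow(x)))
  candidates <- sort(unique(as.integer(candidates)))
  g_levels <- unique(groups)
  group_y <- vapply(g_levels, function(g) mean(y[groups == g]), numeric(1))
  run <- function() {
    splits <- .cv_splits(group_y, folds, train_fraction)
    err <- matrix(NA_real_, folds, length(candidates))
    for (i in seq_along(splits)) {
      hold_g <- g_levels[splits[[i]]]
      te <- groups %in% hold_g
      if (sum(!te) < max(candidates) + 1) {
        rlang::abort("training partition too small for the largest candidate",
                     class = "ramantdm_domain")
      }
      core <- .pls_nipals(x[!te, , drop = FALSE], y[!te], max(candidates))
      for (j in seq_along(candidates)) {
        cf <- .pls_coef(core, candidates[j])
        pred <- drop(x[te, , drop = FALSE] %*% cf$coefficients) + cf$intercept
        err[i, j] <- rmsep(y[te], pred)
      }
    }
    colMeans(err)
  }
  cv <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  names(cv) <- candidates
  list(n_components = candidates[which.min(cv)], cv_rmsep_by_ncomp = cv)
}

#' PLS calibration straight from a spectra table
#'
#' Builds the spectra-by-channels matrix, reads concentrations from the
#' `concentration_uM` metadata, selects the component count by repeated
#' cross-validation and fits the final model on all spectra.
#'
#' @param data A preprocessed spectra table with `concentration_uM`.
#' @param candidates,folds,seed See [select_ncomp()].
#' @return A `ramantdm_pls` model with `cv_rmsep_by_ncomp` filled in.
#' @export
pls_calibration <- function(data, candidates = 3:5, folds = 50, seed = NULL) {
  m <- spectra_to_matrix(data)
  y <- m$meta$concentration_uM
  if (is.null(y) || anyNA(y)) {
    rlang::abort("concentration_uM metadata required for calibration",
                 class = "ramantdm_format")
  }
  sel <- select_ncomp(m$intensity, y, groups = m$meta$sample_id,
                      candidates = candidates, folds = folds, seed = seed)
  fit <- fit_pls(m$intensity, y, sel$n_components)
  fit$cv_rmsep_by_ncomp <- sel$cv_rmsep_by_ncomp
  fit
}
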