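#' PCA dimension reduction
#'
#' Column-centered principal component analysis with a deterministic sign
#' convention (the largest-magnitude element of each loading is positive).
#' Select either a fixed number of components or the smallest number whose
#' cumulative explained-variance ratio reaches a threshold (the common
#' "smallest set covering 95% of the variance" rule).
#'
#' @param x Spectra-by-channels matrix.
#' @param n_pcs Fixed number of components, or `NULL`.
#' @param variance Cumulative explained-variance threshold in (0, 1], used
#'   when `n_pcs` is `NULL` (default 0.95).
#' @param wavenumber Optional channel axis stored for weighting vectors.
#' @return A `ramantdm_pca`: `scores` (samples x PCs), `loadings`
#'   (PCs x channels, orthonormal rows), `explained_variance_ratio` (all
#'   PCs), `n_pcs`, `center`, `wavenumber`.
#' @export
pca_reduce <- function(x, n_pcs = NULL, variance = 0.95, wavenumber = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    rlang::abort("PCA needs at least 2 rows", class = "ramantdm_domain")
  }
  if (is.null(n_pcs) && (variance <= 0 || variance > 1)) {
    rlang::abort("variance threshold must be in (0, 1]",
                 class = "ramantdm_domain")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_pcs)) {
    min(as.integer(n_pcs), ncol(pc$rotation))
  } else {
    which(cumsum(evr) >= variance - 1e-12)[1]
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  structure(list(scores = scores, loadings = t(rot),
                 explained_variance_ratio = evr, n_pcs = k,
                 center = pc$center, wavenumber = wavenumber),
            class = "ramantdm_pca")
}

#' Train a classifier on reduced scores
#'
#' Linear discriminant analysis or a support vector machine with linear
#' (default cost 1000) or radial kernel (default cost 10000, gamma 1).
#' The returned model exposes continuous decision scores for ROC
#' analysis: the LD1 discriminant projection for LDA, the signed margin
#' distance for SVM, both oriented so the positive class (first factor
#' level, alphabetically female) scores high — so swapping labels flips
#' the sign.
#'
#' @param scores Samples-by-features matrix (PCA scores).
#' @param labels Class labels (2 classes for SVM scoring; LDA may take
#'   more for discriminant analysis of pools).
#' @param kind `"lda"`, `"svm_linear"` or `"svm_radial"`.
#' @param cost,gamma SVM hyperparameters; defaults depend on kernel.
#' @return A `ramantdm_classifier`.
#' @export
train_classifier <- function(scores, labels,
                             kind = c("lda", "svm_linear", "svm_radial"),
                             cost = NULL, gamma = NULL) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    rlang::abort("need >= 2 classes with >= 2 members each",
                 class = "ramantdm_domain")
  }
  positive <- levels(labels)[1]
  if (kind == "lda") {
    model <- MASS::lda(scores, grouping = labels)
    proj <- scores %*% model$scaling[, 1]
    orient <- if (mean(proj[labels == positive]) >=
                  mean(proj[labels != positive])) 1 else -1
    out <- list(kind = kind, model = model, orient = orient)
  } else {
    kernel <- if (kind == "svm_linear") "linear" else "radial"
    cost <- cost %||% if (kind == "svm_linear") 1000 else 10000
    gamma <- gamma %||% 1
    model <- e1071::svm(x = scores, y = labels, kernel = kernel, cost = cost,
                        gamma = gamma, scale = TRUE)
    dv <- attr(stats::predict(model, scores, decision.values = TRUE),
               "decision.values")
    orient <- if (startsWith(colnames(dv)[1], paste0(positive, "/"))) 1 else -1
    out <- list(kind = kind, model = model, orient = orient)
  }
  out$positive <- positive
  out$levels <- levels(labels)
  structure(out, class = "ramantdm_classifier")
}

#' Decision scores and predicted classes
#'
#' @param object A `ramantdm_classifier`.
#' @param newdata Feature matrix with training column count.
#' @param ... Unused.
#' @return A tibble with `score` (positive class high) and `.pred_class`.
#' @export
predict.ramantdm_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "lda") {
    pr <- stats::predict(object$model, newdata)
    score <- object$orient * drop(newdata %*% object$model$scaling[, 1])
    cls <- pr$class
  } else {
    pr <- stats::predict(object$model, newdata, decision.values = TRUE)
    score <- object$orient * drop(attr(pr, "decision.values"))
    cls <- pr
  }
  tibble::tibble(score = as.numeric(score),
                 .pred_class = factor(as.character(cls),
                                      levels = object$levels))
}

#' Repeated grouped cross-validation of a classifier
#'
#' `k` repeated stratified 80/20 splits of the donor groups: per class,
#' about 20% of the donors are held out, and every spectrum of one donor
#' stays on the same side of the split (no replicate leakage). Held-out
#' decision scores and truths are returned per repeat for ROC averaging.
#'
#' @param x Feature matrix (e.g. PCA scores).
#' @param labels Two-class labels per row.
#' @param groups Donor identifier per row.
#' @param kind,cost,gamma See [train_classifier()].
#' @param k Number of repeats (default 20).
#' @param train_fraction Fraction of donors per class used for training.
#' @param seed Optional seed for the splits.
#' @return List of length `k`; each element a tibble with `score`,
#'   `truth` and `.pred_class` for the held-out spectra.
#' @export
cross_validate_classifier <- function(x, labels, groups,
                                      kind = c("lda", "svm_linear",
                                               "svm_radial"),
                                      cost = NULL, gamma = NULL, k = 20,
                                      train_fraction = 0.8, seed = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  labels <- factor(labels)
  groups <- as.character(groups)
  g_class <- tapply(as.character(labels), groups, function(v) v[1])
  run <- function() {
    lapply(seq_len(k), function(i) {
      hold <- unlist(lapply(levels(labels), function(cl) {
        g <- names(g_class)[g_class == cl]
        n_hold <- max(1, round((1 - train_fraction) * length(g)))
        if (n_hold >= length(g)) {
          rlang::abort("too few donors in a class to split",
                       class = "ramantdm_domain")
        }
        sample(g, n_hold)
      }))
      te <- groups %in% hold
      fit <- train_classifier(x[!te, , drop = FALSE], droplevels(labels[!te]),
                              kind = kind, cost = cost, gamma = gamma)
      pred <- stats::predict(fit, x[te, , drop = FALSE])
      tibble::tibble(score = pred$score, truth = labels[te],
                     .pred_class = pred$.pred_class, group = groups[te])
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# step-function ROC of one repeat at given thresholds (score >= t positive)
.roc_at <- function(score, is_pos, thresholds) {
  tpr <- vapply(thresholds, function(t) mean(score[is_pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(score[!is_pos] >= t), numeric(1))
  list(fpr = fpr, tpr = tpr)
}

.auc_trapezoid <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o], 1); tpr <- c(0, tpr[o], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Threshold-averaged ROC over cross-validation repeats
#'
#' Each repeat's ROC is evaluated at the union of all decision thresholds
#' seen across repeats; the (FPR, TPR) points are averaged across repeats
#' at each threshold, giving a mean curve with a TPR dispersion band.
#' The AUC is computed per repeat on its own curve by the trapezoid rule
#' and summarized as mean +/- sd.
#'
#' @param per_repeat List of tibbles with `score` and `truth`, as from
#'   [cross_validate_classifier()].
#' @param positive Positive class; default the first factor level.
#' @return A `roc_summary`: `curve` tibble (`threshold`, `mean_fpr`,
#'   `mean_tpr`, `sd_tpr`), `auc_mean`, `auc_sd`, `auc_by_repeat`,
#'   `n_repeats`.
#' @export
threshold_averaged_roc <- function(per_repeat, positive = NULL) {
  stopifnot(length(per_repeat) >= 1)
  positive <- positive %||% levels(factor(per_repeat[[1]]$truth))[1]
  thresholds <- sort(unique(unlist(lapply(per_repeat, `[[`, "score"))),
                     decreasing = TRUE)
  thresholds <- c(Inf, thresholds)
  rocs <- lapply(per_repeat, function(r) {
    is_pos <- r$truth == positive
    if (!any(is_pos) || all(is_pos)) {
      rlang::abort("a repeat holds only one class", class = "ramantdm_domain")
    }
    .roc_at(r$score, is_pos, thresholds)
  })
  fpr_mat <- vapply(rocs, `[[`, numeric(length(thresholds)), "fpr")
  tpr_mat <- vapply(rocs, `[[`, numeric(length(thresholds)), "tpr")
  aucs <- vapply(rocs, function(r) .auc_trapezoid(r$fpr, r$tpr), numeric(1))
  curve <- tibble::tibble(
    threshold = thresholds,
    mean_fpr = rowMeans(fpr_mat),
    mean_tpr = rowMeans(tpr_mat),
    sd_tpr = apply(tpr_mat, 1, stats::sd)
  )
  structure(list(curve = curve, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), auc_by_repeat = aucs,
                 n_repeats = length(per_repeat), positive = positive),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("Threshold-averaged ROC over %d repeats (positive: %s)\n",
              x$n_repeats, x$positive))
  cat(sprintf("  AUC = %.2f +/- %.2f\n", x$auc_mean,
              ifelse(is.na(x$auc_sd), 0, x$auc_sd)))
  invisible(x)
}

#' @export
tidy.roc_summary <- function(x, ...) x$curve

#' @export
glance.roc_summary <- function(x, ...) {
  tibble::tibble(auc_mean = x$auc_mean, auc_sd = x$auc_sd,
                 n_repeats = x$n_repeats, positive = x$positive)
}

#' Discriminant weighting vector in wavenumber space
#'
#' Maps LDA discriminant coefficients back through the PCA loadings to a
#' per-channel weight for each discriminant axis, attributing the
#' classification to chemical bands. Extrema are the local maxima of the
#' absolute weight above its 90th percentile.
#'
#' @param classifier A `ramantdm_classifier` of kind `lda` trained on the
#'   scores of `pca`.
#' @param pca The matching `ramantdm_pca` (with `wavenumber` set).
#' @return A `weighting_vector`: `weights` tibble (`wavenumber`, `ld`,
#'   `weight`) and `extrema` tibble (`ld`, `wavenumber`, `weight`).
#' @export
discriminant_weighting <- function(classifier, pca) {
  stopifnot(inherits(classifier, "ramantdm_classifier"),
            classifier$kind == "lda", inherits(pca, "ramantdm_pca"))
  scaling <- classifier$model$scaling
  if (nrow(scaling) != pca$n_pcs) {
    rlang::abort("LDA was not trained on these PCA scores",
                 class = "ramantdm_domain")
  }
  w_axis <- pca$wavenumber %||% seq_len(ncol(pca$loadings))
  W <- t(pca$loadings) %*% scaling  # channels x n_ld
  weights <- purrr::map_dfr(seq_len(ncol(W)), function(j) {
    tibble::tibble(wavenumber = w_axis, ld = paste0("LD", j),
                   weight = W[, j])
  })
  extrema <- weights |>
    dplyr::group_by(.data$ld) |>
    dplyr::group_modify(function(df, key) {
      aw <- abs(df$weight)
      thr <- stats::quantile(aw, 0.9)
      n <- length(aw)
      is_peak <- aw >= thr &
        aw >= c(-Inf, aw[-n]) & aw >= c(aw[-1], -Inf)
      df[is_peak, c("wavenumber", "weight")]
    }) |>
    dplyr::ungroup()
  structure(list(weights = weights, extrema = extrema),
            class = "weighting_vector")
}

#' @export
tidy.weighting_vector <- function(x, ...) x$weights
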