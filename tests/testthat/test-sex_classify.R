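test_that("PCA reduction selects, reconstructs and fixes signs deterministically", {
  # exact 2-D subspace: variance selector returns 2 with full coverage
  d <- withr::with_seed(1, {
    T_ <- matrix(rnorm(30 * 2), 30, 2)
    P_ <- matrix(rnorm(2 * 40), 2, 40)
    T_ %*% P_
  })
  red <- pca_reduce(d, variance = 0.95)
  expect_equal(red$n_pcs, 2)
  expect_equal(sum(red$explained_variance_ratio[1:2]), 1, tolerance = 1e-10)
  # fixed n_pcs honoured (pool-style 15-PC reduction)
  big <- withr::with_seed(2, matrix(rnorm(40 * 60), 40, 60))
  expect_equal(pca_reduce(big, n_pcs = 15)$n_pcs, 15)
  # loadings orthonormal, ratios non-increasing
  expect_equal(red$loadings %*% t(red$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(red$explained_variance_ratio) < 1e-12))
  # full reconstruction is lossless
  full <- pca_reduce(big, n_pcs = 40)
  recon <- full$scores %*% full$loadings
  centered <- sweep(big, 2, colMeans(big))
  expect_lt(max(abs(recon - centered)), 1e-8)
  # sign convention: largest |loading| element positive
  expect_true(all(apply(red$loadings, 1,
                        function(v) v[which.max(abs(v))] > 0)))
})

make_blobs <- function(n = 30, gap = 6, seed = 3) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = gap), n, 2))
    list(x = x, y = factor(rep(c("female", "male"), each = n)))
  })
}

make_annulus <- function(n = 150, seed = 4) {
  withr::with_seed(seed, {
    th <- runif(2 * n, 0, 2 * pi)
    r <- c(runif(n, 2, 2.4), runif(n, 0, 0.8))
    list(x = cbind(r * cos(th), r * sin(th)),
         y = factor(rep(c("female", "male"), each = n)))
  })
}

test_that("classifiers separate blobs; only the radial kernel solves the annulus", {
  b <- make_blobs()
  for (kind in c("lda", "svm_linear", "svm_radial")) {
    fit <- train_classifier(b$x, b$y, kind)
    expect_equal(mean(predict(fit, b$x)$.pred_class == b$y), 1)
  }
  a <- make_annulus()
  rad <- train_classifier(a$x, a$y, "svm_radial")
  expect_equal(mean(predict(rad, a$x)$.pred_class == a$y), 1)
  lin <- train_classifier(a$x, a$y, "lda")
  expect_lte(mean(predict(lin, a$x)$.pred_class == a$y), 0.65)
})

test_that("label swap inverts decision scores", {
  b <- make_blobs()
  flipped <- factor(ifelse(b$y == "female", "male", "female"))
  for (kind in c("lda", "svm_linear")) {
    s1 <- predict(train_classifier(b$x, b$y, kind), b$x)$score
    s2 <- predict(train_classifier(b$x, flipped, kind), b$x)$score
    expect_lt(cor(s1, s2), -0.95)
  }
  expect_error(train_classifier(b$x, factor(rep("f", nrow(b$x)))),
               class = "ramantdm_domain")
})

test_that("grouped cross-validation is seeded, leak-free and calibrated", {
  b <- make_blobs(n = 50)
  groups <- rep(paste0("d", 1:20), each = 5)
  cv <- cross_validate_classifier(b$x, b$y, groups, "lda", k = 10, seed = 2)
  expect_length(cv, 10)
  for (r in cv) {
    # all spectra of a held-out donor are on the test side together
    expect_true(all(table(r$group) == 5))
    expect_equal(mean(r$.pred_class == r$truth), 1)
  }
  expect_identical(cross_validate_classifier(b$x, b$y, groups, "lda",
                                             k = 10, seed = 2), cv)
  # identical class distributions: held-out accuracy near chance
  null <- withr::with_seed(8, {
    x <- matrix(rnorm(200 * 2), 200, 2)
    y <- factor(rep(c("female", "male"), each = 100))
    g <- rep(paste0("d", 1:20), each = 10)
    cross_validate_classifier(x, y, g, "lda", k = 20, seed = 3)
  })
  acc <- mean(vapply(null, function(r) mean(r$.pred_class == r$truth),
                     numeric(1)))
  expect_gt(acc, 0.35); expect_lt(acc, 0.65)
})

test_that("threshold-averaged ROC matches hand counts and the pROC oracle", {
  # disjoint scores: perfect AUC with zero spread
  rep1 <- tibble::tibble(score = c(0.9, 0.8, 0.3),
                         truth = factor(c("female", "female", "male"),
                                        levels = c("female", "male")))
  roc1 <- threshold_averaged_roc(list(rep1))
  expect_equal(roc1$auc_mean, 1)
  roc2 <- threshold_averaged_roc(list(rep1, rep1))
  expect_equal(roc2$auc_mean, 1); expect_equal(roc2$auc_sd, 0)
  # agreement with pROC on random scores, and monotone-transform invariance
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    sc <- rnorm(40)
    tr <- factor(sample(c("female", "male"), 40, replace = TRUE),
                 levels = c("female", "male"))
    mine <- threshold_averaged_roc(list(tibble::tibble(score = sc, truth = tr)))
    oracle <- pROC::auc(pROC::roc(response = tr, predictor = sc,
                                  levels = c("male", "female"),
                                  direction = "<", quiet = TRUE))
    expect_equal(mine$auc_mean, as.numeric(oracle), tolerance = 1e-10)
    trans <- threshold_averaged_roc(list(tibble::tibble(score = exp(sc),
                                                        truth = tr)))
    expect_equal(trans$auc_mean, mine$auc_mean, tolerance = 1e-10)
  }
  # label-independent scores hover at the permutation null (rank-based
  # AUC oracle for the permuted replicates)
  set.seed(14)
  sc <- rnorm(400)
  tr <- factor(rep(c("female", "male"), 200), levels = c("female", "male"))
  obs <- threshold_averaged_roc(list(tibble::tibble(score = sc, truth = tr)))
  rk <- rank(sc)
  null_aucs <- vapply(1:1000, function(i) {
    pos <- sample(400, 200)
    (mean(rk[pos]) - (200 + 1) / 2) / 200
  }, numeric(1))
  expect_lt(abs(obs$auc_mean - 0.5), 3 * stats::sd(null_aucs))
  # mean curve is monotone along the averaged thresholds
  expect_true(all(diff(obs$curve$mean_tpr) >= -1e-12))
  expect_error(threshold_averaged_roc(list(tibble::tibble(
    score = 1:3, truth = factor(rep("female", 3))))),
    class = "ramantdm_domain")
})

test_that("discriminant weighting maps class differences to the right bands", {
  # single informative channel: global extremum lands on it
  d <- withr::with_seed(16, {
    n <- 40; p <- 120
    x <- matrix(rnorm(n * p, sd = 0.05), n, p)
    y <- factor(rep(c("female", "male"), each = n / 2))
    x[y == "female", 60] <- x[y == "female", 60] + 1
    list(x = x, y = y)
  })
  w_axis <- seq(801, 801 + 119 * 2, 2)
  pca <- pca_reduce(d$x, n_pcs = 5, wavenumber = w_axis)
  lda <- train_classifier(pca$scores, d$y, "lda")
  wv <- discriminant_weighting(lda, pca)
  top <- wv$weights$wavenumber[which.max(abs(wv$weights$weight))]
  expect_lt(abs(top - w_axis[60]), 4)
  expect_equal(nrow(dplyr::filter(wv$weights, .data$ld == "LD1")), 120)
  # synthetic pools whose classes differ only in creatinine: the
  # discriminant extrema include the creatinine bands (vector
  # normalization adds counter-weighted urea/uric-acid extrema, since a
  # creatinine increase depresses every other normalized band)
  cfg <- synth_config(seed = 44, noise_sd = 5e-4)
  base <- make_donor(synth_config(seed = 44, composition_cv = 0), "female")
  comp <- setdiff(names(base), c("donor_id", "sex"))
  pools <- purrr::map_dfr(1:12, function(i) {
    p <- base
    p$donor_id <- paste0("p", i)
    withr::with_seed(100 + i, {
      for (cc in comp) p[[cc]] <- p[[cc]] * exp(rnorm(1, 0, 0.03))
    })
    p$creatinine <- p$creatinine * (if (i <= 6) 0.8 else 1.2)
    p
  })
  spectra <- purrr::map_dfr(seq_len(nrow(pools)), function(i) {
    withr::with_seed(200 + i,
      render_spectrum(pools[i, ], 0, cfg, sample_id = pools$donor_id[i]))
  })
  pre <- preprocess_spectra(spectra) |> normalize_spectra("vector")
  m <- spectra_to_matrix(pre)
  pca2 <- pca_reduce(m$intensity, n_pcs = 5, wavenumber = m$wavenumber)
  labels <- factor(rep(c("low", "high"), each = 6))
  lda2 <- train_classifier(pca2$scores, labels, "lda")
  wv2 <- discriminant_weighting(lda2, pca2)
  ex1 <- dplyr::filter(wv2$extrema, .data$ld == "LD1")
  expect_true(any(vapply(ex1$wavenumber, function(x)
    any(abs(x - c(850, 1050, 1525)) <= 5), logical(1))))
})
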