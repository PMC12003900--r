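test_that("donor draws are seeded, degenerate at cv 0, and hit their means", {
  cfg <- quiet_config(seed = 3, composition_cv = 0)
  d <- make_donor(cfg, "female", index = 1)
  expect_equal(d$urea, cfg$composition_means$female[["urea"]])
  expect_equal(d$creatinine, cfg$composition_means$female[["creatinine"]])
  # determinism
  cfg2 <- synth_config(seed = 3)
  expect_identical(make_donor(cfg2, "male", index = 4),
                   make_donor(cfg2, "male", index = 4))
  expect_false(identical(make_donor(cfg2, "male", index = 4),
                         make_donor(cfg2, "male", index = 5)))
  # law of large numbers against the configured log-normal moments
  cfg3 <- synth_config(seed = 8, composition_cv = 0.15)
  urea <- vapply(seq_len(10000), function(i)
    make_donor(cfg3, "female", index = i)$urea, numeric(1))
  mu <- cfg3$composition_means$female[["urea"]]
  se <- stats::sd(urea) / sqrt(length(urea))
  expect_lt(abs(mean(urea) - mu), 3 * se)
})

test_that("pooling is the component-wise mean with the right label", {
  cfg <- synth_config(seed = 2)
  f <- purrr::map_dfr(1:8, function(i) make_donor(cfg, "female", index = i))
  m <- purrr::map_dfr(1:9, function(i) make_donor(cfg, "male", index = i))
  expect_equal(make_pool(f[1, ])$creatinine, f$creatinine[1])
  two <- f[1:2, ]; two$creatinine <- c(1, 3)
  expect_equal(make_pool(two)$creatinine, 2)
  pf <- make_pool(f); pm <- make_pool(m); pmix <- make_pool(rbind(f, m))
  expect_equal(pf$sex, "pool_female")
  expect_equal(pm$sex, "pool_male")
  expect_equal(pmix$sex, "pool_mixed")
  # mixed pool lies strictly between the two sex pools component-wise
  for (cc in c("urea", "creatinine", "uric_acid")) {
    lo <- min(pf[[cc]], pm[[cc]]); hi <- max(pf[[cc]], pm[[cc]])
    expect_true(pmix[[cc]] > lo && pmix[[cc]] < hi)
  }
  # commutes with component-wise scaling
  scaled <- f
  for (cc in setdiff(names(f), c("donor_id", "sex"))) {
    scaled[[cc]] <- 3 * scaled[[cc]]
  }
  expect_equal(make_pool(scaled)$urea, 3 * make_pool(f)$urea)
  expect_error(make_pool(f[0, ]), class = "ramantdm_domain")
})

test_that("the forward model is exactly linear in drug concentration", {
  cfg <- quiet_config(seed = 1, baseline = list(coef = c(0, 0),
                                                hump_amplitude = 0,
                                                hump_center = 1200,
                                                hump_sigma = 350))
  donor <- make_donor(cfg, "female")
  blank <- render_spectrum(donor, 0, cfg, stochastic = FALSE)
  # noiseless blank equals the closed-form band mixture
  w <- blank$wavenumber
  bt <- cfg$band_table
  expected <- rep(0, length(w))
  for (cc in setdiff(names(donor), c("donor_id", "sex"))) {
    bands <- bt[bt$component == cc, ]
    for (i in seq_len(nrow(bands))) {
      expected <- expected + donor[[cc]] * bands$rel_intensity[i] *
        exp(-(w - bands$center[i])^2 / (2 * bands$sigma[i]^2))
    }
  }
  expect_equal(blank$intensity, expected, tolerance = 1e-12)
  # doubling the dose doubles the difference spectrum exactly
  d1 <- render_spectrum(donor, 500, cfg, stochastic = FALSE)
  d2 <- render_spectrum(donor, 1000, cfg, stochastic = FALSE)
  expect_equal(d2$intensity - blank$intensity,
               2 * (d1$intensity - blank$intensity), tolerance = 1e-12)
  # marker-region integral proportional to dose, relative error < 1e-10
  sel <- w >= 1450 & w <= 1520
  i1 <- sum(d1$intensity[sel] - blank$intensity[sel])
  i2 <- sum(d2$intensity[sel] - blank$intensity[sel])
  expect_lt(abs(i2 / i1 - 2), 1e-10)
  expect_error(render_spectrum(donor, -5, cfg), class = "ramantdm_domain")
})

test_that("marker band amplitude matches the configured response after fitting", {
  cfg <- quiet_config(seed = 6)
  donor <- make_donor(cfg, "female")
  blank <- render_spectrum(donor, 0, cfg, "blank", stochastic = FALSE)
  spiked <- render_spectrum(donor, 1000, cfg, "spiked", stochastic = FALSE)
  diff <- spiked
  diff$intensity <- spiked$intensity - blank$intensity
  fit <- fit_marker_band(diff)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 1000 * cfg$drug_response,
               tolerance = max(3 * fit$amplitude_se / fit$amplitude, 1e-6))
  expect_equal(fit$center, 1485, tolerance = 0.1)
})

test_that("factor experiments scale treated concentrations by 1 - f", {
  cfg <- quiet_config(seed = 4)
  # f = 0: treated and reference render identically up to metadata
  cfg0 <- quiet_config(seed = 4,
                       treatment_factors = c(none = 0, froz = 0,
                                             filt = 0.0236, cent = 0.028,
                                             filt_cent = 0.0505))
  exp0 <- generate_factor_experiment(cfg0, "froz", c(100, 500))
  mr <- spectra_to_matrix(exp0$reference)
  mt <- spectra_to_matrix(exp0$treated)
  expect_equal(unname(mt$intensity), unname(mr$intensity), tolerance = 1e-12)
  # f = 0.5 halves the rendered concentration: the marker-region signal
  # of treated equals the reference rendered at half the dose
  cfg5 <- quiet_config(seed = 4,
                       treatment_factors = c(none = 0, froz = 0.5,
                                             filt = 0.0236, cent = 0.028,
                                             filt_cent = 0.0505))
  exp5 <- generate_factor_experiment(cfg5, "froz", c(100))
  m5 <- spectra_to_matrix(exp5$treated)
  donor <- make_donor(cfg5, "female", index = 1002)
  direct <- render_spectrum(donor, 50, cfg5, stochastic = FALSE)
  expect_equal(unname(m5$intensity[1, ]), direct$intensity,
               tolerance = 1e-12)
  # metadata carries the set concentration, not the effective one
  expect_equal(unique(m5$meta$concentration_uM), 100)
  expect_error(generate_factor_experiment(cfg, "boiled"),
               class = "ramantdm_config")
})

test_that("generators are bit-reproducible and cohort has the right shape", {
  cfg <- synth_config(seed = 12)
  a <- generate_factor_experiment(cfg, "filt", c(0, 100, 250))
  b <- generate_factor_experiment(cfg, "filt", c(0, 100, 250))
  expect_identical(a, b)
  coh <- generate_classification_cohort(cfg, n_female = 8, n_male = 9)
  m <- spectra_to_matrix(coh)
  expect_equal(nrow(m$intensity), 17 * cfg$replicates_class)
  expect_equal(length(unique(m$meta$sample_id)), 17)
  expect_equal(sort(unique(m$meta$sex)), c("female", "male"))
  coh2 <- generate_classification_cohort(cfg, n_female = 8, n_male = 9)
  expect_identical(coh, coh2)
})
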