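test_that("wavenumber calibration recovers polynomial axis distortions", {
  peaks <- c(918, 1029, 1374, 1444, 1710)
  # identity
  map <- fit_wavenumber_calibration(peaks, peaks, degree = 1)
  expect_equal(map$residual_rms, 0, tolerance = 1e-10)
  expect_equal(ramantdm:::.polyval(map$coefficients, 1000), 1000,
               tolerance = 1e-8)
  # constant offset
  map2 <- fit_wavenumber_calibration(peaks - 2, peaks, degree = 1)
  expect_equal(ramantdm:::.polyval(map2$coefficients, 1200), 1202,
               tolerance = 1e-8)
  # quadratic distortion: degree-2 interpolation through three peaks is
  # exact at the peaks
  three <- c(918, 1374, 1710)
  meas <- three + 1e-4 * three^2
  map3 <- fit_wavenumber_calibration(meas, three, degree = 2)
  expect_lt(map3$residual_rms, 1e-8)
  expect_equal(ramantdm:::.polyval(map3$coefficients, meas), three,
               tolerance = 1e-8)
})

test_that("applying a calibration resamples exactly on linear intensities", {
  w <- seq(1000, 1500, 1)
  sp <- toy_spectrum(w = w, y = 0.3 * w + 2)
  map <- fit_wavenumber_calibration(c(1000, 1250, 1500) - 3,
                                    c(1000, 1250, 1500), degree = 1)
  out <- apply_calibration(sp, map, target_grid = seq(1005, 1490, 1))
  # the map shifts the axis by +3; on the calibrated axis the linear
  # intensity profile reads 0.3 (w - 3) + 2, and linear interpolation is
  # exact on linear functions
  expect_equal(out$intensity, 0.3 * (out$wavenumber - 3) + 2,
               tolerance = 1e-9)
  expect_error(apply_calibration(sp, map, target_grid = seq(900, 1400, 1)),
               class = "ramantdm_range")
  # a shifted Gaussian band recenters onto the reference position
  band <- toy_spectrum(w = w, y = exp(-(w - 1303)^2 / (2 * 64)))
  map2 <- fit_wavenumber_calibration(c(1000, 1250, 1500) + 3,
                                     c(1000, 1250, 1500), degree = 1)
  fixed <- apply_calibration(band, map2, target_grid = seq(1010, 1490, 1))
  expect_lt(abs(fixed$wavenumber[which.max(fixed$intensity)] - 1300), 1)
})

test_that("truncation keeps the closed interval with expected channel counts", {
  w <- seq(600, 1900, 1)
  sp <- toy_spectrum(w = w, y = rnorm(length(w)))
  expect_equal(nrow(truncate_spectra(sp, 800, 1800)), 1001)
  expect_equal(nrow(truncate_spectra(sp, 1150, 1750)), 601)
  expect_equal(truncate_spectra(sp, 600, 1900)$intensity, sp$intensity)
  expect_error(truncate_spectra(sp, 2000, 2100), class = "ramantdm_range")
})

test_that("Savitzky-Golay p=2,n=5 reproduces quadratics and shrinks noise", {
  w <- seq(800, 1300, 1)
  quad <- toy_spectrum(w = w, y = 2 + 0.01 * w - 3e-5 * w^2)
  sm <- savgol_smooth(quad, p = 2, n = 5)
  expect_equal(sm$intensity, quad$intensity, tolerance = 1e-10)
  const <- toy_spectrum(w = w, y = rep(4, length(w)))
  expect_equal(savgol_smooth(const)$intensity, const$intensity,
               tolerance = 1e-12)
  # interior variance reduction equals the sum of squared coefficients
  # (17^2 + 2*12^2 + 2*3^2)/35^2 = 0.4857
  set.seed(11)
  noise <- matrix(rnorm(2e5), nrow = 100)
  filt <- apply(noise, 1, function(y) signal::sgolayfilt(y, 2, 5))
  inner <- filt[50:1950, ]
  expect_equal(var(as.vector(inner)), 595 / 1225, tolerance = 0.02)
})

test_that("EMSC removes affine and polynomial contamination exactly", {
  w <- seq(800, 1800, 1)
  ref_y <- exp(-(w - 1200)^2 / 800) + 0.5 * exp(-(w - 1520)^2 / 500)
  ref <- toy_spectrum(w = w, y = ref_y, id = "ref")
  # x == reference -> unchanged
  x0 <- toy_spectrum(w = w, y = ref_y, id = "a")
  expect_equal(emsc_correct(x0, reference = ref)$intensity, ref_y,
               tolerance = 1e-10)
  # affine closure
  x1 <- toy_spectrum(w = w, y = 2 * ref_y + 5, id = "a")
  expect_equal(emsc_correct(x1, reference = ref)$intensity, ref_y,
               tolerance = 1e-9)
  # degree-6 polynomial contamination inside the model span
  wt <- 2 * (w - min(w)) / diff(range(w)) - 1
  contam <- 0.3 - 0.2 * wt + 0.5 * wt^3 - 0.4 * wt^6
  x2 <- toy_spectrum(w = w, y = 1.3 * ref_y + contam, id = "a")
  corr <- emsc_correct(x2, reference = ref, degree = 6)
  expect_lt(max(abs(corr$intensity - ref_y)), 1e-8)
  # constant reference is degenerate
  flat <- toy_spectrum(w = w, y = rep(1, length(w)), id = "ref")
  expect_error(emsc_correct(x2, reference = flat),
               class = "ramantdm_degenerate")
})

test_that("SNIP recovers narrow bands and flattens smooth baselines", {
  w <- seq(800, 1800, 1)
  peak <- 2 * exp(-(w - 1300)^2 / (2 * 64))
  # constant spectrum: baseline is the spectrum, corrected is zero
  flat <- toy_spectrum(w = w, y = rep(3, length(w)))
  out <- snip_baseline(flat)
  expect_equal(out$baseline, rep(3, length(w)), tolerance = 1e-9)
  expect_equal(out$intensity, rep(0, length(w)), tolerance = 1e-9)
  # sigma = 8 Gaussian on zero baseline: >= 95% of height survives
  sp <- toy_spectrum(w = w, y = peak)
  corr <- snip_baseline(sp, iterations = 20, order = 2)
  expect_gte(corr$intensity[which(w == 1300)], 0.95 * 2)
  # Gaussian + linear ramp: off-band residual < 2% of peak height
  ramp <- toy_spectrum(w = w, y = peak + 0.001 * (w - 800))
  corr2 <- snip_baseline(ramp)
  off <- abs(w - 1300) > 100
  expect_lt(mean(abs(corr2$intensity[off])), 0.02 * 2)
  expect_gte(corr2$intensity[which(w == 1300)], 0.95 * 2)
  # idempotence: re-applying removes < 2% further signal
  again <- snip_baseline(dplyr::select(corr2, -"baseline"))
  expect_lt(max(abs(again$baseline)), 0.02 * 2)
})

test_that("normalization modes behave as documented", {
  w <- seq(800, 1800, 1)
  y <- exp(-(w - 1611)^2 / (2 * 64)) + 0.4 * exp(-(w - 1050)^2 / (2 * 64))
  sp <- toy_spectrum(w = w, y = y)
  v1 <- normalize_spectra(sp, "vector")
  expect_equal(sqrt(sum(v1$intensity^2)), 1)
  expect_equal(normalize_spectra(v1, "vector")$intensity, v1$intensity)
  scaled <- toy_spectrum(w = w, y = 7 * y)
  expect_equal(normalize_spectra(scaled, "vector")$intensity, v1$intensity)
  mx <- normalize_spectra(sp, "max_at", center = 1605, window = 15)
  expect_equal(max(mx$intensity[abs(w - 1605) <= 15]), 1)
  expect_error(normalize_spectra(toy_spectrum(w = w, y = rep(0, length(w))),
                                 "vector"),
               class = "ramantdm_normalization")
  expect_error(normalize_spectra(toy_spectrum(w = w, y = -y), "max_at"),
               class = "ramantdm_normalization")
})

test_that("full conditioning chain is invariant to per-spectrum affine distortion", {
  cfg <- quiet_config(seed = 5)
  donor <- make_donor(cfg, "female")
  base <- render_spectrum(donor, 500, cfg, stochastic = FALSE)
  mx <- max(base$intensity)
  set.seed(9)
  gains <- c(1, 0.5, 2, 1.4)
  offs <- c(0, -0.1, 0.1, 0.05) * mx
  distorted <- purrr::map_dfr(seq_along(gains), function(i) {
    sp <- base
    sp$replicate <- i
    sp$intensity <- gains[i] * sp$intensity + offs[i]
    sp
  })
  out <- preprocess_spectra(distorted)
  m <- spectra_to_matrix(out)
  ref <- m$intensity[1, ]
  for (i in 2:4) {
    rms <- sqrt(mean((m$intensity[i, ] - ref)^2)) / sqrt(mean(ref^2))
    expect_lt(rms, 0.01)
  }
})
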