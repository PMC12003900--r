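#' Difference spectrum against a reference urine
#'
#' Channel-wise `sample - reference` of maxima-normalized median spectra.
#' Both inputs must already be maxima-normalized at the ~1605 cm^-1 urea
#' band (apex intensity 1 within 1e-9 inside 1605 +/- 15 cm^-1); this is
#' enforced, since differencing un-normalized spectra silently mixes
#' scale with composition.
#'
#' @param data Spectra table of one or more (median) sample spectra.
#' @param reference Spectra table holding one reference spectrum on the
#'   same axis.
#' @param center,window Normalization-check window, cm^-1.
#' @return A spectra table of difference spectra.
#' @export
difference_spectrum <- function(data, reference, center = 1605, window = 15) {
  m <- spectra_to_matrix(data)
  r <- spectra_to_matrix(reference)
  if (nrow(r$intensity) != 1) {
    rlang::abort("reference must hold exactly one spectrum",
                 class = "ramantdm_format")
  }
  if (length(r$wavenumber) != length(m$wavenumber) ||
      any(abs(r$wavenumber - m$wavenumber) >
          1e-9 * pmax(abs(m$wavenumber), 1))) {
    rlang::abort("sample and reference axes differ", class = "ramantdm_axis")
  }
  sel <- m$wavenumber >= center - window & m$wavenumber <= center + window
  check <- function(y, who) {
    if (!any(sel) || abs(max(y[sel]) - 1) > 1e-9) {
      rlang::abort(paste0(who, " spectrum is not maxima-normalized at ~",
                          center, " cm^-1"),
                   class = "ramantdm_contract")
    }
  }
  check(r$intensity[1, ], "reference")
  diff <- m$intensity
  for (i in seq_len(nrow(diff))) {
    check(m$intensity[i, ], paste0("sample ", m$meta$sample_id[i]))
    diff[i, ] <- m$intensity[i, ] - r$intensity[1, ]
  }
  matrix_to_spectra(m$wavenumber, diff, m$meta)
}

#' Fit a Gaussian to the piperacillin marker band
#'
#' Nonlinear least squares of `A * exp(-(w - c)^2 / (2 s^2)) + offset` on
#' the window `center0 +/- window` of a difference spectrum, with the
#' center bounded to the window and sigma to `[1, window]`. A constant
#' offset absorbs residual baseline. Restarts over a deterministic grid
#' of start widths guard against bad starts; non-convergence is reported,
#' never silent.
#'
#' @param diff A spectra table holding one difference spectrum.
#' @param center0 Expected band center, cm^-1 (default 1485).
#' @param window Half-width of the fit window, cm^-1 (default 30).
#' @param offset Include the constant offset term? Default `TRUE`.
#' @return A `gaussian_fit`: `amplitude`, `center`, `sigma`, `offset`,
#'   `amplitude_se`, `converged`, `low_signal`.
#' @export
fit_marker_band <- function(diff, center0 = 1485, window = 30,
                            offset = TRUE) {
  m <- spectra_to_matrix(diff)
  if (nrow(m$intensity) != 1) {
    rlang::abort("fit_marker_band takes exactly one spectrum",
                 class = "ramantdm_format")
  }
  sel <- m$wavenumber >= center0 - window & m$wavenumber <= center0 + window
  if (sum(sel) < 8) {
    rlang::abort("fit window holds fewer than 8 channels",
                 class = "ramantdm_range")
  }
  w <- m$wavenumber[sel]
  y <- m$intensity[sel]
  if (stats::sd(y) < 1e-14) {
    return(structure(list(amplitude = 0, center = center0, sigma = 8,
                          offset = mean(y), amplitude_se = 0,
                          converged = TRUE, low_signal = TRUE,
                          diagnostics = "flat input"),
                     class = "gaussian_fit"))
  }
  df <- data.frame(w = w, y = y)
  lower <- c(A = -Inf, c = center0 - window, s = 1,
             o = if (offset) -Inf else 0)
  upper <- c(A = Inf, c = center0 + window, s = window,
             o = if (offset) Inf else 0)
  # start at the known marker position (the in-window argmax can sit on a
  # matrix-mismatch shoulder and pull the fit into a spurious optimum)
  starts <- c(
    lapply(c(8, 4, 16), function(s0) {
      list(A = max(y) - min(y), c = center0, s = s0,
           o = if (offset) min(y) else 0)
    }),
    list(list(A = max(y) - min(y), c = w[which.max(y)], s = 8,
              o = if (offset) min(y) else 0))
  )
  fit <- NULL; msg <- character(0)
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(w - c)^2 / (2 * s^2)) + o,
                        data = df, start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(res, "error")) { fit <- res; break }
    msg <- c(msg, conditionMessage(res))
  }
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, center = NA_real_,
                          sigma = NA_real_, offset = NA_real_,
                          amplitude_se = NA_real_, converged = FALSE,
                          low_signal = TRUE,
                          diagnostics = paste(msg, collapse = "; ")),
                     class = "gaussian_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["A", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(amplitude = unname(cf["A"]), center = unname(cf["c"]),
                 sigma = unname(cf["s"]), offset = unname(cf["o"]),
                 amplitude_se = unname(se), converged = TRUE,
                 low_signal = isTRUE(unname(cf["A"]) < 3 * se),
                 diagnostics = NULL),
            class = "gaussian_fit")
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, center = x$center, sigma = x$sigma,
                 offset = x$offset, amplitude_se = x$amplitude_se,
                 converged = x$converged, low_signal = x$low_signal)
}

#' ICH limits of detection and quantification
#'
#' `LoD = 3.3 * sigma_n / m` and `LoQ = 10 * sigma_n / m`, with `sigma_n`
#' the standard error of the calibration intercept and `m` its slope, so
#' `LoQ / LoD = 10 / 3.3` identically.
#'
#' @param sigma_n Intercept standard error (a.u.).
#' @param m Calibration slope (a.u. per micromolar), > 0.
#' @return Named vector `c(lod_uM, loq_uM)`.
#' @export
lod_loq <- function(sigma_n, m) {
  stopifnot(sigma_n >= 0)
  if (m <= 0) {
    rlang::abort("calibration slope must be positive",
                 class = "ramantdm_sign")
  }
  c(lod_uM = 3.3 * sigma_n / m, loq_uM = 10 * sigma_n / m)
}

#' Build a marker-band calibration curve
#'
#' Ordinary least squares of fitted band amplitude on concentration
#' (replicate concentration levels allowed), with the intercept standard
#' error from the classical OLS formula and ICH detection limits derived
#' from it.
#'
#' @param concentrations Micromolar, >= 3 distinct values.
#' @param amplitudes Fitted marker-band amplitudes, a.u.
#' @param reference Label of the reference matrix used.
#' @return A `calibration_curve`: `slope`, `intercept`, `sigma_n`,
#'   `r_squared`, `n_points`, `lod_uM`, `loq_uM`, `reference`, `data`.
#' @export
build_calibration <- function(concentrations, amplitudes,
                              reference = "own") {
  stopifnot(length(concentrations) == length(amplitudes))
  if (length(unique(concentrations)) < 3) {
    rlang::abort("need >= 3 distinct concentration levels",
                 class = "ramantdm_domain")
  }
  fit <- stats::lm(amplitudes ~ concentrations)
  # an exactly linear calibration is legitimate; summary.lm warns then
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    rlang::abort("calibration slope is not positive; quantification impossible",
                 class = "ramantdm_sign")
  }
  sigma_n <- sm$coefficients["(Intercept)", "Std. Error"]
  lims <- lod_loq(sigma_n, slope)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 sigma_n = sigma_n, r_squared = sm$r.squared,
                 n_points = length(concentrations),
                 lod_uM = unname(lims["lod_uM"]),
                 loq_uM = unname(lims["loq_uM"]),
                 reference = reference,
                 data = tibble::tibble(concentration_uM = concentrations,
                                       amplitude = amplitudes)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Marker-band calibration vs '%s' reference (n = %d)\n",
              x$reference, x$n_points))
  cat(sprintf("  slope = %.3g a.u./uM, sigma_n = %.3g a.u., R^2 = %.4f\n",
              x$slope, x$sigma_n, x$r_squared))
  cat(sprintf("  LoD = %.3g uM (%.3g mg/L), LoQ = %.3g uM (%.3g mg/L)\n",
              x$lod_uM, umol_to_mgL(x$lod_uM), x$loq_uM,
              umol_to_mgL(x$loq_uM)))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$sigma_n, NA_real_))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(reference = x$reference, slope = x$slope,
                 sigma_n = x$sigma_n, r_squared = x$r_squared,
                 n_points = x$n_points, lod_uM = x$lod_uM,
                 loq_uM = x$loq_uM)
}

#' Percent deviation of a pool-reference LoD from the own-matrix LoD
#'
#' `100 * (lod_pool - lod_own) / lod_pool`: how much worse (in percent of
#' the pool value) detection gets when a surrogate pool replaces the
#' patient's own urine as reference.
#'
#' @param lod_reference_pool,lod_own Limits of detection, micromolar.
#' @return Deviation in percent.
#' @export
percent_deviation <- function(lod_reference_pool, lod_own) {
  if (any(lod_reference_pool <= 0)) {
    rlang::abort("pool LoD must be positive", class = "ramantdm_domain")
  }
  100 * (lod_reference_pool - lod_own) / lod_reference_pool
}

#' Micromolar to mg/L
#'
#' Default molar mass is piperacillin sodium (539.5 g/mol); the free acid
#' is 517.55 g/mol.
#'
#' @param c Concentration, micromolar, >= 0.
#' @param molar_mass g/mol, > 0.
#' @return Concentration in mg/L.
#' @export
umol_to_mgL <- function(c, molar_mass = 539.5) {
  stopifnot(all(c >= 0), molar_mass > 0)
  c * molar_mass / 1000
}
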