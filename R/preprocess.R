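#' Fit a wavenumber calibration map
#'
#' Least-squares polynomial mapping measured peak positions of calibration
#' standards (acetonitrile, Teflon, toluene) to their reference positions.
#'
#' @param measured_peaks,reference_peaks Sorted peak positions, cm^-1,
#'   equal lengths >= `degree + 1`.
#' @param degree Polynomial degree.
#' @return A `calibration_map`: coefficients (ascending powers), degree,
#'   `residual_rms` (cm^-1) and the measured range it is valid on.
#' @export
fit_wavenumber_calibration <- function(measured_peaks, reference_peaks,
                                       degree = 2) {
  stopifnot(length(measured_peaks) == length(reference_peaks),
            length(measured_peaks) >= degree + 1)
  X <- outer(measured_peaks, 0:degree, `^`)
  fit <- stats::lm.fit(X, reference_peaks)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  rng <- range(measured_peaks)
  grid <- seq(rng[1], rng[2], length.out = 512)
  mapped <- .polyval(coefs, grid)
  if (any(diff(mapped) <= 0)) {
    rlang::abort("fitted calibration map is not strictly increasing",
                 class = "ramantdm_calibration")
  }
  structure(list(coefficients = coefs, degree = degree,
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 range = rng),
            class = "calibration_map")
}

.polyval <- function(coefs, x) {
  y <- numeric(length(x))
  for (k in seq_along(coefs)) y <- y + coefs[k] * x^(k - 1)
  y
}

#' Apply a calibration map and resample
#'
#' Transforms each spectrum's axis through the map and linearly
#' interpolates the intensities onto `target_grid` (default: the mapped
#' axis of the first spectrum). Requesting channels outside the mapped
#' range is an error, never an extrapolation.
#'
#' @param data A spectra table.
#' @param map A `calibration_map`.
#' @param target_grid Wavenumber axis for the output, cm^-1.
#' @return A spectra table on `target_grid`.
#' @export
apply_calibration <- function(data, map, target_grid = NULL) {
  stopifnot(inherits(map, "calibration_map"))
  .per_spectrum(data, function(w, y) {
    w_true <- .polyval(map$coefficients, w)
    grid <- target_grid %||% w_true
    if (min(grid) < min(w_true) - 1e-9 || max(grid) > max(w_true) + 1e-9) {
      rlang::abort("target grid extends beyond the calibrated range",
                   class = "ramantdm_range")
    }
    list(wavenumber = grid,
         intensity = stats::approx(w_true, y, xout = grid, rule = 1)$y)
  })
}

# apply fn(w, y) -> list(wavenumber, intensity) to every spectrum
.per_spectrum <- function(data, fn) {
  data <- as_spectra(data)
  key <- paste(data$sample_id, data$replicate, sep = "\r")
  idx <- split(seq_len(nrow(data)), factor(key, levels = unique(key)))
  pieces <- lapply(idx, function(rows) {
    res <- fn(data$wavenumber[rows], data$intensity[rows])
    keep <- data[rows[1], setdiff(names(data), c("wavenumber", "intensity")),
                 drop = FALSE]
    out <- keep[rep(1, length(res$wavenumber)), , drop = FALSE]
    out$wavenumber <- res$wavenumber
    out$intensity <- res$intensity
    if (!is.null(res$baseline)) out$baseline <- res$baseline
    out
  })
  as_spectra(dplyr::bind_rows(pieces))
}

#' Truncate spectra to a wavenumber window
#'
#' Keeps channels with `lo <= wavenumber <= hi` (closed interval). The
#' region of interest for the full pipeline is 800-1800 cm^-1; the PLS
#' stage narrows further to 1150-1750 cm^-1.
#'
#' @param data A spectra table.
#' @param lo,hi Window bounds, cm^-1, `lo < hi`.
#' @return A spectra table.
#' @export
truncate_spectra <- function(data, lo = 800, hi = 1800) {
  stopifnot(lo < hi)
  data <- as_spectra(data)
  out <- dplyr::filter(data, .data$wavenumber >= lo, .data$wavenumber <= hi)
  if (nrow(out) == 0) {
    rlang::abort("truncation window contains no channels",
                 class = "ramantdm_range")
  }
  as_spectra(out)
}

#' Savitzky-Golay smoothing
#'
#' Sliding-window polynomial least-squares smoothing (defaults p = 2,
#' n = 5). Edges are handled by evaluating the terminal-window polynomial
#' fits, so polynomials of degree <= p pass through unchanged everywhere,
#' including the first and last channels.
#'
#' @param data A spectra table.
#' @param p Polynomial degree.
#' @param n Window length (odd, > p).
#' @return A spectra table.
#' @export
savgol_smooth <- function(data, p = 2, n = 5) {
  stopifnot(n %% 2 == 1, n > p)
  .per_spectrum(data, function(w, y) {
    if (length(y) < n) {
      rlang::abort("spectrum shorter than the smoothing window",
                   class = "ramantdm_range")
    }
    list(wavenumber = w, intensity = as.numeric(signal::sgolayfilt(y, p, n)))
  })
}

#' Extended multiplicative signal correction
#'
#' Decomposes each spectrum by least squares as
#' `x = b * reference + sum_k a_k P_k + e`, where `P_k` are orthogonal
#' polynomials of degree 0..`degree` on the axis rescaled to \[-1, 1\],
#' then returns `(x - sum_k a_k P_k) / b`. This removes per-spectrum
#' affine scatter distortion and any smooth contamination inside the
#' polynomial span exactly. The default reference is the channel-wise
#' median of each sample's replicates, so correction is relative to the
#' sample's own median spectrum; pass `reference` to override.
#'
#' @param data A spectra table on a common axis.
#' @param reference Optional spectra table (or single spectrum) used as
#'   the common reference; default per-sample median.
#' @param degree Polynomial degree (default 6).
#' @return A spectra table of corrected spectra.
#' @export
emsc_correct <- function(data, reference = NULL, degree = 6) {
  m <- spectra_to_matrix(data)
  w <- m$wavenumber
  wt <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  P <- cbind(1, stats::poly(wt, degree = degree))
  if (is.null(reference)) {
    refs <- lapply(split(seq_len(nrow(m$meta)), m$meta$sample_id),
                   function(rows) apply(m$intensity[rows, , drop = FALSE],
                                        2, stats::median))
  } else {
    rm_ <- spectra_to_matrix(reference)
    if (any(abs(rm_$wavenumber - w) > 1e-9 * pmax(abs(w), 1))) {
      rlang::abort("reference axis differs from data axis",
                   class = "ramantdm_axis")
    }
    if (nrow(rm_$intensity) > 1) {
      rlang::abort("reference must be a single spectrum",
                   class = "ramantdm_format")
    }
    common_ref <- rm_$intensity[1, ]
  }
  X <- m$intensity
  out <- X
  for (i in seq_len(nrow(X))) {
    ref <- if (is.null(reference)) refs[[m$meta$sample_id[i]]] else common_ref
    if (stats::sd(ref) == 0) {
      rlang::abort("EMSC reference is constant", class = "ramantdm_degenerate")
    }
    D <- cbind(ref, P)
    cf <- stats::lm.fit(D, X[i, ])$coefficients
    cf[is.na(cf)] <- 0
    b <- cf[1]
    if (abs(b) < 1e-8) {
      rlang::abort("degenerate EMSC fit: reference coefficient ~ 0",
                   class = "ramantdm_degenerate")
    }
    out[i, ] <- (X[i, ] - drop(P %*% cf[-1])) / b
  }
  matrix_to_spectra(w, out, m$meta)
}

#' SNIP baseline estimation and removal
#'
#' Statistics-sensitive nonlinear iterative peak clipping with the
#' log-log-square-root (LLS) compression transform. Iteration `m` clips
#' each channel to the minimum of itself and a symmetric neighbour filter
#' at distance `m`. `order` follows the filter-order convention of the
#' classic implementations: `2` (default) is the two-point neighbour
#' average, `4` adds the four-point term using neighbours at `m/2` and
#' takes the larger of the two (smoother baselines, but it cuts into
#' bands whose width approaches the window). Intensities are shifted to
#' be positive before the LLS transform and the shift is removed
#' afterwards, so negative preprocessed intensities are fine.
#'
#' @param data A spectra table.
#' @param iterations Number of clipping passes (maximum half-window).
#' @param order Clipping filter order, 2 or 4.
#' @param lls Apply the LLS transform? Default `TRUE`.
#' @return The spectra table with `intensity` replaced by the
#'   baseline-corrected signal and a new `baseline` column.
#' @export
snip_baseline <- function(data, iterations = 20, order = 2, lls = TRUE) {
  stopifnot(iterations >= 1, order %in% c(2, 4))
  .per_spectrum(data, function(w, y) {
    b <- .snip_vec(y, iterations, order, lls)
    list(wavenumber = w, intensity = y - b, baseline = b)
  })
}

.snip_vec <- function(y, iterations, order, lls) {
  stopifnot(all(is.finite(y)))
  shift <- min(y)
  v <- y - shift
  if (lls) v <- log(log(sqrt(v + 1) + 1) + 1)
  N <- length(v)
  for (m in seq_len(iterations)) {
    if (2 * m + 1 > N) break
    i <- (m + 1):(N - m)
    a1 <- (v[i - m] + v[i + m]) / 2
    cand <- a1
    m2 <- m %/% 2
    if (order == 4 && m2 >= 1) {
      a2 <- (4 * (v[i - m2] + v[i + m2]) - (v[i - m] + v[i + m])) / 6
      cand <- pmax(a1, a2)
    }
    v[i] <- pmin(v[i], cand)
  }
  if (lls) v <- (exp(exp(v) - 1) - 1)^2 - 1
  v + shift
}

#' Normalize spectra
#'
#' `vector` mode divides by the Euclidean norm (unit-norm output,
#' idempotent, scale-invariant). `max_at` mode divides by the maximum
#' intensity within `center +/- window`, the maxima normalization at the
#' ~1605 cm^-1 urea C=O-stretch band used for reference-matrix
#' quantification.
#'
#' @param data A spectra table.
#' @param mode `"vector"` or `"max_at"`.
#' @param center,window Band search window for `max_at`, cm^-1.
#' @return A spectra table.
#' @export
normalize_spectra <- function(data, mode = c("vector", "max_at"),
                              center = 1605, window = 15) {
  mode <- match.arg(mode)
  .per_spectrum(data, function(w, y) {
    if (mode == "vector") {
      nrm <- sqrt(sum(y^2))
      if (nrm == 0) {
        rlang::abort("cannot vector-normalize an all-zero spectrum",
                     class = "ramantdm_normalization")
      }
      list(wavenumber = w, intensity = y / nrm)
    } else {
      sel <- w >= center - window & w <= center + window
      if (!any(sel)) {
        rlang::abort("normalization window contains no channels",
                     class = "ramantdm_normalization")
      }
      mx <- max(y[sel])
      if (mx <= 0) {
        rlang::abort("no positive maximum in the normalization window",
                     class = "ramantdm_normalization")
      }
      list(wavenumber = w, intensity = y / mx)
    }
  })
}

#' Full spectral conditioning chain
#'
#' The standard order: truncate to the region of interest, Savitzky-Golay
#' smooth, EMSC against the per-sample median, SNIP baseline removal.
#' Task-specific truncation/normalization (PLS window, vector or maxima
#' normalization) is applied afterwards by the caller.
#'
#' @param data A spectra table.
#' @param lo,hi Region of interest, cm^-1.
#' @param sg_p,sg_n Savitzky-Golay degree and window.
#' @param emsc_degree EMSC polynomial degree.
#' @param snip_iterations,snip_order SNIP parameters.
#' @return A spectra table (with `baseline` column from SNIP removed).
#' @export
preprocess_spectra <- function(data, lo = 800, hi = 1800, sg_p = 2, sg_n = 5,
                               emsc_degree = 6, snip_iterations = 20,
                               snip_order = 2) {
  out <- data |>
    truncate_spectra(lo, hi) |>
    savgol_smooth(p = sg_p, n = sg_n) |>
    emsc_correct(degree = emsc_degree) |>
    snip_baseline(iterations = snip_iterations, order = snip_order)
  out$baseline <- NULL
  as_spectra(out)
}
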