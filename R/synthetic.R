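#' Default Raman band table for the urine matrix and piperacillin
#'
#' Gaussian band positions for the three dominant urine chromophores and
#' the analyte. Urea carries its strong C=O-stretch band near 1611 cm^-1
#' (the maxima-normalization anchor), creatinine its bands near 850, 1050
#' and 1525 cm^-1, uric acid near 1355, 1435 and 1660 cm^-1, and
#' piperacillin the HC-CH-rocking / NH-out-of-plane marker near 1485 cm^-1.
#' Widths default to sigma = 8 cm^-1.
#'
#' @return A tibble with columns `component`, `center` (cm^-1),
#'   `sigma` (cm^-1) and `rel_intensity`.
#' @export
band_table_default <- function() {
  tibble::tribble(
    ~component,     ~center, ~sigma, ~rel_intensity,
    "urea",          1015,      8,     0.60,
    "urea",          1265,      8,     0.35,
    "urea",          1611,      8,     1.00,
    "creatinine",     850,      8,     0.70,
    "creatinine",    1050,      8,     0.60,
    "creatinine",    1525,      8,     1.00,
    "uric_acid",     1355,      8,     0.80,
    "uric_acid",     1435,      8,     0.90,
    "uric_acid",     1660,      8,     1.00,
    "minor_a",        935,      8,     0.50,
    "minor_a",       1320,      8,     0.50,
    "minor_b",        970,      8,     0.60,
    "minor_b",       1560,      8,     0.40,
    "piperacillin",  1485,      8,     1.00,
    "piperacillin",  1230,      8,     0.35
  )
}

#' Synthetic urine spectrum generator configuration
#'
#' Bundles every generative choice: the wavenumber grid, the band table,
#' per-sex matrix composition (arbitrary units; the field publishes no
#' absolute values, so these are order-of-magnitude defaults), donor
#' variability, the linear drug response, baseline/scatter/noise model,
#' the per-treatment concentration-loss factors `f` (defaults are the
#' freezing/filtration/centrifugation losses the analysis is built to
#' recover), replicate counts and the master seed. All randomness in the
#' generators derives from `seed` through named streams, so regeneration
#' is bit-reproducible.
#'
#' @param grid `c(lo, hi, step)` in cm^-1.
#' @param band_table See [band_table_default()].
#' @param composition_means Named list `female`/`male`, each a named vector
#'   of mean matrix-component concentrations (a.u.).
#' @param composition_cv Donor-to-donor coefficient of variation of each
#'   component (log-normal model).
#' @param drug_response Marker-band amplitude per micromolar (a.u./uM).
#' @param baseline List: `coef` (constant, linear term on the scaled axis),
#'   `hump_amplitude`, `hump_center`, `hump_sigma` for a broad
#'   fluorescence-like hump.
#' @param scatter `c(gain_sd, offset_sd)`: per-spectrum multiplicative gain
#'   (mean 1) and additive offset (mean 0).
#' @param noise_sd Additive white-noise standard deviation (a.u.).
#' @param treatment_factors Named vector mapping treatment code to the
#'   fractional concentration loss `f` in (-1, 1).
#' @param replicates_quant,replicates_class Spectra per sample for
#'   quantification (default 3) and classification (default 20).
#' @param annulus Nonlinear sex-structure of the classification cohort:
#'   female donors sit on a bounded ring in the plane of the two
#'   band-intensity ratios creatinine/urea and uric acid/urea (linear
#'   offsets about the cross-sex mean composition at `scale`), male donors
#'   in its complement (central core plus an outer shell clustered in an
#'   angular sector), so only a radial boundary separates the classes.
#'   `theta_jitter` is the tangential aliquot-level drift of replicates;
#'   `urea_mean`, `urea_sex_gap`, `urea_cv` control the cohort's urea
#'   level and its modest sex shift.
#' @param seed Master seed (integer).
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid = c(600, 1900, 1),
                         band_table = band_table_default(),
                         composition_means = list(
                           female = c(urea = 1.00, creatinine = 0.55,
                                      uric_acid = 0.30, minor_a = 0.10,
                                      minor_b = 0.10),
                           male   = c(urea = 1.15, creatinine = 0.45,
                                      uric_acid = 0.36, minor_a = 0.10,
                                      minor_b = 0.10)),
                         composition_cv = 0.08,
                         drug_response = 2e-4,
                         baseline = list(coef = c(0.05, 0.10),
                                         hump_amplitude = 0.30,
                                         hump_center = 1200,
                                         hump_sigma = 350),
                         scatter = c(gain_sd = 0.10, offset_sd = 0.02),
                         noise_sd = 0.001,
                         treatment_factors = c(none = 0, froz = 0.0842,
                                               filt = 0.0236, cent = 0.0280,
                                               filt_cent = 0.0505),
                         replicates_quant = 3L,
                         replicates_class = 20L,
                         annulus = list(scale = 0.35,
                                        female_radius = c(0.95, 1.05),
                                        male_core = c(0.00, 0.35),
                                        male_outer = c(1.80, 2.00),
                                        outer_sector = 0.6,
                                        theta_jitter = 0.55,
                                        urea_mean = 1.05,
                                        urea_sex_gap = 0.025,
                                        urea_cv = 0.02),
                         seed = 1L) {
  stopifnot(length(grid) == 3, grid[3] > 0, grid[1] < grid[2],
            composition_cv >= 0, drug_response >= 0,
            all(scatter >= 0), noise_sd >= 0,
            replicates_quant >= 1, replicates_class >= 1)
  if (any(treatment_factors <= -1 | treatment_factors >= 1)) {
    rlang::abort("treatment factors must lie in (-1, 1)",
                 class = "ramantdm_config")
  }
  structure(list(grid = grid, band_table = tibble::as_tibble(band_table),
                 composition_means = composition_means,
                 composition_cv = composition_cv,
                 drug_response = drug_response, baseline = baseline,
                 scatter = scatter, noise_sd = noise_sd,
                 treatment_factors = treatment_factors,
                 replicates_quant = as.integer(replicates_quant),
                 replicates_class = as.integer(replicates_class),
                 annulus = annulus, seed = as.integer(seed)),
            class = "synth_config")
}

# named substream of the master seed; keeps every generator call
# independent of global RNG state and bit-reproducible
.with_stream <- function(seed, stream, code) {
  sub <- (as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483629
  withr::with_seed(as.integer(sub), code)
}

.stream_id <- function(...) {
  # small deterministic hash of integer coordinates into one stream id
  parts <- c(...)
  h <- 0
  for (p in parts) h <- (h * 131 + as.numeric(p)) %% 1e9
  h
}

#' Draw one synthetic urine donor
#'
#' Matrix-component concentrations are drawn per component from a
#' log-normal with the sex-specific arithmetic mean and the configured
#' coefficient of variation, so concentrations stay positive and
#' `composition_cv = 0` reproduces the means exactly.
#'
#' @param config A [synth_config()].
#' @param sex `"female"` or `"male"`.
#' @param index Draw index; the same `(seed, sex, index)` always yields the
#'   same donor.
#' @param donor_id Identifier, defaults to `<sex-initial><index>`.
#' @return One-row tibble: `donor_id`, `sex`, one column per component.
#' @export
make_donor <- function(config, sex = c("female", "male"), index = 1,
                       donor_id = NULL) {
  sex <- match.arg(sex)
  means <- config$composition_means[[sex]]
  cv <- config$composition_cv
  donor_id <- donor_id %||% paste0(substr(sex, 1, 1), index)
  vals <- .with_stream(config$seed, .stream_id(11, match(sex, c("female", "male")), index), {
    if (cv == 0) means else {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(means) - sdlog^2 / 2
      stats::setNames(stats::rlnorm(length(means), meanlog, sdlog), names(means))
    }
  })
  tibble::as_tibble(c(list(donor_id = donor_id, sex = sex), as.list(vals)))
}

#' Pool donors by equal mixing
#'
#' Component-wise arithmetic mean of the donor concentrations, the model
#' of pipetting equal volumes. The pool's `sex` label is `pool_female`,
#' `pool_male` or `pool_mixed` according to the members.
#'
#' @param donors Tibble of donor rows as from [make_donor()].
#' @param pool_id Identifier for the pooled profile.
#' @return One-row donor tibble.
#' @export
make_pool <- function(donors, pool_id = "pool") {
  if (nrow(donors) == 0) {
    rlang::abort("cannot pool zero donors", class = "ramantdm_domain")
  }
  comp <- setdiff(names(donors), c("donor_id", "sex"))
  sexes <- unique(donors$sex)
  label <- if (identical(sexes, "female")) "pool_female"
           else if (identical(sexes, "male")) "pool_male"
           else "pool_mixed"
  out <- tibble::tibble(donor_id = pool_id, sex = label)
  for (cc in comp) out[[cc]] <- mean(donors[[cc]])
  out
}

# deterministic part of the forward model (chemistry + drug + baseline)
.render_clean <- function(profile, drug_uM, config) {
  g <- config$grid
  w <- seq(g[1], g[2], by = g[3])
  bt <- config$band_table
  y <- numeric(length(w))
  comp_names <- setdiff(names(profile), c("donor_id", "sex"))
  for (cc in comp_names) {
    bands <- bt[bt$component == cc, ]
    for (i in seq_len(nrow(bands))) {
      y <- y + profile[[cc]][1] * bands$rel_intensity[i] *
        exp(-(w - bands$center[i])^2 / (2 * bands$sigma[i]^2))
    }
  }
  drug_bands <- bt[bt$component == "piperacillin", ]
  for (i in seq_len(nrow(drug_bands))) {
    y <- y + drug_uM * config$drug_response * drug_bands$rel_intensity[i] *
      exp(-(w - drug_bands$center[i])^2 / (2 * drug_bands$sigma[i]^2))
  }
  bl <- config$baseline
  t01 <- (w - g[1]) / (g[2] - g[1])
  base <- bl$coef[1] + bl$coef[2] * t01 +
    bl$hump_amplitude * exp(-(w - bl$hump_center)^2 / (2 * bl$hump_sigma^2))
  list(wavenumber = w, signal = y + base)
}

#' Render one synthetic spectrum
#'
#' Forward model: sum of concentration-weighted Gaussian matrix bands,
#' plus the piperacillin bands with amplitude exactly linear in
#' concentration, plus a smooth baseline, an affine per-spectrum scatter
#' distortion (gain x signal + offset) and additive white noise. The
#' stochastic parts draw from the current RNG state; the experiment-level
#' generators wrap calls in named seeded streams.
#'
#' @param profile One-row donor tibble.
#' @param drug_uM Piperacillin concentration, micromolar, >= 0.
#' @param config A [synth_config()].
#' @param sample_id,replicate Metadata stamped on the output.
#' @param stochastic Apply scatter and noise? `FALSE` gives the pure
#'   deterministic forward model.
#' @return A one-spectrum spectra table.
#' @export
render_spectrum <- function(profile, drug_uM, config, sample_id = "s1",
                            replicate = 1L, stochastic = TRUE) {
  if (drug_uM < 0) {
    rlang::abort("drug concentration must be >= 0", class = "ramantdm_domain")
  }
  clean <- .render_clean(profile, drug_uM, config)
  y <- clean$signal
  if (stochastic) {
    gain <- max(1 + stats::rnorm(1, 0, config$scatter[["gain_sd"]]), 0.05)
    offset <- stats::rnorm(1, 0, config$scatter[["offset_sd"]])
    y <- gain * y + offset + stats::rnorm(length(y), 0, config$noise_sd)
  }
  tibble::tibble(sample_id = sample_id, replicate = as.integer(replicate),
                 wavenumber = clean$wavenumber, intensity = y,
                 sex = profile$sex[1], treatment = "none",
                 concentration_uM = drug_uM, role = "sample")
}

# render a block of replicates for one (sample, concentration)
.render_sample <- function(profile, drug_uM, config, sample_id, n_rep,
                           stream, role = "sample", treatment = "none",
                           set_uM = drug_uM, comp_jitter_cv = 0) {
  comp_cols <- setdiff(names(profile), c("donor_id", "sex"))
  .with_stream(config$seed, stream, {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      prof_r <- profile
      if (comp_jitter_cv > 0) {
        sdl <- sqrt(log(1 + comp_jitter_cv^2))
        for (cc in comp_cols) {
          prof_r[[cc]] <- prof_r[[cc]] * stats::rlnorm(1, -sdl^2 / 2, sdl)
        }
      }
      sp <- render_spectrum(prof_r, drug_uM, config, sample_id = sample_id,
                            replicate = r, stochastic = TRUE)
      sp$role <- role
      sp$treatment <- treatment
      sp$concentration_uM <- set_uM
      sp
    })
  })
}

#' Generate a paired reference/treated calibration experiment
#'
#' Emulates the treatment-loss design: reference samples are spiked after
#' treatment (so they carry the nominal concentrations), while treated
#' samples are spiked before treatment, which scales their effective
#' concentration to `(1 - f) x nominal` with `f` the configured loss
#' factor of the treatment. Both series share one female urine matrix and
#' get `replicates_quant` replicate spectra per level; the treated
#' samples' `concentration_uM` metadata records the nominal (set) value.
#'
#' @param config A [synth_config()].
#' @param treatment One of the configured treatment codes.
#' @param concentrations Nominal spike levels, micromolar.
#' @return List of two spectra tables: `reference` and `treated`.
#' @export
generate_factor_experiment <- function(config, treatment,
                                       concentrations = c(0, 100, 250, 500,
                                                          750, 1000, 1500,
                                                          2000)) {
  if (!treatment %in% names(config$treatment_factors)) {
    rlang::abort(paste0("unknown treatment: ", treatment),
                 class = "ramantdm_config")
  }
  f <- config$treatment_factors[[treatment]]
  trt_i <- match(treatment, names(config$treatment_factors))
  donor <- make_donor(config, "female", index = 1000 + trt_i)
  n_rep <- config$replicates_quant
  reference <- purrr::imap_dfr(concentrations, function(cc, i) {
    .render_sample(donor, cc, config, sprintf("ref_%02d", i), n_rep,
                   stream = .stream_id(21, trt_i, i), role = "reference")
  })
  treated <- purrr::imap_dfr(concentrations, function(cc, i) {
    .render_sample(donor, (1 - f) * cc, config, sprintf("trt_%02d", i), n_rep,
                   stream = .stream_id(22, trt_i, i), role = "sample",
                   treatment = treatment, set_uM = cc)
  })
  list(reference = as_spectra(reference), treated = as_spectra(treated))
}

# latent donor state of the structured cohort: ring radius r, angle
# theta (stratified around the circle so small cohorts cover the ring;
# outer-shell males cluster in one angular sector so no donor is
# isolated from its class under donor-grouped CV splits), and a urea
# level carrying a modest sex mean shift
.donor_latent <- function(config, sex, index, n_of_sex) {
  ann <- config$annulus
  sector0 <- .with_stream(config$seed, 30, stats::runif(1, 0, 2 * pi))
  n_core <- ceiling(n_of_sex * 0.55)
  .with_stream(config$seed, .stream_id(31, match(sex, c("female", "male")), index), {
    if (sex == "female") {
      theta <- 2 * pi * (index - 1 + stats::runif(1)) / n_of_sex
      r <- stats::runif(1, ann$female_radius[1], ann$female_radius[2])
    } else if (index <= n_core) {
      theta <- 2 * pi * (index - 1 + stats::runif(1)) / n_core
      r <- stats::runif(1, ann$male_core[1], ann$male_core[2])
    } else {
      n_outer <- n_of_sex - n_core
      sector <- ann$outer_sector %||% 0.6
      theta <- sector0 +
        sector * (index - n_core - 1 + stats::runif(1)) / n_outer
      r <- stats::runif(1, ann$male_outer[1], ann$male_outer[2])
    }
    cv <- ann$urea_cv %||% 0.02
    gap <- ann$urea_sex_gap %||% 0.025
    urea_mu <- (ann$urea_mean %||% 1.05) *
      (1 + if (sex == "male") gap / 2 else -gap / 2)
    urea <- if (cv == 0) urea_mu else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(1, log(urea_mu) - sdlog^2 / 2, sdlog)
    }
    list(r = r, theta = theta, urea = urea)
  })
}

# deterministic map from latent state to matrix composition. The ring
# and its complement share one center (the cross-sex mean creatinine /
# uric acid composition) so the radial geometry is concentric; the
# sex-neutral minor components follow the squared radius, keeping the
# higher principal components donor-structured without handing linear
# classifiers a second independent radial coordinate
.composition_from_latent <- function(config, sex, latent, donor_id) {
  center <- (config$composition_means$female +
               config$composition_means$male) / 2
  s <- config$annulus$scale
  r <- latent$r; theta <- latent$theta
  out <- tibble::tibble(
    donor_id = donor_id, sex = sex,
    urea = latent$urea,
    creatinine = center[["creatinine"]] * max(1 + s * r * cos(theta), 0.05),
    uric_acid  = center[["uric_acid"]]  * max(1 + s * r * sin(theta), 0.05)
  )
  minors <- setdiff(names(center), c("urea", "creatinine", "uric_acid"))
  coefs <- c(1, -0.6, 0.3, -0.2)
  for (j in seq_along(minors)) {
    out[[minors[j]]] <- center[[minors[j]]] *
      max(1 + 0.4 * s * coefs[((j - 1) %% length(coefs)) + 1] * r^2, 0.05)
  }
  out
}

.make_structured_donor <- function(config, sex, index, n_of_sex) {
  latent <- .donor_latent(config, sex, index, n_of_sex)
  .composition_from_latent(config, sex, latent,
                           paste0(substr(sex, 1, 1), index))
}

#' Generate the sex-classification cohort
#'
#' Renders `replicates_class` spectra (no drug) for each of `n_female`
#' female and `n_male` male donors. With `structure = TRUE` (default) the
#' sexes differ both in mean composition and through a nonlinear
#' geometry: in the plane of the two log concentration ratios
#' creatinine/urea and uric acid/urea, female donors occupy a bounded
#' annulus and male donors its complement (inner core or outer shell), so
#' no linear boundary separates the classes but a radial one does. With
#' `structure = FALSE` donors are plain [make_donor()] draws.
#'
#' @param config A [synth_config()].
#' @param n_female,n_male Donor counts (>= 1).
#' @param structure Enable the nonlinear class geometry?
#' @return A spectra table with `sex` metadata, one sample per donor.
#' @export
generate_classification_cohort <- function(config, n_female = 8, n_male = 9,
                                           structure = TRUE) {
  stopifnot(n_female >= 1, n_male >= 1)
  if (!structure) {
    donors <- dplyr::bind_rows(
      purrr::map_dfr(seq_len(n_female), function(i)
        make_donor(config, "female", index = i)),
      purrr::map_dfr(seq_len(n_male), function(i)
        make_donor(config, "male", index = i))
    )
    out <- purrr::map_dfr(seq_len(nrow(donors)), function(i) {
      .render_sample(donors[i, ], 0, config, donors$donor_id[i],
                     config$replicates_class,
                     stream = .stream_id(32, i), role = "sample")
    })
    return(as_spectra(out))
  }
  jit <- config$annulus$theta_jitter %||% 0.25
  plan <- dplyr::bind_rows(
    tibble::tibble(sex = "female", index = seq_len(n_female), n = n_female),
    tibble::tibble(sex = "male", index = seq_len(n_male), n = n_male)
  )
  out <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    sex <- plan$sex[i]
    latent <- .donor_latent(config, sex, plan$index[i], plan$n[i])
    donor_id <- paste0(substr(sex, 1, 1), plan$index[i])
    # replicates vary tangentially (along the ring) only: aliquot-level
    # compositional drift that bridges the angular gaps between donors
    # without eroding the radial class margins
    .with_stream(config$seed, .stream_id(32, i), {
      purrr::map_dfr(seq_len(config$replicates_class), function(rep_i) {
        lat_r <- latent
        lat_r$theta <- latent$theta + stats::rnorm(1, 0, jit)
        prof <- .composition_from_latent(config, sex, lat_r, donor_id)
        render_spectrum(prof, 0, config, sample_id = donor_id,
                        replicate = rep_i, stochastic = TRUE)
      })
    })
  })
  as_spectra(out)
}
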