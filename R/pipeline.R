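.provenance <- function(config, parameters = list()) {
  list(config_hash = rlang::hash(unclass(config)), seed = config$seed,
       package_version = as.character(utils::packageVersion("ramantdm")),
       parameters = parameters)
}

#' Treatment-loss experiment on synthetic spectra
#'
#' For each treatment: generate the paired reference/treated calibration
#' series, run the full conditioning chain, narrow to the PLS window
#' (1150-1750 cm^-1) and vector normalize, fit a PLS model on the
#' untreated references with cross-validated component selection, predict
#' the treated spectra, and estimate the correction factor with its
#' cross-validated dispersion. One report row per treatment, shaped like
#' a published correction-factor table.
#'
#' @param config A [synth_config()]; its `treatment_factors` are the
#'   ground truth the pipeline should recover.
#' @param treatments Treatment codes to run (default: all configured
#'   except `none`).
#' @param concentrations Calibration levels, micromolar.
#' @param candidates,folds PLS component selection (see [select_ncomp()]).
#' @param cv_repeats Subsets for [factor_cv()] (default 10).
#' @return A tibble: `treatment`, `factor_pct`, `factor_mad_pct`,
#'   `rmsep_before_uM`, `rmsep_after_uM`, `n`, `n_components`, plus a
#'   `provenance` attribute (config hash, seed, package version).
#' @export
run_factor_experiment <- function(config,
                                  treatments = setdiff(
                                    names(config$treatment_factors), "none"),
                                  concentrations = c(0, 100, 250, 500, 750,
                                                     1000, 1500, 2000),
                                  candidates = 3:5, folds = 50,
                                  cv_repeats = 10) {
  if (length(unique(concentrations)) < 4) {
    rlang::abort("need >= 4 concentration levels", class = "ramantdm_config")
  }
  rows <- purrr::imap_dfr(stats::setNames(treatments, treatments),
                          function(trt, nm) {
    ti <- match(trt, names(config$treatment_factors))
    exp <- generate_factor_experiment(config, trt, concentrations)
    condition <- function(x) {
      preprocess_spectra(x) |>
        truncate_spectra(1150, 1750) |>
        normalize_spectra("vector")
    }
    ref <- condition(exp$reference)
    trt_sp <- condition(exp$treated)
    model <- pls_calibration(ref, candidates = candidates, folds = folds,
                             seed = (config$seed + 101 * ti) %% 2147483647)
    m <- spectra_to_matrix(trt_sp)
    pred <- stats::predict(model, m$intensity)$.pred
    est <- factor_cv(m$meta$concentration_uM, pred, repeats = cv_repeats,
                     seed = (config$seed + 211 * ti) %% 2147483647,
                     treatment = trt)
    dplyr::mutate(tidy(est), n_components = model$n_components)
  })
  attr(rows, "provenance") <- .provenance(config, list(
    concentrations = concentrations, candidates = candidates, folds = folds,
    cv_repeats = cv_repeats))
  rows
}

#' Donor-sex classification experiment on synthetic spectra
#'
#' Generates the classification cohort, runs the conditioning chain plus
#' vector normalization, reduces to `n_pcs` principal components, and
#' cross-validates each classifier with `k` repeated donor-grouped 80/20
#' splits, summarizing threshold-averaged ROC curves and AUCs.
#'
#' @param config A [synth_config()].
#' @param n_female,n_male Donor counts.
#' @param kinds Classifiers to run.
#' @param n_pcs Principal components kept (default 5).
#' @param k Cross-validation repeats (default 20).
#' @param structure Nonlinear class geometry on? (see
#'   [generate_classification_cohort()]).
#' @param shuffle_labels Permute donor sexes (null experiment)?
#' @return A `classification_report`: `summary` tibble (`classifier`,
#'   `auc_mean`, `auc_sd`), `roc` (named list of `roc_summary`), `pca`,
#'   and `provenance`.
#' @export
run_classification_experiment <- function(config, n_female = 8, n_male = 9,
                                          kinds = c("lda", "svm_linear",
                                                    "svm_radial"),
                                          n_pcs = 5, k = 20,
                                          structure = TRUE,
                                          shuffle_labels = FALSE) {
  cohort <- generate_classification_cohort(config, n_female, n_male,
                                           structure = structure)
  pre <- preprocess_spectra(cohort) |> normalize_spectra("vector")
  m <- spectra_to_matrix(pre)
  groups <- m$meta$sample_id
  labels <- factor(m$meta$sex)
  if (shuffle_labels) {
    donors <- unique(groups)
    donor_sex <- vapply(donors, function(d)
      as.character(labels[match(d, groups)]), character(1))
    perm <- .with_stream(config$seed, 390, sample(donor_sex))
    labels <- factor(perm[match(groups, donors)])
  }
  pca <- pca_reduce(m$intensity, n_pcs = n_pcs, wavenumber = m$wavenumber)
  rocs <- purrr::imap(stats::setNames(kinds, kinds), function(kind, nm) {
    ki <- match(kind, c("lda", "svm_linear", "svm_radial"))
    cv <- cross_validate_classifier(pca$scores, labels, groups, kind = kind,
                                    k = k,
                                    seed = (config$seed + 307 * ki) %%
                                      2147483647)
    threshold_averaged_roc(cv)
  })
  summary <- purrr::imap_dfr(rocs, function(r, nm) {
    tibble::tibble(classifier = nm, auc_mean = r$auc_mean, auc_sd = r$auc_sd)
  })
  structure(list(summary = summary, roc = rocs, pca = pca,
                 provenance = .provenance(config, list(
                   n_female = n_female, n_male = n_male, n_pcs = n_pcs,
                   k = k, structure = structure,
                   shuffle_labels = shuffle_labels))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Sex-classification experiment (threshold-averaged ROC)\n")
  print(x$summary)
  invisible(x)
}

#' Reference-matrix quantification experiment on synthetic spectra
#'
#' A piperacillin dilution series in one female donor's urine is
#' quantified by marker-band fitting against four reference matrices: the
#' donor's own urine, a female pool, a male pool, and a mixed pool. Each
#' series/reference pair yields a calibration curve and ICH detection
#' limits; the report mirrors a published LoD comparison table, with the
#' percent deviation of each pool LoD from the own-matrix LoD.
#'
#' @param config A [synth_config()].
#' @param concentrations Dilution series, micromolar.
#' @param n_female,n_male Pool donor counts.
#' @param molar_mass g/mol for the mg/L columns (default sodium salt).
#' @return A tibble: `reference`, `slope`, `sigma_n`, `r_squared`,
#'   `lod_uM`, `lod_mgL`, `loq_uM`, `loq_mgL`, `deviation_pct`; attributes
#'   `curves` (named list of `calibration_curve`) and `provenance`.
#' @export
run_reference_experiment <- function(config,
                                     concentrations = c(0, 100, 250, 500,
                                                        750, 1000, 1500,
                                                        2000),
                                     n_female = 8, n_male = 9,
                                     molar_mass = 539.5) {
  females <- purrr::map_dfr(seq_len(n_female), function(i)
    make_donor(config, "female", index = i))
  males <- purrr::map_dfr(seq_len(n_male), function(i)
    make_donor(config, "male", index = i))
  own <- females[1, ]
  refs <- list(
    own = own,
    pool_female = make_pool(females, "pool_female"),
    pool_male = make_pool(males, "pool_male"),
    pool_mixed = make_pool(dplyr::bind_rows(females, males), "pool_mixed")
  )
  n_rep <- config$replicates_quant
  series <- purrr::imap_dfr(concentrations, function(cc, i) {
    .render_sample(own, cc, config, sprintf("series_%02d", i), n_rep,
                   stream = .stream_id(41, i), role = "sample")
  })
  ref_sp <- purrr::imap_dfr(refs, function(profile, nm) {
    ri <- match(nm, names(refs))
    .render_sample(profile, 0, config, paste0("ref_", nm), n_rep,
                   stream = .stream_id(42, ri), role = "reference")
  })
  all_pre <- preprocess_spectra(dplyr::bind_rows(series, ref_sp))
  med <- median_spectrum(all_pre) |> normalize_spectra("max_at")
  series_med <- dplyr::filter(med, startsWith(.data$sample_id, "series_"))
  curves <- purrr::imap(refs, function(profile, nm) {
    ref_med <- dplyr::filter(med, .data$sample_id == paste0("ref_", nm))
    diffs <- difference_spectrum(series_med, ref_med)
    dm <- spectra_to_matrix(diffs)
    amps <- vapply(seq_len(nrow(dm$meta)), function(i) {
      fit_marker_band(matrix_to_spectra(dm$wavenumber,
                                        dm$intensity[i, , drop = FALSE],
                                        dm$meta[i, ]))$amplitude
    }, numeric(1))
    build_calibration(dm$meta$concentration_uM, amps, reference = nm)
  })
  lod_own <- curves$own$lod_uM
  report <- purrr::imap_dfr(curves, function(cv, nm) {
    dplyr::mutate(glance(cv),
                  lod_mgL = umol_to_mgL(.data$lod_uM, molar_mass),
                  loq_mgL = umol_to_mgL(.data$loq_uM, molar_mass),
                  deviation_pct = percent_deviation(.data$lod_uM, lod_own))
  })
  attr(report, "curves") <- curves
  attr(report, "provenance") <- .provenance(config, list(
    concentrations = concentrations, n_female = n_female, n_male = n_male,
    molar_mass = molar_mass))
  report
}
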