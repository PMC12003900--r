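#' @importFrom rlang .data abort %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct across left_join bind_rows n first
#' @importFrom tibble tibble as_tibble
NULL

# canonical spectra-table columns; everything else is carried metadata
.spectra_cols <- c("sample_id", "replicate", "wavenumber", "intensity")
.meta_cols    <- c("sex", "treatment", "concentration_uM", "role")

.sex_levels       <- c("female", "male", "pool_female", "pool_male",
                       "pool_mixed", "unknown")
.treatment_levels <- c("none", "froz", "filt", "cent", "filt_cent")

#' Validate and canonicalize a spectra table
#'
#' A spectra table is a long tibble with one row per spectral channel:
#' columns `sample_id`, `replicate`, `wavenumber` (cm^-1), `intensity`
#' (detector counts, a.u.; may be negative after preprocessing), plus
#' optional metadata columns `sex`, `treatment`, `concentration_uM`, `role`.
#' Channels are sorted to strictly increasing wavenumber within each
#' spectrum; additional columns are preserved untouched.
#'
#' @param data A data frame with at least the four canonical columns.
#' @return A tibble sorted by sample, replicate and wavenumber.
#' @export
as_spectra <- function(data) {
  data <- as_tibble(data)
  missing <- setdiff(.spectra_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("spectra table is missing column(s): ",
                 paste(missing, collapse = ", ")), class = "ramantdm_format")
  }
  for (col in c("wavenumber", "intensity")) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))
      abort(paste0("non-numeric value in column '", col, "' at row ",
                   if (length(bad)) bad[1] else "?"),
            class = "ramantdm_parse")
    }
  }
  data$sample_id <- as.character(data$sample_id)
  data$replicate <- as.integer(data$replicate)
  if ("treatment" %in% names(data)) {
    bad <- setdiff(unique(stats::na.omit(data$treatment)), .treatment_levels)
    if (length(bad) > 0) {
      abort(paste0("unknown treatment code(s): ", paste(bad, collapse = ", ")),
            class = "ramantdm_integrity")
    }
  }
  data <- arrange(data, .data$sample_id, .data$replicate, .data$wavenumber)
  dup <- data |>
    group_by(.data$sample_id, .data$replicate) |>
    summarise(dup = anyDuplicated(.data$wavenumber) > 0, .groups = "drop")
  if (any(dup$dup)) {
    bad <- dup[dup$dup, ]
    abort(paste0("duplicate (sample_id, replicate) channel data for ",
                 bad$sample_id[1], " replicate ", bad$replicate[1]),
          class = "ramantdm_integrity")
  }
  n_chan <- data |>
    group_by(.data$sample_id, .data$replicate) |>
    summarise(n = dplyr::n(), .groups = "drop")
  if (any(n_chan$n < 2)) {
    abort("each spectrum needs at least 2 channels", class = "ramantdm_format")
  }
  data
}

#' Convert a spectra table to an intensity matrix
#'
#' All spectra must share one wavenumber axis (relative tolerance 1e-9).
#'
#' @param data A spectra table.
#' @return A list with `wavenumber` (length-p axis), `intensity`
#'   (n_spectra x p matrix) and `meta` (one row per spectrum, canonical and
#'   carried metadata columns, row order matching the matrix).
#' @export
spectra_to_matrix <- function(data) {
  data <- as_spectra(data)
  key <- paste(data$sample_id, data$replicate, sep = "\r")
  idx <- split(seq_len(nrow(data)), factor(key, levels = unique(key)))
  w0 <- data$wavenumber[idx[[1]]]
  scale <- pmax(abs(w0), 1)
  X <- matrix(NA_real_, nrow = length(idx), ncol = length(w0))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    if (length(rows) != length(w0) ||
        any(abs(data$wavenumber[rows] - w0) > 1e-9 * scale)) {
      abort("spectra do not share a common wavenumber axis; resample first",
            class = "ramantdm_axis")
    }
    X[i, ] <- data$intensity[rows]
  }
  meta <- data[vapply(idx, `[`, integer(1), 1),
               setdiff(names(data), c("wavenumber", "intensity"))]
  list(wavenumber = w0, intensity = X, meta = as_tibble(meta))
}

#' Rebuild a spectra table from an intensity matrix
#'
#' @param wavenumber Common axis (cm^-1).
#' @param intensity n_spectra x p matrix.
#' @param meta One metadata row per spectrum.
#' @return A spectra table.
#' @export
matrix_to_spectra <- function(wavenumber, intensity, meta) {
  stopifnot(nrow(intensity) == nrow(meta), ncol(intensity) == length(wavenumber))
  out <- meta[rep(seq_len(nrow(meta)), each = length(wavenumber)), , drop = FALSE]
  out$wavenumber <- rep(wavenumber, times = nrow(meta))
  out$intensity <- as.vector(t(intensity))
  as_spectra(out)
}

#' Read spectra from delimited text
#'
#' Two dialects are supported. `long_csv` holds one row per channel with
#' columns `sample_id,replicate,wavenumber_cm1,intensity`; sample-level
#' metadata may live in a sidecar table (columns
#' `sample_id,sex,treatment,concentration_uM,role`), either passed via
#' `metadata` or discovered as `samples.csv` next to `path`. `wide_csv`
#' has a `wavenumber_cm1` first column and one `sample_id.replicate`
#' column per spectrum.
#'
#' @param path Path to the spectra file.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @param metadata Optional path or data frame with sample metadata.
#' @return A spectra table (see [as_spectra()]).
#' @export
read_spectra <- function(path, dialect = c("long_csv", "wide_csv"),
                         metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ramantdm_io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (dialect == "long_csv") {
    need <- c("sample_id", "replicate", "wavenumber_cm1", "intensity")
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      abort(paste0("missing column(s) in ", path, ": ",
                   paste(missing, collapse = ", ")), class = "ramantdm_format")
    }
    data <- tibble(
      sample_id  = raw$sample_id,
      replicate  = .parse_num(raw$replicate, "replicate"),
      wavenumber = .parse_num(raw$wavenumber_cm1, "wavenumber_cm1"),
      intensity  = .parse_num(raw$intensity, "intensity")
    )
    extra <- setdiff(names(raw), need)
    for (col in extra) data[[col]] <- raw[[col]]
  } else {
    if (!"wavenumber_cm1" %in% names(raw)) {
      abort(paste0("missing column(s) in ", path, ": wavenumber_cm1"),
            class = "ramantdm_format")
    }
    if (ncol(raw) < 2) {
      abort("wide_csv file holds no intensity columns",
            class = "ramantdm_format")
    }
    w <- .parse_num(raw$wavenumber_cm1, "wavenumber_cm1")
    cols <- setdiff(names(raw), "wavenumber_cm1")
    parts <- regmatches(cols, regexpr("\\.[0-9]+$", cols))
    if (length(parts) != length(cols)) {
      abort("wide_csv column names must look like <sample_id>.<replicate>",
            class = "ramantdm_format")
    }
    data <- purrr::map_dfr(cols, function(col) {
      rep_i <- as.integer(sub("^.*\\.", "", col))
      tibble(sample_id  = sub("\\.[0-9]+$", "", col),
             replicate  = rep_i,
             wavenumber = w,
             intensity  = .parse_num(raw[[col]], col))
    })
  }
  if (is.null(metadata)) {
    sidecar <- file.path(dirname(path), "samples.csv")
    if (file.exists(sidecar)) metadata <- sidecar
  }
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) {
      readr::read_csv(metadata, col_types = readr::cols(
        sample_id = "c", sex = "c", treatment = "c",
        concentration_uM = "d", role = "c", .default = "c"
      ), progress = FALSE)
    } else as_tibble(metadata)
    if (!"sample_id" %in% names(md)) {
      abort("metadata table needs a sample_id column",
            class = "ramantdm_format")
    }
    md$sample_id <- as.character(md$sample_id)
    data <- left_join(data, md, by = "sample_id")
  }
  as_spectra(data)
}

.parse_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad) > 0) {
    abort(paste0("non-numeric value '", x[bad[1]], "' in column '", col,
                 "' at data row ", bad[1]), class = "ramantdm_parse")
  }
  out
}

#' Write spectra to delimited text
#'
#' Column order is deterministic and doubles are rendered at full
#' round-trip precision, so `read_spectra(write_spectra(x))` reproduces
#' `x` bit-for-bit. For `long_csv` the sample metadata columns are split
#' into a `samples.csv` sidecar next to `path`.
#'
#' @inheritParams read_spectra
#' @param data A spectra table.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path, dialect = c("long_csv", "wide_csv")) {
  dialect <- match.arg(dialect)
  if (nrow(data) > 0) data <- as_spectra(data)
  if (dialect == "long_csv") {
    out <- tibble(sample_id = character(), replicate = integer(),
                  wavenumber_cm1 = double(), intensity = double())
    if (nrow(data) > 0) {
      out <- tibble(sample_id = data$sample_id, replicate = data$replicate,
                    wavenumber_cm1 = data$wavenumber,
                    intensity = data$intensity)
    }
    readr::write_csv(out, path, progress = FALSE)
    md_cols <- intersect(.meta_cols, names(data))
    if (length(md_cols) > 0) {
      md <- distinct(data[, c("sample_id", md_cols)])
      readr::write_csv(md, file.path(dirname(path), "samples.csv"),
                       progress = FALSE)
    }
  } else {
    if (nrow(data) == 0) {
      readr::write_csv(tibble(wavenumber_cm1 = double()), path,
                       progress = FALSE)
      return(invisible(path))
    }
    m <- spectra_to_matrix(data) # errors if axes differ: resample first
    out <- tibble(wavenumber_cm1 = m$wavenumber)
    for (i in seq_len(nrow(m$meta))) {
      out[[paste0(m$meta$sample_id[i], ".", m$meta$replicate[i])]] <-
        m$intensity[i, ]
    }
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Channel-wise median spectrum per sample
#'
#' Reduces the replicates of each sample to their channel-wise median
#' (even replicate counts average the two central values). The median
#' spectrum carries the sample's metadata with `replicate = 0`.
#'
#' @param data A spectra table; replicates of a sample must share an axis.
#' @return A spectra table with one spectrum per sample.
#' @export
median_spectrum <- function(data) {
  data <- as_spectra(data)
  keep <- setdiff(names(data), c("replicate", "wavenumber", "intensity"))
  out <- data |>
    group_by(.data$sample_id, .data$wavenumber) |>
    summarise(n_rep = dplyr::n(),
              across(dplyr::all_of(setdiff(keep, "sample_id")), first),
              intensity = stats::median(.data$intensity),
              .groups = "drop")
  n_rep_per_sample <- out |>
    group_by(.data$sample_id) |>
    summarise(u = length(unique(.data$n_rep)), .groups = "drop")
  if (any(n_rep_per_sample$u > 1)) {
    abort("replicates of one sample do not share a wavenumber axis",
          class = "ramantdm_axis")
  }
  out$replicate <- 0L
  out$n_rep <- NULL
  as_spectra(out)
}
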