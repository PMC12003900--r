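# small in-code fixtures shared across tests

# one synthetic spectrum as a spectra tibble
toy_spectrum <- function(w = seq(800, 1800, 2), y = NULL, id = "s1", rep = 1L,
                         ...) {
  y <- y %||% exp(-(w - 1200)^2 / (2 * 64))
  extra <- list(...)
  out <- tibble::tibble(sample_id = id, replicate = as.integer(rep),
                        wavenumber = w, intensity = y)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# n replicates of a sample with per-replicate intensities in a list
toy_group <- function(ys, w = seq(800, 1800, 2), id = "s1") {
  purrr::imap_dfr(ys, function(y, i) toy_spectrum(w, y, id = id, rep = i))
}

# quick config with near-ideal measurement conditions for unit tests
quiet_config <- function(seed = 42, ...) {
  synth_config(seed = seed, noise_sd = 0,
               scatter = c(gain_sd = 0, offset_sd = 0), ...)
}

`%||%` <- rlang::`%||%`
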