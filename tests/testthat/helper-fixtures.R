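# Shared fixtures built in code: tiny tracks, interval sets and simulator
# configurations used across the test files.

# A minimal single-chromosome track with the given values on a 300-bp grid.
toy_track <- function(values, chrom = "chr2L", spacing = 300) {
  n <- length(values)
  tibble::tibble(chrom = chrom,
                 start = (seq_len(n) - 1L) * spacing,
                 end = (seq_len(n) - 1L) * spacing + 60L,
                 value = values)
}

toy_replicates <- function(v1, v2, chrom = "chr2L", spacing = 300) {
  tr <- toy_track(v1, chrom, spacing)
  tr$value_1 <- tr$value
  tr$value_2 <- v2
  tr$value <- NULL
  tr
}

# Simulator configuration used by most integration-style tests: two 4-Mb
# chromosomes, 20 LADs of ~120 kb, 100 separated peaks.
test_sim_config <- function(seed, ...) {
  sim_config(chrom_lengths = c(chrA = 4e6, chrB = 4e6),
             n_lads = 20, lad_size_meanlog = log(1.2e5),
             lad_size_sdlog = 0.3, n_peaks = 100, seed = seed, ...)
}

# Brute-force running-window statistic with shrinking symmetric windows.
brute_window_stat <- function(x, window, fun) {
  half <- (window - 1) %/% 2
  sapply(seq_along(x), function(i) {
    v <- x[max(1, i - half):min(length(x), i + half)]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fun(v)
  })
}
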