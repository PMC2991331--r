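# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map2 pmap list_rbind
NULL

# Columns of a probe-track tibble that hold log2-ratio values (everything
# numeric that is not a coordinate).
track_value_cols <- function(track) {
  cand <- setdiff(names(track), c("chrom", "start", "end"))
  cand[vapply(track[cand], is.numeric, logical(1))]
}

probe_centers <- function(track) (track$start + track$end) / 2

assert_track <- function(track, n_values = 1L, arg = "track") {
  if (!is.data.frame(track) || !all(c("chrom", "start", "end") %in% names(track))) {
    abort(sprintf("`%s` must be a data frame with columns chrom/start/end", arg))
  }
  vals <- track_value_cols(track)
  if (length(vals) < n_values) {
    abort(sprintf("`%s` needs at least %d value column(s), found %d",
                  arg, n_values, length(vals)))
  }
  invisible(vals)
}

assert_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom/start/end", arg))
  }
  if (any(x$end < x$start)) abort(sprintf("`%s` has records with end < start", arg))
  invisible(x)
}

# Sort a track (or interval set) per chromosome by start.
sort_genomic <- function(x) dplyr::arrange(x, .data$chrom, .data$start)

is_sorted_genomic <- function(x) {
  !is.unsorted(order(x$chrom, x$start))
  # order() trick is O(n log n); cheap enough for our sizes
}

# Running window statistic with shrinking symmetric windows at the edges.
# Missing values are excluded; an all-missing window yields NA.
run_window_stat <- function(x, window, fun = stats::median) {
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    v <- x[max(1L, i - half):min(n, i + half)]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else fun(v)
  }, numeric(1))
  out
}

check_odd_window <- function(window, arg = "window") {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2L != 1L) {
    abort(sprintf("`%s` must be a single odd integer >= 1 (got %s)",
                  arg, paste(window, collapse = ",")))
  }
  as.integer(window)
}

# GRanges from an interval tibble in internal 0-based half-open coordinates.
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}
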