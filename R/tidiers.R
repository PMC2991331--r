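#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation enrichment result
#'
#' @param x a `lads_enrichment` object from [permutation_enrichment()].
#' @param ... ignored.
#' @return a one-row tibble with the observed and expected fractions, the
#'   permutation p-value, direction and bookkeeping columns.
#' @export
tidy.lads_enrichment <- function(x, ...) {
  tibble(observed_fraction = x$observed_fraction,
         expected_fraction = x$expected_fraction,
         p_value = x$p_value,
         direction = x$direction,
         n_peaks = x$n_peaks,
         n_permutations = x$n_permutations,
         seed = x$seed)
}

#' @rdname tidy.lads_enrichment
#' @export
glance.lads_enrichment <- function(x, ...) tidy(x)

#' Tidy a LAD-class comparison
#'
#' @param x a `lads_class_test` object from [compare_lad_classes()].
#' @param ... ignored.
#' @return the underlying tibble (one row per class pair).
#' @export
tidy.lads_class_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lads_class_test")
  out
}

#' @rdname tidy.lads_class_test
#' @return `glance()`: a one-row tibble with the smallest pairwise p-value
#'   and the number of class pairs tested.
#' @export
glance.lads_class_test <- function(x, ...) {
  tibble(n_comparisons = nrow(x),
         min_p_value = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
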