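#' Border regions just outside LADs
#'
#' Builds the two `width_bp` intervals immediately outside each LAD border.
#' Where a region would run into a neighboring LAD or into the facing
#' border region of a nearby LAD, it is truncated at the midpoint of the
#' gap; at chromosome starts it is clamped at 0.
#'
#' @param lads sorted, non-overlapping LAD interval tibble.
#' @param width_bp border-region width (default 10000, i.e. 10 kb).
#' @return interval tibble of border regions with a `name` column tying
#'   each region to its LAD and side.
#' @export
border_region_set <- function(lads, width_bp = 10000) {
  assert_intervals(lads, "lads")
  if (nrow(lads) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  lads <- sort_genomic(lads)
  lads |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      K <- nrow(g)
      # midpoint truncation applies between LADs; terminal flanks are only
      # clamped at the chromosome start
      gap_before <- c(Inf, g$start[-1] - g$end[-K])
      gap_after <- c(g$start[-1] - g$end[-K], Inf)
      left <- tibble(
        chrom = key$chrom,
        start = pmax(g$start - width_bp, g$start - floor(gap_before / 2), 0),
        end = g$start,
        name = sprintf("border_L_%s_%d", key$chrom, seq_len(K)))
      right <- tibble(
        chrom = key$chrom,
        start = g$end,
        end = pmin(g$end + width_bp, g$end + floor(gap_after / 2)),
        name = sprintf("border_R_%s_%d", key$chrom, seq_len(K)))
      bind_rows(left, right) |> filter(.data$end > .data$start)
    }) |>
    list_rbind() |>
    sort_genomic()
}

#' Fraction of peak centers inside a region set
#'
#' Intervals are half-open; a center exactly on a region start counts as
#' inside.
#'
#' @param peaks peak tibble (`chrom`, `center`).
#' @param regions interval tibble.
#' @return a single fraction in \[0, 1\].
#' @export
fraction_in_regions <- function(peaks, regions) {
  if (nrow(peaks) == 0L) abort("`peaks` is empty")
  if (nrow(regions) == 0L) return(0)
  assert_intervals(regions, "regions")
  mean(points_in_regions(peaks$chrom, peaks$center, regions))
}

# Merge possibly-overlapping intervals into a per-chromosome sorted
# boundary vector c(s1, e1, s2, e2, ...); a point is inside iff
# findInterval() lands on an odd index (half-open convention).
region_boundaries <- function(regions) {
  lapply(split(regions[, c("start", "end")], regions$chrom), function(r) {
    o <- order(r$start)
    s <- r$start[o]; e <- r$end[o]
    grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
    ms <- s[!duplicated(grp)]
    me <- cummax(e)[!duplicated(grp, fromLast = TRUE)]
    as.vector(rbind(ms, me))
  })
}

# logical vector: is each (chrom, pos) inside any region (half-open)?
points_in_regions <- function(chrom, pos, regions, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
    boundaries <- region_boundaries(regions)
  }
  out <- rep(FALSE, length(pos))
  for (chr in intersect(unique(chrom), names(boundaries))) {
    sel <- chrom == chr
    out[sel] <- findInterval(pos[sel], boundaries[[chr]]) %% 2L == 1L
  }
  out
}

#' Permutation test of peak enrichment in a region set
#'
#' The observed fraction of peaks inside `regions` is compared against
#' `n_permutations` random re-placements of the peak centers, uniform
#' within the probed span of each chromosome with per-chromosome counts
#' preserved. The p-value is `(1 + k) / (n_permutations + 1)` where `k`
#' counts permutations at least as extreme as the observation in the
#' tested direction.
#'
#' @param peaks peak tibble (`chrom`, `center`).
#' @param regions interval tibble (e.g. LADs or border regions).
#' @param probed_spans interval tibble of the probed genome per chromosome
#'   (where peaks may be placed).
#' @param n_permutations number of permutations (default 1000).
#' @param alternative `"enrichment"`, `"depletion"`, or `"auto"` (test in
#'   the observed direction).
#' @param seed integer seed recorded in the result; required for
#'   reproducibility.
#' @return an object of class `lads_enrichment`: a list with
#'   `observed_fraction`, `expected_fraction`, `p_value`, `direction`,
#'   `n_peaks`, `n_permutations`, `seed` and the permuted fractions.
#' @export
permutation_enrichment <- function(peaks, regions, probed_spans,
                                   n_permutations = 1000,
                                   alternative = c("auto", "enrichment", "depletion"),
                                   seed = 1L) {
  alternative <- match.arg(alternative)
  if (nrow(peaks) == 0L) abort("`peaks` is empty")
  assert_intervals(probed_spans, "probed_spans")
  if (n_permutations < 1L) abort("`n_permutations` must be >= 1")
  reg_gr <- intervals_to_granges(regions)
  span_gr <- GenomicRanges::reduce(intervals_to_granges(probed_spans))
  uncovered <- GenomicRanges::setdiff(GenomicRanges::reduce(reg_gr), span_gr)
  if (sum(IRanges::width(uncovered)) > 0L) {
    abort("`regions` extend outside `probed_spans`")
  }
  observed <- fraction_in_regions(peaks, regions)
  counts <- table(peaks$chrom)
  chroms <- names(counts)
  if (!all(chroms %in% probed_spans$chrom)) {
    abort("peaks on chromosomes without a probed span")
  }
  bnd <- region_boundaries(regions)
  spans <- lapply(chroms, function(chr) {
    sp <- probed_spans[probed_spans$chrom == chr, ]
    w <- sp$end - sp$start
    list(start = sp$start, w = w, cw = cumsum(w))
  })
  names(spans) <- chroms
  n_total <- sum(counts)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(n_permutations), function(i) {
      inside <- 0L
      for (chr in chroms) {
        sp <- spans[[chr]]
        u <- stats::runif(counts[[chr]], 0, sp$cw[length(sp$cw)])
        j <- findInterval(u, c(0, sp$cw[-length(sp$cw)]), left.open = TRUE)
        j <- pmin(pmax(j, 1L), length(sp$w))
        pos <- sp$start[j] + (u - c(0, sp$cw)[j])
        if (!is.null(bnd[[chr]])) {
          inside <- inside + sum(findInterval(pos, bnd[[chr]]) %% 2L == 1L)
        }
      }
      inside / n_total
    }, numeric(1))
  })
  direction <- switch(alternative,
    auto = if (observed >= mean(rng)) "enrichment" else "depletion",
    alternative)
  k <- if (direction == "enrichment") sum(rng >= observed) else sum(rng <= observed)
  res <- list(observed_fraction = observed,
              expected_fraction = mean(rng),
              p_value = (1 + k) / (n_permutations + 1),
              direction = direction,
              n_peaks = nrow(peaks),
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed),
              permuted_fractions = rng)
  class(res) <- "lads_enrichment"
  res
}

#' @export
print.lads_enrichment <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment test (%d peaks, %d permutations, seed %d)\n  observed: %.1f%%  expected: %.1f%%  %s p = %.4g\n",
    x$n_peaks, x$n_permutations, x$seed, 100 * x$observed_fraction,
    100 * x$expected_fraction, x$direction, x$p_value))
  invisible(x)
}

#' Occupancy of the LAD-interior window
#'
#' Among LADs whose half-size is at least `min_half_size_bp`, the fraction
#' with at least one peak in the `window_bp` band measured inward from
#' either border.
#'
#' @param lads LAD interval tibble.
#' @param peaks peak tibble (`chrom`, `center`).
#' @param window_bp two-element inward window, default `c(35000, 45000)`.
#' @param min_half_size_bp minimum LAD half-size, default 45000.
#' @return a single fraction.
#' @export
interior_window_occupancy <- function(lads, peaks,
                                      window_bp = c(35000, 45000),
                                      min_half_size_bp = 45000) {
  assert_intervals(lads, "lads")
  qual <- lads[(lads$end - lads$start) / 2 >= min_half_size_bp, ]
  if (nrow(qual) == 0L) abort("no LADs with half-size >= `min_half_size_bp`")
  occupied <- vapply(seq_len(nrow(qual)), function(i) {
    p <- peaks$center[peaks$chrom == qual$chrom[i]]
    any((p >= qual$start[i] + window_bp[1] & p < qual$start[i] + window_bp[2]) |
        (p > qual$end[i] - window_bp[2] & p <= qual$end[i] - window_bp[1]))
  }, logical(1))
  mean(occupied)
}

#' Association between border and interior-window peak presence
#'
#' For each LAD two indicators are formed — a peak in one of its 10-kb
#' border regions, and a peak in its 35-45 kb interior window — and their
#' association is tested with a two-sided Fisher exact test.
#'
#' @inheritParams interior_window_occupancy
#' @param border_width_bp border-region width (default 10000).
#' @return a one-row tibble: the 2x2 table counts (`n11`, `n10`, `n01`,
#'   `n00`), `odds_ratio` and `p_value`.
#' @export
border_interior_association <- function(lads, peaks, border_width_bp = 10000,
                                        window_bp = c(35000, 45000)) {
  assert_intervals(lads, "lads")
  lads <- sort_genomic(lads)
  borders <- border_region_set(lads, border_width_bp)
  lad_id <- sub("^border_[LR]_", "", borders$name)
  has_border_peak <- rep(FALSE, nrow(lads))
  key <- sprintf("%s_%d", lads$chrom, stats::ave(seq_len(nrow(lads)),
                                                 lads$chrom, FUN = seq_along))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(floor(peaks$center) + 1L,
                                            floor(peaks$center) + 1L)),
    intervals_to_granges(borders))
  has_border_peak[match(lad_id[unique(S4Vectors::subjectHits(hits))], key)] <- TRUE
  has_interior_peak <- vapply(seq_len(nrow(lads)), function(i) {
    p <- peaks$center[peaks$chrom == lads$chrom[i]]
    any((p >= lads$start[i] + window_bp[1] & p < lads$start[i] + window_bp[2]) |
        (p > lads$end[i] - window_bp[2] & p <= lads$end[i] - window_bp[1]))
  }, logical(1))
  tab <- table(factor(has_border_peak, levels = c(TRUE, FALSE)),
               factor(has_interior_peak, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warn("degenerate contingency table (a margin is zero); p = 1")
    p <- 1; or <- NA_real_
  } else {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    p <- ft$p.value; or <- unname(ft$estimate)
  }
  tibble(n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1], n00 = tab[2, 2],
         odds_ratio = or, p_value = p)
}

#' Histogram of pairwise peak distances
#'
#' All same-chromosome pairwise distances between peak centers, binned.
#'
#' @param peaks peak tibble (`chrom`, `center`).
#' @param bin_bp bin width.
#' @param max_bp optional upper bound on distances kept.
#' @return tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
pairwise_distance_histogram <- function(peaks, bin_bp = 5000, max_bp = NULL) {
  d <- unlist(lapply(split(peaks$center, peaks$chrom), function(cen) {
    if (length(cen) < 2L) return(numeric())
    as.numeric(stats::dist(cen))
  }), use.names = FALSE)
  if (!is.null(max_bp)) d <- d[d <= max_bp]
  if (length(d) == 0L) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer()))
  }
  brk <- seq(0, (max(d) %/% bin_bp + 1) * bin_bp, by = bin_bp)
  h <- hist(d, breaks = brk, right = FALSE, plot = FALSE)
  tibble(bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
         count = h$counts)
}

#' Classify peaks by co-binding of a second protein
#'
#' Each peak is scored with the mean of a second protein's track over the
#' peak's span and labeled `"without"` (mean below `low`), `"with"` (mean
#' above `high`) or `"intermediate"`.
#'
#' @param peaks peak tibble with `chrom`, `center` and optionally
#'   `start`/`end` spans.
#' @param track single-value probe track of the co-binding protein.
#' @param low,high class thresholds on the mean log2 ratio (defaults 1.0
#'   and 1.5).
#' @param flank_bp span used when peaks carry no `start`/`end` (default
#'   1000 bp each side of the center).
#' @return `peaks` with `cobind_mean` and `cobind_class` columns
#'   (`cobind_class` is NA where no probe covers the span).
#' @export
classify_peaks_by_cobinding <- function(peaks, track, low = 1.0, high = 1.5,
                                        flank_bp = 1000) {
  if (!(low < high)) abort("`low` must be < `high`")
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("co-binding track needs a single value column")
  spans <- if (all(c("start", "end") %in% names(peaks))) {
    tibble(chrom = peaks$chrom, start = pmin(peaks$start, peaks$center - 1),
           end = pmax(peaks$end, peaks$center + 1))
  } else {
    tibble(chrom = peaks$chrom, start = peaks$center - flank_bp,
           end = peaks$center + flank_bp)
  }
  cen <- floor(probe_centers(track))
  pts <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(cen + 1L, cen + 1L))
  hits <- GenomicRanges::findOverlaps(pts, GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(floor(spans$start) + 1L, ceiling(spans$end))))
  mns <- tibble(peak = S4Vectors::subjectHits(hits),
                v = track[[vals]][S4Vectors::queryHits(hits)]) |>
    group_by(.data$peak) |>
    summarise(m = mean(.data$v, na.rm = TRUE))
  out <- peaks
  out$cobind_mean <- NA_real_
  out$cobind_mean[mns$peak] <- mns$m
  out$cobind_class <- dplyr::case_when(
    is.na(out$cobind_mean) ~ NA_character_,
    out$cobind_mean < low ~ "without",
    out$cobind_mean > high ~ "with",
    TRUE ~ "intermediate")
  out
}
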