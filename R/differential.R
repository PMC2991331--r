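#' Per-probe change in NL interaction
#'
#' Elementwise difference between a treatment and a control track on an
#' identical probe layout; missing values propagate.
#'
#' @param treatment,control single-value probe-track tibbles with the same
#'   probes in the same order.
#' @return a probe-track tibble with a `delta` column
#'   (treatment - control).
#' @export
delta_track <- function(treatment, control) {
  tv <- assert_track(treatment, arg = "treatment")
  cv <- assert_track(control, arg = "control")
  if (length(tv) != 1L || length(cv) != 1L) {
    abort("both tracks need exactly one value column")
  }
  if (nrow(treatment) != nrow(control) ||
      !identical(treatment$chrom, control$chrom) ||
      !identical(treatment$start, control$start) ||
      !identical(treatment$end, control$end)) {
    abort("treatment and control probe layouts differ")
  }
  out <- treatment[, c("chrom", "start", "end")]
  out$delta <- treatment[[tv]] - control[[cv]]
  as_tibble(out)
}

#' Average change in NL interaction per LAD
#'
#' @param delta delta-track tibble from [delta_track()].
#' @param lads LAD interval tibble.
#' @param stat `"mean"` (default) or `"median"` summary over the probes
#'   inside each LAD.
#' @return `lads` with `delta` (summary of probe deltas) and `n_probes`
#'   columns; probe-free LADs get NA with a warning.
#' @export
per_lad_delta <- function(delta, lads, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!"delta" %in% names(delta)) abort("`delta` needs a `delta` column")
  assert_intervals(lads, "lads")
  fun <- if (stat == "mean") mean else stats::median
  cen <- probe_centers(delta)
  out <- lads
  out$delta <- NA_real_
  out$n_probes <- 0L
  for (i in seq_len(nrow(lads))) {
    inside <- delta$chrom == lads$chrom[i] &
      cen >= lads$start[i] & cen < lads$end[i]
    out$n_probes[i] <- sum(inside)
    if (any(inside)) out$delta[i] <- fun(delta$delta[inside], na.rm = TRUE)
  }
  if (any(out$n_probes == 0L)) {
    warn(sprintf("%d LAD(s) contain no probes; delta set to NA",
                 sum(out$n_probes == 0L)))
  }
  out$delta[is.nan(out$delta)] <- NA_real_
  as_tibble(out)
}

#' Classify LADs by insulator peak density
#'
#' Density is peaks per bp of LAD; the `top25_density` class is cut at the
#' 75th percentile of density over all LADs, with ties included (so at
#' least a quarter of the LADs qualify when densities tie).
#'
#' @param lads LAD interval tibble.
#' @param peaks peak tibble (`chrom`, `center`).
#' @return `lads` with `peak_count`, `density_per_100kb` and `class`
#'   (`"no_peaks"`, `"has_peaks"`, `"top25_density"`) columns.
#' @export
classify_lads_by_peak_density <- function(lads, peaks) {
  assert_intervals(lads, "lads")
  out <- lads
  out$peak_count <- vapply(seq_len(nrow(lads)), function(i) {
    sum(peaks$chrom == lads$chrom[i] &
          peaks$center >= lads$start[i] & peaks$center < lads$end[i])
  }, numeric(1))
  size <- out$end - out$start
  out$density_per_100kb <- out$peak_count / size * 1e5
  out$class <- ifelse(out$peak_count == 0, "no_peaks", "has_peaks")
  if (any(out$peak_count > 0)) {
    cut75 <- stats::quantile(out$density_per_100kb, 0.75, type = 7)
    top <- out$density_per_100kb >= cut75 & out$peak_count > 0
    out$class[top] <- "top25_density"
  }
  as_tibble(out)
}

#' Compare per-LAD NL-interaction changes between LAD classes
#'
#' Two-sided Wilcoxon rank-sum test for every pair of classes, with class
#' medians. The `top25_density` class is also folded into `has_peaks` for
#' the `no_peaks` vs `has_peaks` comparison (it is a subset by
#' construction).
#'
#' @param classified output of [classify_lads_by_peak_density()] joined
#'   with [per_lad_delta()] deltas: a tibble with `class` and `delta`.
#' @return an object of class `lads_class_test`: a tibble with one row per
#'   class pair (`class_a`, `class_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `p_value`).
#' @export
compare_lad_classes <- function(classified) {
  if (!all(c("class", "delta") %in% names(classified))) {
    abort("`classified` needs columns class and delta")
  }
  d <- classified |> filter(!is.na(.data$delta))
  groups <- list(
    no_peaks = d$delta[d$class == "no_peaks"],
    has_peaks = d$delta[d$class %in% c("has_peaks", "top25_density")],
    top25_density = d$delta[d$class == "top25_density"])
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    p <- if (length(a) < 3L || length(b) < 3L) {
      warn(sprintf("class %s or %s has < 3 members; p set to NA", pr[1], pr[2]))
      NA_real_
    } else {
      stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL)$p.value
    }
    tibble(class_a = pr[1], class_b = pr[2], n_a = length(a), n_b = length(b),
           median_a = stats::median(a), median_b = stats::median(b),
           p_value = p)
  })
  out <- list_rbind(res)
  class(out) <- c("lads_class_test", class(out))
  out
}

#' Change in NL interaction versus distance to the nearest peak
#'
#' Peaks are stratified by where they fall (inside a LAD, in a 10-kb
#' border region, or outside); for each stratum every probe is assigned to
#' its nearest peak of that stratum and the running-window median of the
#' probe deltas is computed against |distance|.
#'
#' @param delta delta-track tibble from [delta_track()].
#' @param peaks peak tibble (`chrom`, `center`).
#' @param lads LAD interval tibble.
#' @param window_fraction running-window fraction (default 0.10).
#' @param border_width_bp border-region width for the stratification.
#' @param max_distance_bp probes farther than this from every peak of a
#'   stratum are dropped (default 50 kb).
#' @return a profile tibble with columns `stratum`, `distance_bp`
#'   (|distance|), `value` and `n`; empty strata are omitted with a
#'   warning.
#' @export
delta_vs_peak_distance <- function(delta, peaks, lads,
                                   window_fraction = 0.10,
                                   border_width_bp = 10000,
                                   max_distance_bp = 50000) {
  if (!"delta" %in% names(delta)) abort("`delta` needs a `delta` column")
  borders <- border_region_set(lads, border_width_bp)
  in_lad <- points_in_regions(peaks$chrom, peaks$center, lads)
  in_border <- points_in_regions(peaks$chrom, peaks$center, borders) & !in_lad
  stratum <- ifelse(in_lad, "inside", ifelse(in_border, "border", "outside"))
  probes <- tibble(chrom = delta$chrom, pos = probe_centers(delta),
                   value = delta$delta)
  res <- lapply(c("inside", "border", "outside"), function(st) {
    pk <- peaks[stratum == st, ]
    if (nrow(pk) == 0L) {
      warn(sprintf("no peaks in stratum '%s'; omitted", st))
      return(NULL)
    }
    aligned <- peak_relative_coords(probes, pk, max_distance_bp) |>
      mutate(rel_bp = abs(.data$rel_bp))
    if (nrow(aligned) < 2L) return(NULL)
    value_profile(aligned, window_fraction) |>
      mutate(stratum = st) |>
      rename(distance_bp = "rel_bp")
  })
  list_rbind(res)
}
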