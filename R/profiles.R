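#' Convert genomic positions to mirrored LAD-border-relative coordinates
#'
#' Each position is assigned to the nearest LAD border on its chromosome.
#' The relative coordinate is positive inside the LAD and negative outside;
#' data around right-side borders are mirrored so that "inside" is positive
#' for both borders and all borders can be pooled. A position belongs to a
#' border only up to the midpoint of its LAD (inward) and the midpoint of
#' the adjacent inter-LAD gap (outward), so every datum is used at most
#' once. Chromosome-terminal flanks are bounded by half the terminal gap.
#'
#' @param points tibble with columns `chrom` and `pos` (bp); extra columns
#'   (e.g. `value`) are carried through.
#' @param lads sorted, non-overlapping LAD interval tibble.
#' @param chrom_lengths optional named numeric vector of chromosome lengths
#'   (bp), used to bound the flank after the last LAD; if omitted that
#'   flank is unbounded.
#' @return the in-range rows of `points` with added columns `rel_bp`
#'   (signed, mirrored relative coordinate), `border_id` and `side`
#'   (`"left"`/`"right"`).
#' @export
border_relative_coords <- function(points, lads, chrom_lengths = NULL) {
  if (!all(c("chrom", "pos") %in% names(points))) {
    abort("`points` needs columns chrom and pos")
  }
  if (nrow(lads) == 0L || nrow(points) == 0L) {
    return(points[0, ] |> mutate(rel_bp = numeric(),
                                 border_id = character(),
                                 side = character()))
  }
  assert_intervals(lads, "lads")
  lads <- sort_genomic(lads)
  points |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      ld <- lads[lads$chrom == key$chrom, ]
      if (nrow(ld) == 0L) return(NULL)
      S <- ld$start; E <- ld$end; K <- nrow(ld)
      bnd <- as.vector(rbind(S, E))
      p <- g$pos
      reg <- findInterval(p, bnd)            # odd -> inside LAD (reg+1)/2
      rel <- rep(NA_real_, length(p))
      k_idx <- rep(NA_integer_, length(p))
      side <- rep(NA_character_, length(p))
      inside <- reg %% 2L == 1L
      if (any(inside)) {
        k <- (reg[inside] + 1L) %/% 2L
        dl <- p[inside] - S[k]
        dr <- E[k] - p[inside]
        left <- dl <= dr
        rel[inside] <- ifelse(left, dl, dr)
        k_idx[inside] <- k
        side[inside] <- ifelse(left, "left", "right")
      }
      gap <- !inside
      if (any(gap)) {
        r <- reg[gap]
        pg <- p[gap]
        # distance to flanking borders; Inf where no flanking LAD
        dl <- ifelse(r >= 2L, pg - E[pmax(r %/% 2L, 1L)], Inf)
        dr <- ifelse(r < 2L * K, S[pmin(r %/% 2L + 1L, K)] - pg, Inf)
        # terminal bounds: half the terminal gap
        first_mid <- S[1] / 2
        dr[r == 0L & pg < first_mid] <- Inf
        if (any(r == 2L * K)) {
          len <- if (is.null(chrom_lengths)) NA_real_ else
            (chrom_lengths[[key$chrom]] %||% NA_real_)
          if (!is.na(len)) {
            last_mid <- E[K] + (len - E[K]) / 2
            dl[r == 2L * K & pg > last_mid] <- Inf
          }
        }
        use_left <- dl <= dr
        rel[gap] <- ifelse(is.infinite(pmin(dl, dr)), NA_real_,
                           -pmin(dl, dr))
        k_idx[gap] <- ifelse(use_left, r %/% 2L, r %/% 2L + 1L)
        side[gap] <- ifelse(use_left, "right", "left")
      }
      keep <- !is.na(rel)
      g[keep, ] |>
        mutate(rel_bp = rel[keep],
               border_id = paste0(key$chrom, ":LAD", k_idx[keep], ":",
                                  substr(side[keep], 1, 1)),
               side = side[keep],
               chrom = key$chrom)
    }) |>
    list_rbind()
}

#' Convert genomic positions to peak-relative coordinates
#'
#' Each position is assigned to its nearest peak center; the region claimed
#' by a peak extends halfway to the adjacent peak on each side. The signed
#' distance is `pos - center` (bp).
#'
#' @param points tibble with columns `chrom` and `pos`.
#' @param peaks peak tibble with columns `chrom` and `center`.
#' @param max_distance_bp optional cap on |distance|; positions farther from
#'   every peak are dropped.
#' @return in-range rows of `points` with `rel_bp` and `peak_id` columns.
#' @export
peak_relative_coords <- function(points, peaks, max_distance_bp = NULL) {
  if (!all(c("chrom", "pos") %in% names(points))) {
    abort("`points` needs columns chrom and pos")
  }
  if (nrow(peaks) == 0L || nrow(points) == 0L) {
    return(points[0, ] |> mutate(rel_bp = numeric(), peak_id = character()))
  }
  points |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      pk <- peaks[peaks$chrom == key$chrom, ]
      if (nrow(pk) == 0L) return(NULL)
      cen <- sort(pk$center)
      mids <- (cen[-1] + cen[-length(cen)]) / 2
      j <- findInterval(g$pos, mids) + 1L
      rel <- g$pos - cen[j]
      out <- g |> mutate(rel_bp = rel,
                         peak_id = paste0(key$chrom, ":peak", j),
                         chrom = key$chrom)
      if (!is.null(max_distance_bp)) out <- filter(out, abs(.data$rel_bp) <= max_distance_bp)
      out
    }) |>
    list_rbind()
}

#' Running-window median profile of aligned values
#'
#' Points are sorted by relative coordinate and summarized with a running
#' window covering a fixed fraction of the data: each window of
#' `ceiling(window_fraction * n)` consecutive points emits its median
#' coordinate and median value.
#'
#' @param aligned tibble with columns `rel_bp` and `value` (e.g. from
#'   [border_relative_coords()] run on probe centers).
#' @param window_fraction fraction of the aligned points per window
#'   (default 0.05).
#' @return a profile tibble with strictly increasing `rel_bp`, the window
#'   `value` (median) and `n` (window size in points).
#' @export
value_profile <- function(aligned, window_fraction = 0.05) {
  if (!all(c("rel_bp", "value") %in% names(aligned))) {
    abort("`aligned` needs columns rel_bp and value")
  }
  if (!(window_fraction > 0 && window_fraction <= 1)) {
    abort("`window_fraction` must be in (0, 1]")
  }
  a <- aligned |> filter(!is.na(.data$value)) |> arrange(.data$rel_bp)
  n <- nrow(a)
  k <- max(1L, as.integer(ceiling(window_fraction * n)))
  if (n < max(k, 2L)) {
    abort(sprintf("need at least %d aligned points, got %d", max(k, 2L), n))
  }
  starts <- seq_len(n - k + 1L)
  coord <- vapply(starts, function(i) stats::median(a$rel_bp[i:(i + k - 1L)]),
                  numeric(1))
  val <- vapply(starts, function(i) stats::median(a$value[i:(i + k - 1L)]),
                numeric(1))
  tibble(rel_bp = coord, value = val) |>
    group_by(.data$rel_bp) |>
    summarise(value = mean(.data$value)) |>
    ungroup() |>
    arrange(.data$rel_bp) |>
    mutate(n = k)
}

#' Peak density across aligned LAD borders
#'
#' Peak centers are converted to mirrored border-relative coordinates and
#' the per-border peak frequency is evaluated on a regular grid: at each
#' grid point the count of aligned peaks within a `density_window_bp`-wide
#' window is divided by the number of borders. With
#' `literal_median = TRUE` the per-border median count is reported instead.
#'
#' @param peaks peak tibble (`chrom`, `center`).
#' @param lads LAD interval tibble.
#' @param density_window_bp full window width, default 10000 (10 kb).
#' @param grid_bp grid step, default 1000.
#' @param range_bp two-element range of relative coordinates to evaluate.
#' @param chrom_lengths optional chromosome lengths for terminal bounds.
#' @param literal_median report the median (rather than mean) per-border
#'   count in each window.
#' @return profile tibble with `rel_bp`, `value` (peaks per border per
#'   window), `n` (aligned peaks in the window).
#' @export
peak_density_profile <- function(peaks, lads, density_window_bp = 10000,
                                 grid_bp = 1000,
                                 range_bp = c(-50000, 100000),
                                 chrom_lengths = NULL,
                                 literal_median = FALSE) {
  aligned <- border_relative_coords(
    tibble(chrom = peaks$chrom, pos = peaks$center), lads, chrom_lengths)
  grid <- seq(range_bp[1], range_bp[2], by = grid_bp)
  half <- density_window_bp / 2
  n_borders <- 2L * nrow(lads)
  if (nrow(aligned) == 0L) {
    return(tibble(rel_bp = grid, value = 0, n = 0L))
  }
  rel <- sort(aligned$rel_bp)
  counts <- findInterval(grid + half, rel) - findInterval(grid - half, rel)
  value <- if (literal_median) {
    vapply(grid, function(x) {
      per_border <- table(factor(aligned$border_id[abs(aligned$rel_bp - x) <= half],
                                 levels = unique(aligned$border_id)))
      stats::median(c(as.numeric(per_border),
                      numeric(n_borders - length(per_border))))
    }, numeric(1))
  } else {
    counts / n_borders
  }
  tibble(rel_bp = grid, value = value, n = counts)
}

#' Base-level coverage of intervals across aligned LAD borders
#'
#' For every border and every bin of relative coordinate, the fraction of
#' bases covered by the (union of the) intervals is computed; the profile
#' is the median across borders per bin. Bins outside a border's allowed
#' range (past the LAD or gap midpoint) do not contribute for that border.
#'
#' @param intervals interval tibble (may overlap; coverage is computed on
#'   the union), e.g. gene bodies.
#' @param lads LAD interval tibble.
#' @param bin_bp bin width in bp (default 1000).
#' @param range_bp two-element range of relative coordinates.
#' @return profile tibble with `rel_bp` (bin midpoint), `value` (median
#'   covered fraction) and `n` (contributing borders).
#' @export
coverage_profile <- function(intervals, lads, bin_bp = 1000,
                             range_bp = c(-50000, 50000)) {
  assert_intervals(intervals, "intervals")
  assert_intervals(lads, "lads")
  lads <- sort_genomic(lads)
  bin_lo <- seq(range_bp[1], range_bp[2] - bin_bp, by = bin_bp)
  covs <- GenomicRanges::coverage(GenomicRanges::reduce(
    intervals_to_granges(intervals)))
  per_border <- list()
  for (chr in unique(lads$chrom)) {
    ld <- lads[lads$chrom == chr, ]
    cov <- if (chr %in% names(covs)) covs[[chr]] else S4Vectors::Rle(0L, 0)
    K <- nrow(ld)
    gaps_left <- c(ld$start[1], ld$start[-1] - ld$end[-K])  # gap before LAD k
    gaps_right <- c(ld$start[-1] - ld$end[-K], Inf)         # gap after LAD k
    for (k in seq_len(K)) {
      size <- ld$end[k] - ld$start[k]
      for (side in c("left", "right")) {
        lo_ok <- -(if (side == "left") gaps_left[k] else gaps_right[k]) / 2
        hi_ok <- size / 2
        use <- bin_lo >= lo_ok & (bin_lo + bin_bp) <= hi_ok
        if (!any(use)) next
        x0 <- bin_lo[use]
        if (side == "left") {
          gs <- ld$start[k] + x0          # genomic start (0-based) of bin
        } else {
          gs <- ld$end[k] - x0 - bin_bp
        }
        frac <- vapply(gs, function(a) {
          if (a < 0) return(NA_real_)
          lo <- a + 1; hi <- a + bin_bp
          if (length(cov) < hi) cov <- c(cov, S4Vectors::Rle(0L, hi - length(cov)))
          mean(pmin(as.numeric(S4Vectors::window(cov, lo, hi)), 1))
        }, numeric(1))
        per_border[[length(per_border) + 1L]] <-
          tibble(rel_bp = x0 + bin_bp / 2, frac = frac)
      }
    }
  }
  if (length(per_border) == 0L) {
    return(tibble(rel_bp = numeric(), value = numeric(), n = integer()))
  }
  list_rbind(per_border) |>
    filter(!is.na(.data$frac)) |>
    group_by(.data$rel_bp) |>
    summarise(value = stats::median(.data$frac), n = dplyr::n()) |>
    ungroup() |>
    arrange(.data$rel_bp)
}
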