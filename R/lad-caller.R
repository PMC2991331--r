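#' Parameters for the sliding edge-filter LAD caller
#'
#' @param edge_window_probes total edge-filter window (odd; the two
#'   half-windows each span `(edge_window_probes - 1) / 2` probes).
#' @param edge_threshold minimum |edge score| (log2 units) for a transition.
#' @param positive_fraction_min minimum fraction of enclosed probes with a
#'   positive (smoothed) log2 ratio for a candidate domain to be kept.
#' @param score_smoothing_window running-median window (probes) applied to
#'   the track before evaluating the positive fraction.
#' @param smooth_positive_rule evaluate the positive-fraction rule on the
#'   running-median smoothed values (default) or on raw values.
#' @param min_probes minimum number of enclosed probes for a domain.
#' @return a list of validated parameters.
#' @export
lad_params <- function(edge_window_probes = 199L, edge_threshold = 0.3,
                       positive_fraction_min = 0.70,
                       score_smoothing_window = 5L,
                       smooth_positive_rule = TRUE, min_probes = 5L) {
  edge_window_probes <- check_odd_window(edge_window_probes, "edge_window_probes")
  if (edge_window_probes < 3L) abort("`edge_window_probes` must be >= 3")
  if (!(edge_threshold > 0)) abort("`edge_threshold` must be > 0")
  if (!(positive_fraction_min > 0 && positive_fraction_min <= 1)) {
    abort("`positive_fraction_min` must be in (0, 1]")
  }
  score_smoothing_window <- check_odd_window(score_smoothing_window,
                                             "score_smoothing_window")
  list(edge_window_probes = edge_window_probes,
       edge_threshold = edge_threshold,
       positive_fraction_min = positive_fraction_min,
       score_smoothing_window = score_smoothing_window,
       smooth_positive_rule = smooth_positive_rule,
       min_probes = as.integer(min_probes))
}

# Edge score for one chromosome's value vector: difference of the mean over
# the w probes right of i and the mean over the w probes up to and including
# i; NA where either half-window is incomplete. Missing values are excluded
# from the half-window means.
edge_score_vector <- function(x, edge_window_probes) {
  n <- length(x)
  w <- (edge_window_probes - 1L) %/% 2L
  out <- rep(NA_real_, n)
  if (n < edge_window_probes) return(out)
  x0 <- ifelse(is.na(x), 0, x)
  k0 <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(x0))
  ck <- c(0, cumsum(k0))
  idx <- w:(n - w)
  left_sum  <- cs[idx + 1L] - cs[idx - w + 1L]   # probes idx-w+1 .. idx
  left_n    <- ck[idx + 1L] - ck[idx - w + 1L]
  right_sum <- cs[idx + w + 1L] - cs[idx + 1L]   # probes idx+1 .. idx+w
  right_n   <- ck[idx + w + 1L] - ck[idx + 1L]
  sc <- right_sum / right_n - left_sum / left_n
  sc[left_n == 0 | right_n == 0] <- NA_real_
  out[idx] <- sc
  out
}

#' Sliding edge-filter scores
#'
#' At each probe the edge score contrasts the mean log2 ratio of the
#' half-window of probes to its right with the half-window up to and
#' including it. Sharp up-transitions into a domain give large positive
#' scores, down-transitions large negative scores. Scores are NA where
#' either half-window runs off the chromosome.
#'
#' @param track probe-track tibble with a single value column.
#' @param params [lad_params()] list.
#' @return the track with an added `edge_score` column.
#' @export
edge_scores <- function(track, params = lad_params()) {
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("edge_scores() needs a single value column")
  short <- track |> count(.data$chrom) |>
    filter(.data$n < params$edge_window_probes)
  if (nrow(short) > 0L) {
    warn(sprintf("chromosome(s) shorter than the edge window: %s",
                 paste(short$chrom, collapse = ", ")))
  }
  track |>
    group_by(.data$chrom) |>
    mutate(edge_score = edge_score_vector(.data[[vals]],
                                          params$edge_window_probes)) |>
    ungroup()
}

# Local extrema of one sign in an edge-score vector; plateaus collapse to
# their midpoint probe. Returns integer indices.
local_extrema <- function(s, maxima = TRUE) {
  v <- if (maxima) s else -s
  n <- length(v)
  if (n == 0L) return(integer())
  vv <- ifelse(is.na(v), -Inf, v)
  is_ext <- vv >= c(-Inf, vv[-n]) & vv >= c(vv[-1], -Inf) & !is.na(v)
  idx <- which(is_ext)
  if (length(idx) == 0L) return(integer())
  # collapse runs of adjacent extrema with equal value to their midpoint
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L | diff(vv[idx]) != 0)))
  vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1))
}

# Collapse runs of same-sign transitions, keeping the largest |score|
# (leftmost on ties). `trans` is a tibble with columns idx, sign, score.
collapse_transition_runs <- function(trans) {
  if (nrow(trans) == 0L) return(trans)
  trans <- arrange(trans, .data$idx)
  run <- cumsum(c(TRUE, trans$sign[-1] != trans$sign[-nrow(trans)]))
  trans |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    slice(which.max(abs(.data$score))) |>
    ungroup() |>
    select(-".run")
}

#' Call lamina-associated domains with the sliding edge filter
#'
#' Up-transitions are local maxima of the edge score above
#' `edge_threshold`, down-transitions local minima below the negated
#' threshold. Runs of same-sign transitions keep only their strongest
#' member, each up-transition is paired with the next down-transition, and
#' the pair becomes a LAD if at least `positive_fraction_min` of the
#' enclosed probes have a positive log2 ratio after running-median
#' smoothing. Domain boundaries sit at the genomic midpoint between the
#' transition's extremum probe and its neighbor in the transition
#' direction.
#'
#' @inheritParams edge_scores
#' @return an interval tibble of LADs with columns `chrom`, `start`, `end`,
#'   `score` (the positive-probe fraction), `probe_count` and `name`.
#' @export
call_lads <- function(track, params = lad_params()) {
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("call_lads() needs a single value column")
  track <- sort_genomic(track)
  scored <- edge_scores(track, params)
  pos_vals <- if (params$smooth_positive_rule) {
    smooth_track(track, params$score_smoothing_window, "median")[[vals]]
  } else {
    track[[vals]]
  }

  out <- scored |>
    mutate(.pos = pos_vals) |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      s <- g$edge_score
      cen <- (g$start + g$end) / 2
      up <- local_extrema(s, maxima = TRUE)
      up <- up[!is.na(s[up]) & s[up] > params$edge_threshold]
      dn <- local_extrema(s, maxima = FALSE)
      dn <- dn[!is.na(s[dn]) & s[dn] < -params$edge_threshold]
      trans <- bind_rows(
        tibble(idx = up, sign = 1L, score = s[up]),
        tibble(idx = dn, sign = -1L, score = s[dn])
      )
      trans <- collapse_transition_runs(trans)
      doms <- list()
      i <- 1L
      while (i < nrow(trans)) {
        if (trans$sign[i] == 1L && trans$sign[i + 1L] == -1L) {
          iu <- trans$idx[i]; id <- trans$idx[i + 1L]
          # boundary: midpoint between the extremum probe and its neighbor
          # in the transition direction (the step lies between iu and iu+1)
          start_bp <- (cen[iu] + cen[min(iu + 1L, length(cen))]) / 2
          end_bp   <- (cen[id] + cen[min(id + 1L, length(cen))]) / 2
          inside <- which(cen >= start_bp & cen < end_bp)
          npos <- sum(g$.pos[inside] > 0, na.rm = TRUE)
          nval <- sum(!is.na(g$.pos[inside]))
          frac <- if (nval > 0L) npos / nval else 0
          if (length(inside) >= params$min_probes &&
              frac >= params$positive_fraction_min) {
            doms[[length(doms) + 1L]] <- tibble(
              chrom = key$chrom, start = floor(start_bp), end = floor(end_bp),
              score = frac, probe_count = length(inside))
          }
          i <- i + 2L
        } else {
          i <- i + 1L
        }
      }
      if (length(doms) == 0L) {
        tibble(chrom = character(), start = numeric(), end = numeric(),
               score = numeric(), probe_count = integer())
      } else {
        list_rbind(doms)
      }
    }) |>
    list_rbind()
  out <- sort_genomic(out)
  out$name <- if (nrow(out) > 0L) sprintf("LAD_%04d", seq_len(nrow(out))) else character()
  out
}

#' Summarize a LAD catalog
#'
#' @param lads interval tibble of LADs.
#' @param genome_size_bp total size of the probed genome in bp.
#' @return one-row tibble: `n_lads`, `n_borders`, `min_kb`, `median_kb`,
#'   `max_kb`, `coverage_fraction`.
#' @export
lad_summary <- function(lads, genome_size_bp) {
  if (!(genome_size_bp > 0)) abort("`genome_size_bp` must be > 0")
  if (nrow(lads) == 0L) {
    return(tibble(n_lads = 0L, n_borders = 0L, min_kb = NA_real_,
                  median_kb = NA_real_, max_kb = NA_real_,
                  coverage_fraction = 0))
  }
  assert_intervals(lads, "lads")
  sizes <- (lads$end - lads$start) / 1000
  tibble(n_lads = nrow(lads), n_borders = 2L * nrow(lads),
         min_kb = min(sizes), median_kb = stats::median(sizes),
         max_kb = max(sizes),
         coverage_fraction = sum(lads$end - lads$start) / genome_size_bp)
}
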