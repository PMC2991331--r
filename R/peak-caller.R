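#' Parameters for insulator binding-peak calling
#'
#' @param mean_window running-mean smoothing window (probes).
#' @param derivative_window window (probes) of the local least-squares slope
#'   taken as the derivative of the smoothed track.
#' @param probe_alpha per-probe significance threshold applied to
#'   FDR-adjusted p-values (to raw p-values when `adjust = FALSE`).
#' @param min_significant_probes minimum number of significant probes that
#'   must support a peak.
#' @param adjust threshold BH-adjusted p-values (default) or raw p-values.
#' @return a list of validated parameters.
#' @export
peak_params <- function(mean_window = 5L, derivative_window = 7L,
                        probe_alpha = 0.005, min_significant_probes = 3L,
                        adjust = TRUE) {
  mean_window <- check_odd_window(mean_window, "mean_window")
  derivative_window <- check_odd_window(derivative_window, "derivative_window")
  if (!(probe_alpha > 0 && probe_alpha < 1)) abort("`probe_alpha` must be in (0, 1)")
  if (min_significant_probes < 1L) abort("`min_significant_probes` must be >= 1")
  list(mean_window = mean_window, derivative_window = derivative_window,
       probe_alpha = probe_alpha,
       min_significant_probes = as.integer(min_significant_probes),
       adjust = adjust)
}

# Centered least-squares slope of x against probe index over an odd window;
# NA at the edges and wherever the window contains a missing value.
ols_slope_vector <- function(x, window) {
  k <- (window - 1L) %/% 2L
  offs <- (-k):k
  # stats::filter applies its first coefficient to x[i + k], so pass the
  # offsets in decreasing order to get the slope sum(o * x[i + o]) / sum(o^2)
  coef <- rev(offs) / sum(offs^2)
  as.numeric(stats::filter(x, coef, sides = 2))
}

#' Local derivative of a smoothed track
#'
#' The derivative at each probe is the least-squares slope of the smoothed
#' values against probe index over a centered window, per chromosome.
#' Edges where the window is incomplete are NA.
#'
#' @param track probe-track tibble with a single (already smoothed) value
#'   column.
#' @param derivative_window odd window size in probes.
#' @return the track with an added `derivative` column (units: log2 ratio
#'   per probe).
#' @export
derivative_track <- function(track, derivative_window = 7L) {
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("derivative_track() needs a single value column")
  derivative_window <- check_odd_window(derivative_window, "derivative_window")
  if (derivative_window < 3L) abort("`derivative_window` must be >= 3")
  track |>
    group_by(.data$chrom) |>
    mutate(derivative = ols_slope_vector(.data[[vals]], derivative_window)) |>
    ungroup()
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated one-sample probe test
#'
#' For each probe the replicate mean is tested for enrichment above zero
#' with a moderated t statistic: per-probe sample variances are shrunk
#' toward a prior variance `s0^2` with `d0` prior degrees of freedom,
#' estimated by moments matching on the log sample variances across all
#' probes. The test is one-sided (enrichment), and p-values are
#' Benjamini-Hochberg adjusted across all tested probes.
#'
#' @param track probe-track tibble with >= 2 replicate value columns.
#' @return the track's probes with columns `mean`, `t_mod`, `p_value`,
#'   `p_adj`, plus attributes `d0` and `s0_sq` on the result.
#' @export
moderated_probe_test <- function(track) {
  vals <- assert_track(track, n_values = 2L)
  m <- as.matrix(track[, vals])
  n_i <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  s2 <- apply(m, 1L, stats::var, na.rm = TRUE)
  testable <- n_i >= 2L & is.finite(s2)
  d <- n_i - 1L
  # moments matching on log sample variances (Smyth-style scaled-F prior)
  zok <- testable & s2 > 0
  if (!any(zok)) {
    warn("all probe variances are zero; falling back to a pooled variance (d0 = Inf)")
    d0 <- Inf
    s0_sq <- mean(s2[testable])
  } else {
    dd <- d[zok]
    e <- log(s2[zok]) - digamma(dd / 2) + log(dd / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (sum(zok) - 1) - mean(trigamma(dd / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no detectable excess spread in the log variances: infinite prior
      # df, i.e. a common (pooled) variance
      d0 <- Inf
      s0_sq <- mean(s2[testable])
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  t_mod <- mu / sqrt(s2_post / n_i)
  df_tot <- d0 + d
  p <- stats::pt(t_mod, df = df_tot, lower.tail = FALSE)
  p[!testable] <- NA_real_
  t_mod[!testable] <- NA_real_
  out <- track[, c("chrom", "start", "end")]
  out$mean <- mu
  out$t_mod <- t_mod
  out$p_value <- p
  out$p_adj <- stats::p.adjust(p, method = "BH")
  out <- as_tibble(out)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Call insulator binding peaks
#'
#' The replicate-averaged track is smoothed by a running mean, its local
#' derivative is computed, and candidate apices are placed where the
#' derivative changes sign from positive to negative. A candidate becomes a
#' peak if its support — the maximal contiguous run of probes with positive
#' smoothed signal containing the apex — holds at least
#' `min_significant_probes` probes whose moderated-test adjusted p-value is
#' below `probe_alpha`. Within one support run, apices closer than
#' `derivative_window` probes to a stronger apex are suppressed.
#'
#' @param track probe-track tibble with >= 2 replicate value columns.
#' @param params [peak_params()] list.
#' @return a tibble of peaks: `chrom`, `start`, `end` (span of the
#'   significant probes), `center` (apex probe center, bp), `height`
#'   (smoothed log2 ratio at the apex), `n_significant_probes`, `name`.
#' @export
call_peaks <- function(track, params = peak_params()) {
  vals <- assert_track(track, n_values = 2L)
  track <- sort_genomic(track)
  stats_tbl <- moderated_probe_test(track)
  sig <- !is.na(stats_tbl$p_adj) &
    (if (params$adjust) stats_tbl$p_adj else stats_tbl$p_value) < params$probe_alpha
  avg <- track[, c("chrom", "start", "end")]
  avg$value <- rowMeans(as.matrix(track[, vals]), na.rm = TRUE)
  sm <- smooth_track(as_tibble(avg), params$mean_window, "mean")
  dv <- derivative_track(sm, params$derivative_window)

  res <- dv |>
    mutate(.sig = sig) |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      n <- nrow(g)
      v <- g$value
      d <- g$derivative
      cen <- (g$start + g$end) / 2
      flip <- which(!is.na(d[-n]) & !is.na(d[-1]) & d[-n] > 0 & d[-1] <= 0)
      if (length(flip) == 0L) return(NULL)
      apex <- ifelse(!is.na(v[flip + 1L]) & v[flip + 1L] > v[flip], flip + 1L, flip)
      apex <- apex[!is.na(v[apex]) & v[apex] > 0]
      if (length(apex) == 0L) return(NULL)
      pos_run <- cumsum(c(TRUE, diff(!is.na(v) & v > 0) != 0))
      apex <- unique(apex)
      # non-maximum suppression within derivative_window probes
      ord <- apex[order(-v[apex], apex)]
      kept <- integer()
      for (a in ord) {
        if (!any(abs(kept - a) < params$derivative_window &
                 pos_run[pmax(kept, 1L)] == pos_run[a])) kept <- c(kept, a)
      }
      kept <- sort(kept)
      rows <- lapply(kept, function(a) {
        run_id <- pos_run[a]
        support <- which(pos_run == run_id & !is.na(v) & v > 0)
        sig_in <- support[g$.sig[support]]
        if (length(sig_in) < params$min_significant_probes) return(NULL)
        tibble(chrom = key$chrom,
               start = g$start[min(sig_in)], end = g$end[max(sig_in)],
               center = cen[a], height = v[a],
               n_significant_probes = length(sig_in))
      })
      bind_rows(rows)
    }) |>
    list_rbind()
  if (nrow(res) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  center = numeric(), height = numeric(),
                  n_significant_probes = integer(), name = character()))
  }
  res <- sort_genomic(res)
  res$name <- sprintf("peak_%05d", seq_len(nrow(res)))
  res
}
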