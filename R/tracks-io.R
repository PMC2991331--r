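#' Read a probe-level DamID track
#'
#' Reads a probe track from a bedGraph or TSV file into a tidy tibble with
#' one row per probe: `chrom`, `start`, `end` (0-based half-open) and one or
#' more numeric log2(Dam-fusion/Dam-only) value columns. Probes are sorted
#' per chromosome by start; unsorted input is sorted with a message.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"bedgraph"` (4+ columns, no
#'   header, optional `track` line) or `"tsv"` (header with
#'   `chrom`/`start`/`end` plus value columns).
#' @return a tibble with columns `chrom`, `start`, `end` and the value
#'   column(s) (`value` for bedGraph; header names for TSV).
#' @export
load_track <- function(path, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.bedgraph$|\\.bdg$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  if (format == "bedgraph") {
    raw <- utils::read.table(text = lines[keep], sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    nv <- ncol(raw) - 3L
    if (nv < 1L) abort("bedGraph needs >= 4 columns")
    names(raw) <- c("chrom", "start", "end",
                    if (nv == 1L) "value" else paste0("value_", seq_len(nv)))
  } else {
    raw <- utils::read.table(text = lines[keep], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(raw))) {
      abort("TSV track needs header columns chrom, start, end")
    }
  }
  bad <- which(raw$end <= raw$start)
  if (length(bad) > 0L) {
    abort(sprintf("probe with end <= start at data line %d of %s", bad[1], path))
  }
  out <- as_tibble(raw)
  out$chrom <- as.character(out$chrom)
  if (!is_sorted_genomic(out)) {
    inform("input probes were not position-sorted; sorting")
    out <- sort_genomic(out)
  }
  out
}

#' Write a single-value track as bedGraph
#'
#' @param track probe-track tibble with one value column.
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("bedGraph export needs exactly one value column")
  utils::write.table(track[, c("chrom", "start", "end", vals)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write genomic interval sets as GFF
#'
#' GFF records (1-based inclusive coordinates) are converted to the internal
#' 0-based half-open convention. Writing converts back, so a write/read
#' round trip is the identity on `chrom`, `start`, `end` and `score`.
#'
#' @param path path to a GFF (version-2 style) file.
#' @return `read_intervals_gff()`: a tibble with columns `chrom`, `start`,
#'   `end` (0-based half-open), `score` (NA where the GFF holds `.`) and
#'   `name` (the GFF feature type).
#' @export
read_intervals_gff <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (length(readLines(path, warn = FALSE)) == 0L ||
      all(grepl("^(#|\\s*$)", readLines(path, warn = FALSE)))) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  score = numeric(), name = character()))
  }
  gr <- rtracklayer::import(path, format = "gff2")
  sc <- if ("score" %in% names(S4Vectors::mcols(gr))) {
    as.numeric(S4Vectors::mcols(gr)$score)
  } else rep(NA_real_, length(gr))
  nm <- if ("type" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$type)
  } else rep(NA_character_, length(gr))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end   = GenomicRanges::end(gr),
    score = sc,
    name  = nm
  )
  assert_intervals(out, "GFF records")
  sort_genomic(out)
}

#' @rdname read_intervals_gff
#' @param intervals interval tibble (`chrom`, `start`, `end`, optional
#'   `score`, optional `name`) in 0-based half-open coordinates.
#' @param source source tag written to GFF column 2.
#' @export
write_intervals_gff <- function(intervals, path, source = "ladscape") {
  assert_intervals(intervals)
  gr <- intervals_to_granges(intervals)
  if ("score" %in% names(intervals)) {
    S4Vectors::mcols(gr)$score <- intervals$score
  }
  S4Vectors::mcols(gr)$type <- if ("name" %in% names(intervals) &&
                                   !all(is.na(intervals$name))) {
    ifelse(is.na(intervals$name), "region", intervals$name)
  } else "region"
  S4Vectors::mcols(gr)$source <- source
  rtracklayer::export(gr, path, format = "gff2")
  invisible(path)
}

#' Loess-normalize, median-center, dye-swap-correct and average replicates
#'
#' Reproduces the standard two-color DamID preprocessing: each replicate
#' column is loess-detrended against a covariate, median-centered to 0,
#' dye-swapped replicates are sign-corrected, and the columns are averaged
#' into a single `value` column.
#'
#' @param track probe-track tibble with at least two value columns on a
#'   common probe layout.
#' @param span loess span (fraction of points), default 0.3.
#' @param dye_swap character vector naming the value columns hybridized in
#'   reversed dye orientation (these are negated before averaging), or NULL.
#' @param intensity optional name of a column holding mean log-intensity to
#'   use as the loess covariate; by default the probe index along the array
#'   (genomic order) is used.
#' @param loess_detrend set FALSE to skip the loess step (centering and
#'   averaging only).
#' @return a probe-track tibble with a single `value` column.
#' @export
normalize_and_average <- function(track, span = 0.3, dye_swap = NULL,
                                  intensity = NULL, loess_detrend = TRUE) {
  vals <- assert_track(track, n_values = 2L)
  if (length(intensity) == 1L && intensity %in% vals) {
    vals <- setdiff(vals, intensity)
  }
  if (!(is.numeric(span) && length(span) == 1L && span > 0 && span <= 1)) {
    abort("`span` must be in (0, 1]")
  }
  if (!is.null(dye_swap) && !all(dye_swap %in% vals)) {
    abort("`dye_swap` names columns that are not value columns")
  }
  covariate <- if (is.null(intensity)) {
    seq_len(nrow(track))
  } else {
    track[[intensity]]
  }
  mat <- vapply(vals, function(v) {
    y <- track[[v]]
    if (all(is.na(y))) abort(sprintf("value column `%s` is entirely missing", v))
    if (loess_detrend) {
      ok <- !is.na(y) & !is.na(covariate)
      fit <- stats::loess(y[ok] ~ covariate[ok], span = span, degree = 1,
                          family = "symmetric")
      y[ok] <- stats::residuals(fit)
    }
    y - stats::median(y, na.rm = TRUE)
  }, numeric(nrow(track)))
  if (!is.null(dye_swap)) mat[, dye_swap] <- -mat[, dye_swap, drop = FALSE]
  out <- track[, c("chrom", "start", "end")]
  out$value <- rowMeans(mat, na.rm = TRUE)
  out$value[rowSums(!is.na(mat)) == 0L] <- NA_real_
  # averaging re-centered columns can leave a tiny offset; center once more
  out$value <- out$value - stats::median(out$value, na.rm = TRUE)
  as_tibble(out)
}

#' Running-window smoothing of a probe track
#'
#' Applies a running median or mean per chromosome with a centered window of
#' `window` probes. Windows shrink symmetrically at chromosome ends so the
#' output stays aligned to the input probes; missing values are excluded
#' from each window (an all-missing window yields NA). Smoothing never
#' crosses a chromosome boundary.
#'
#' @param track probe-track tibble.
#' @param window odd window size in probes.
#' @param stat `"median"` or `"mean"`.
#' @return a tibble with the same probes and smoothed value columns.
#' @export
smooth_track <- function(track, window, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  vals <- assert_track(track)
  window <- check_odd_window(window)
  fun <- if (stat == "median") stats::median else mean
  track |>
    group_by(.data$chrom) |>
    mutate(across(all_of(vals), ~ run_window_stat(.x, window, fun))) |>
    ungroup()
}

#' Two-channel average intensity (A-value)
#'
#' `A = (log2(cy5) + log2(cy3)) / 2`, the standard average log intensity of a
#' two-color microarray spot.
#'
#' @param cy5,cy3 positive channel intensities (vectorized).
#' @return numeric vector of A-values.
#' @export
a_value <- function(cy5, cy3) {
  if (any(cy5 <= 0, na.rm = TRUE) || any(cy3 <= 0, na.rm = TRUE)) {
    abort("channel intensities must be positive")
  }
  (log2(cy5) + log2(cy3)) / 2
}

#' Resample a track onto a coarser probe layout
#'
#' Each target interval receives the mean of the source probes whose centers
#' fall inside it (half-open); targets covering no probe center get NA.
#' This mirrors downsampling a high-resolution tiling array to the layout of
#' an older cDNA array.
#'
#' @param track probe-track tibble with one value column.
#' @param targets non-overlapping interval tibble (`chrom`, `start`, `end`).
#' @return `targets` with a `value` column appended.
#' @export
resample_track <- function(track, targets) {
  vals <- assert_track(track)
  if (length(vals) != 1L) abort("resample_track() needs a single value column")
  assert_intervals(targets, "targets")
  tg <- sort_genomic(targets)
  red <- GenomicRanges::reduce(intervals_to_granges(tg), min.gapwidth = 0L)
  if (length(red) < nrow(tg)) abort("`targets` must be non-overlapping")
  cen <- floor(probe_centers(track))
  pts <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(cen + 1L, cen + 1L))
  hits <- GenomicRanges::findOverlaps(pts, intervals_to_granges(tg))
  agg <- tibble(target = S4Vectors::subjectHits(hits),
                v = track[[vals]][S4Vectors::queryHits(hits)]) |>
    group_by(.data$target) |>
    summarise(value = mean(.data$v, na.rm = TRUE)) |>
    ungroup()
  out <- tg
  out$value <- NA_real_
  out$value[agg$target] <- agg$value
  out$value[is.nan(out$value)] <- NA_real_
  as_tibble(out)
}
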