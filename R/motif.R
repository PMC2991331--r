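#' Read a position weight matrix from JASPAR-style text
#'
#' Accepts the common 4-row count layouts: either plain whitespace-separated
#' rows (A, C, G, T order) or rows prefixed with the base and optional
#' brackets, e.g. `A [ 3 10 1 ]`, with an optional `>name` header line.
#'
#' @param path path to the matrix file.
#' @param pseudocount added to every count before the log-odds transform.
#' @param background per-base background probabilities (uniform by default).
#' @return a `pwm` object: a 4 x L numeric log-odds matrix with rownames
#'   ACGT and attributes `name` and `counts`.
#' @export
read_pwm <- function(path, pseudocount = 0.25,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- if (grepl("^>", lines[1])) {
    nm <- sub("^>\\s*", "", lines[1]); lines <- lines[-1]; nm
  } else sub("\\.[^.]*$", "", basename(path))
  if (length(lines) < 4L) abort("PWM file must have 4 matrix rows (A, C, G, T)")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("\\[|\\]", " ", l)
    toks <- strsplit(l, "\\s+")[[1]]
    if (toupper(toks[1]) %in% c("A", "C", "G", "T")) toks <- toks[-1]
    as.numeric(toks)
  })
  if (length(unique(lengths(rows))) != 1L) abort("PWM rows have unequal length")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  pwm_from_counts(counts, name = name, pseudocount = pseudocount,
                  background = background)
}

#' Build a log-odds PWM from a count matrix
#'
#' @param counts 4 x L matrix of base counts (rows A, C, G, T).
#' @param name motif name.
#' @inheritParams read_pwm
#' @return a `pwm` object (see [read_pwm()]).
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 0.25,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (nrow(counts) != 4L) abort("`counts` must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) abort("PWM length must be >= 4")
  rownames(counts) <- c("A", "C", "G", "T")
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(p / background[c("A", "C", "G", "T")])
  structure(lo, class = "pwm", name = name, counts = counts)
}

#' Relative matching score of a sequence window against a PWM
#'
#' `(S - S_min) / (S_max - S_min)` where `S` is the summed per-position
#' score of the window and `S_max`/`S_min` are the best and worst
#' attainable sums, so the score lies in \[0, 1\] with 1 at the consensus.
#' Windows containing `N` score NA.
#'
#' @param pwm a `pwm` log-odds matrix (see [read_pwm()]).
#' @param window character string of length `ncol(pwm)` over ACGTN.
#' @return relative score in \[0, 1\], or NA.
#' @export
relative_score <- function(pwm, window) {
  L <- ncol(pwm)
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != L) abort(sprintf("window length %d != PWM length %d",
                                    length(b), L))
  if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
  s <- sum(pwm[cbind(match(b, rownames(pwm)), seq_len(L))])
  smax <- sum(apply(pwm, 2, max))
  smin <- sum(apply(pwm, 2, min))
  (s - smin) / (smax - smin)
}

# Integer-coded scan of one strand: relative scores of all windows.
scan_strand <- function(code, pwm) {
  L <- ncol(pwm)
  n <- length(code)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1L)
  s <- numeric(length(starts))
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(L)) {
    cj <- code[starts + j - 1L]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    s <- s + pwm[cbind(cj, j)]
  }
  smax <- sum(apply(pwm, 2, max))
  smin <- sum(apply(pwm, 2, min))
  out <- (s - smin) / (smax - smin)
  out[!ok] <- NA_real_
  out
}

#' Scan sequences for PWM matches above a relative-score threshold
#'
#' Both strands are scanned; reverse-strand hits are reported at their
#' forward-strand coordinates. Overlapping hits are retained.
#'
#' @param sequences a named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param pwm a `pwm` object.
#' @param threshold minimum relative score (default 0.85).
#' @return a tibble of hits: `chrom`, `start` (0-based), `end`, `strand`,
#'   `raw_score`, `rel_score`.
#' @export
scan_sequence <- function(sequences, pwm, threshold = 0.85) {
  if (!(threshold > 0 && threshold <= 1)) abort("`threshold` must be in (0, 1]")
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  L <- ncol(pwm)
  smax <- sum(apply(pwm, 2, max))
  smin <- sum(apply(pwm, 2, min))
  res <- lapply(names(sequences), function(nm) {
    seq_chr <- toupper(sequences[[nm]])
    n <- nchar(seq_chr)
    if (n < L) return(NULL)
    code <- match(strsplit(seq_chr, "")[[1]], c("A", "C", "G", "T"))
    fwd <- scan_strand(code, pwm)
    rc_code <- rev(5L - code)  # A<->T (1<->4), C<->G (2<->3); NA stays NA
    rev_ <- scan_strand(rc_code, pwm)
    hits_f <- which(!is.na(fwd) & fwd >= threshold)
    hits_r <- which(!is.na(rev_) & rev_ >= threshold)
    bind_rows(
      if (length(hits_f)) tibble(chrom = nm, start = hits_f - 1L,
                                 strand = "+", rel_score = fwd[hits_f]),
      if (length(hits_r)) tibble(chrom = nm,
                                 start = n - (hits_r - 1L) - L,
                                 strand = "-", rel_score = rev_[hits_r])
    )
  })
  out <- list_rbind(res)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), raw_score = numeric(),
                  rel_score = numeric()))
  }
  out |>
    mutate(end = .data$start + L,
           raw_score = .data$rel_score * (smax - smin) + smin) |>
    select("chrom", "start", "end", "strand", "raw_score", "rel_score") |>
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Convert motif hits to point features
#'
#' Hit midpoints, ready for [border_relative_coords()] /
#' [peak_relative_coords()].
#'
#' @param hits hit tibble from [scan_sequence()].
#' @return tibble with `chrom` and `pos` (midpoint, bp).
#' @export
hits_to_points <- function(hits) {
  tibble(chrom = hits$chrom, pos = (hits$start + hits$end) / 2)
}
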