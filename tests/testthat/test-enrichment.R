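test_that("border regions sit just outside LADs and truncate at midpoints", {
  one <- tibble::tibble(chrom = "c", start = 100000, end = 200000)
  br <- border_region_set(one)
  expect_equal(br$start, c(90000, 200000))
  expect_equal(br$end, c(100000, 210000))

  # two LADs 12 kb apart: facing regions truncated to 6 kb each
  two <- tibble::tibble(chrom = "c", start = c(100000, 212000),
                        end = c(200000, 300000))
  br2 <- border_region_set(two)
  facing <- br2[br2$start >= 200000 & br2$end <= 212000, ]
  expect_equal(facing$start, c(200000, 206000))
  expect_equal(facing$end, c(206000, 212000))

  # LAD at the chromosome start: left region clamped at 0
  edge <- tibble::tibble(chrom = "c", start = 4000, end = 50000)
  br3 <- border_region_set(edge)
  expect_equal(br3$start[1], 0)
  expect_equal(br3$end[1], 4000)
})

test_that("fraction_in_regions counts peak centers in half-open intervals", {
  reg <- tibble::tibble(chrom = "c", start = c(0, 1000), end = c(500, 2000))
  pk <- tibble::tibble(chrom = "c",
                       center = c(0, 250, 500, 999, 1000, 1999, 2000, 5000,
                                  100, 3000))
  # boundary starts count as inside, boundary ends do not
  expect_equal(fraction_in_regions(pk, reg), 5 / 10)
  expect_equal(fraction_in_regions(pk, reg[0, ]), 0)
  expect_error(fraction_in_regions(pk[0, ], reg), "empty")

  # random case vs IRanges overlap oracle
  set.seed(151)
  regs <- tibble::tibble(chrom = sample(c("a", "b"), 30, TRUE),
                         start = round(runif(30, 0, 9e5)))
  regs$end <- regs$start + round(runif(30, 100, 5e4))
  pks <- tibble::tibble(chrom = sample(c("a", "b"), 500, TRUE),
                        center = round(runif(500, 0, 1e6)))
  want <- mean(IRanges::overlapsAny(
    GenomicRanges::GRanges(pks$chrom,
                           IRanges::IRanges(pks$center + 1, pks$center + 1)),
    GenomicRanges::GRanges(regs$chrom,
                           IRanges::IRanges(regs$start + 1, regs$end))))
  expect_equal(fraction_in_regions(pks, regs), want)
})

test_that("permutation enrichment has the right floor, null and expectation", {
  spans <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  # regions covering the whole probed span: observed = expected = 1, p = 1
  all_reg <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  pk <- tibble::tibble(chrom = "c", center = runif(50, 0, 1e6))
  r <- permutation_enrichment(pk, all_reg, spans, n_permutations = 99, seed = 1)
  expect_equal(r$observed_fraction, 1)
  expect_equal(r$expected_fraction, 1)
  expect_equal(r$p_value, 1)

  # all peaks planted inside a 10% region: p at the 1/(N+1) floor
  reg <- tibble::tibble(chrom = "c", start = 0, end = 1e5)
  pk2 <- tibble::tibble(chrom = "c", center = runif(100, 0, 1e5))
  r2 <- permutation_enrichment(pk2, reg, spans, n_permutations = 999, seed = 2)
  expect_equal(r2$p_value, 0.001)
  expect_equal(r2$direction, "enrichment")

  # expected fraction converges to the regions' share of the probed span
  r3 <- permutation_enrichment(pk2, reg, spans, n_permutations = 2000, seed = 3)
  mc_sd <- sd(r3$permuted_fractions) / sqrt(2000)
  expect_lt(abs(r3$expected_fraction - 0.1), max(3 * mc_sd, 0.005))

  # reproducibility: same seed, same result
  r4 <- permutation_enrichment(pk2, reg, spans, n_permutations = 200, seed = 7)
  r5 <- permutation_enrichment(pk2, reg, spans, n_permutations = 200, seed = 7)
  expect_identical(r4[names(r4) != "permuted_fractions"],
                   r5[names(r5) != "permuted_fractions"])
  expect_identical(r4$permuted_fractions, r5$permuted_fractions)

  # regions outside the probed span are rejected
  bad <- tibble::tibble(chrom = "c", start = 5e5, end = 2e6)
  expect_error(permutation_enrichment(pk2, bad, spans, 10, seed = 1),
               "outside")

  expect_s3_class(tidy(r2), "tbl_df")
  expect_equal(tidy(r2)$p_value, 0.001)
})

test_that("permutation test type-I error is calibrated under the null", {
  lads <- synthetic_lad_catalog(n_lads = 30, coverage = 0.4,
                                median_bp = 80000,
                                arm_lengths = c(cA = 4e6, cB = 2e6))
  spans <- tibble::tibble(chrom = c("cA", "cB"), start = 0,
                          end = c(4e6, 2e6))
  set.seed(161)
  pvals <- sapply(seq_len(200), function(i) {
    chr <- sample(c("cA", "cB"), 100, TRUE, prob = c(2, 1))
    pk <- tibble::tibble(chrom = chr,
                         center = runif(100, 0, ifelse(chr == "cA", 4e6, 2e6)))
    permutation_enrichment(pk, lads, spans, n_permutations = 199,
                           alternative = "enrichment", seed = 7000 + i)$p_value
  })
  expect_gte(mean(pvals <= 0.05), 0.02)
  expect_lte(mean(pvals <= 0.05), 0.08)
})

test_that("interior window occupancy filters LADs by half-size", {
  lads <- tibble::tibble(chrom = "c",
                         start = c(0, 2e5, 5e5),
                         end = c(1e5, 2e5 + 8e4, 5e5 + 1e5))
  # 100-kb LAD with a peak 40 kb from its left border counts as occupied;
  # the 80-kb LAD is excluded (half-size 40 kb < 45 kb)
  pk <- tibble::tibble(chrom = "c", center = c(40000, 240000))
  expect_equal(interior_window_occupancy(lads, pk), 0.5)
  expect_error(interior_window_occupancy(lads[2, ], pk), "half-size")

  # planted occupancy is recovered
  set.seed(171)
  n <- 60
  big <- tibble::tibble(chrom = "c",
                        start = seq(0, by = 3e5, length.out = n),
                        end = seq(0, by = 3e5, length.out = n) + 1.2e5)
  occ <- rbinom(n, 1, 0.6) == 1
  pks <- tibble::tibble(chrom = "c", center = big$start[occ] + 40000)
  got <- interior_window_occupancy(big, pks)
  expect_equal(got, mean(occ))
})

test_that("Fisher border/interior association matches the exact test", {
  # construct LADs and peaks realizing a prescribed 2x2 table
  mk_lads <- function(n) {
    tibble::tibble(chrom = "c", start = seq(1e5, by = 3e5, length.out = n),
                   end = seq(1e5, by = 3e5, length.out = n) + 1.5e5)
  }
  tab_from <- function(n11, n10, n01, n00) {
    n <- n11 + n10 + n01 + n00
    lads <- mk_lads(n)
    border <- c(rep(TRUE, n11 + n10), rep(FALSE, n01 + n00))
    interior <- c(rep(TRUE, n11), rep(FALSE, n10), rep(TRUE, n01),
                  rep(FALSE, n00))
    pk <- dplyr::bind_rows(
      tibble::tibble(chrom = "c", center = lads$start[border] - 5000),
      tibble::tibble(chrom = "c", center = lads$start[interior] + 40000))
    border_interior_association(lads, pk)
  }
  perfect <- tab_from(10, 10, 10, 10)
  expect_equal(perfect$p_value, 1.0)
  expect_equal(unname(unlist(perfect[, c("n11", "n10", "n01", "n00")])),
               c(10, 10, 10, 10))

  assoc <- tab_from(8, 2, 1, 9)
  expect_equal(assoc$p_value, fisher.test(matrix(c(8, 2, 1, 9), 2))$p.value)
  expect_equal(assoc$p_value, 0.005477, tolerance = 1e-3)

  # hypergeometric enumeration oracle for small tables
  hyper_p <- function(m) {
    all_t <- 0:min(m[1, 1] + m[1, 2], m[1, 1] + m[2, 1])
    probs <- dhyper(all_t, m[1, 1] + m[1, 2], m[2, 1] + m[2, 2],
                    m[1, 1] + m[2, 1])
    sum(probs[probs <= dhyper(m[1, 1], m[1, 1] + m[1, 2],
                              m[2, 1] + m[2, 2],
                              m[1, 1] + m[2, 1]) * (1 + 1e-7)])
  }
  for (tab in list(matrix(c(8, 2, 1, 9), 2), matrix(c(3, 7, 6, 4), 2),
                   matrix(c(12, 3, 5, 10), 2))) {
    expect_equal(fisher.test(tab)$p.value, hyper_p(tab), tolerance = 1e-9)
  }

  # degenerate margin: p = 1 with a warning
  expect_warning(deg <- tab_from(0, 0, 5, 15), "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("pairwise distance histogram enumerates same-chromosome pairs", {
  pk <- tibble::tibble(chrom = "c", center = c(0, 10000, 25000))
  h <- pairwise_distance_histogram(pk, bin_bp = 5000)
  got <- rep(h$bin_lo, h$count)
  expect_equal(sort(got), c(10000, 15000, 25000))
  expect_equal(sum(h$count), 3L)

  expect_equal(nrow(pairwise_distance_histogram(pk[1, ], 5000)), 0L)

  # uniform peaks: histogram matches the triangular null within MC error
  set.seed(181)
  L <- 1e6
  pku <- tibble::tibble(chrom = "c", center = runif(400, 0, L))
  hu <- pairwise_distance_histogram(pku, bin_bp = 50000, max_bp = 9e5)
  n_pairs <- choose(400, 2)
  expect_true(all(diff(hu$count) <= 3 * sqrt(pmax(hu$count[-1], 10))))
  tri <- function(lo, hi) (hi - lo) * (2 * L - lo - hi) / L^2
  want <- n_pairs * tri(hu$bin_lo, hu$bin_hi)
  expect_lt(max(abs(hu$count - want) / sqrt(want)), 5)
})

test_that("co-binding classification uses mean track level over peak spans", {
  tr0 <- toy_track(rep(0, 100))
  tr2 <- toy_track(rep(2, 100))
  tr12 <- toy_track(rep(1.2, 100))
  pk <- tibble::tibble(chrom = "chr2L", center = c(5000, 20000))
  expect_equal(classify_peaks_by_cobinding(pk, tr0)$cobind_class,
               rep("without", 2))
  expect_equal(classify_peaks_by_cobinding(pk, tr2)$cobind_class,
               rep("with", 2))
  expect_equal(classify_peaks_by_cobinding(pk, tr12)$cobind_class,
               rep("intermediate", 2))
  # peak with no covering probes gets a missing label
  far <- tibble::tibble(chrom = "chr2L", center = 5e6)
  expect_true(is.na(classify_peaks_by_cobinding(far, tr0)$cobind_class))
  expect_error(classify_peaks_by_cobinding(pk, tr0, low = 2, high = 1), "low")
})
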