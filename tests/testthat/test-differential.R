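test_that("delta_track is the elementwise treatment-minus-control difference", {
  set.seed(231)
  ctrl <- toy_track(rnorm(100))
  same <- delta_track(ctrl, ctrl)
  expect_true(all(same$delta == 0))

  shifted <- ctrl; shifted$value <- ctrl$value + 0.5
  expect_equal(delta_track(shifted, ctrl)$delta, rep(0.5, 100))

  trt <- ctrl; trt$value <- rnorm(100)
  trt$value[3] <- NA
  d <- delta_track(trt, ctrl)
  expect_equal(d$delta, trt$value - ctrl$value)
  expect_true(is.na(d$delta[3]))

  # antisymmetry: swapping treatment and control negates the delta exactly
  expect_equal(delta_track(ctrl, trt)$delta, -d$delta)

  bad <- ctrl[-1, ]
  expect_error(delta_track(trt, bad), "layouts differ")
})

test_that("per_lad_delta averages probe deltas inside each LAD", {
  tr <- toy_track(rep(0, 200), spacing = 1000)
  lads <- tibble::tibble(chrom = "chr2L", start = c(10000, 100000),
                         end = c(40000, 150000))
  d0 <- tr; names(d0)[names(d0) == "value"] <- "delta"
  expect_equal(per_lad_delta(d0, lads)$delta, c(0, 0))

  # +0.5 added inside the first LAD only
  cen <- (tr$start + tr$end) / 2
  d1 <- d0
  d1$delta[cen >= 10000 & cen < 40000] <- 0.5
  pl <- per_lad_delta(d1, lads)
  expect_equal(pl$delta, c(0.5, 0))

  # random case vs brute-force probe-in-interval means
  set.seed(241)
  d2 <- d0; d2$delta <- rnorm(200)
  got <- per_lad_delta(d2, lads)
  want <- sapply(seq_len(2), function(i) {
    mean(d2$delta[cen >= lads$start[i] & cen < lads$end[i]])
  })
  expect_equal(got$delta, want)

  # probe-free LAD: NA with a warning
  lads3 <- dplyr::bind_rows(lads,
                            tibble::tibble(chrom = "chrX", start = 0, end = 1e4))
  expect_warning(pl3 <- per_lad_delta(d2, lads3), "no probes")
  expect_true(is.na(pl3$delta[3]))
})

test_that("LAD classification by peak density honors the tie rule", {
  lads <- tibble::tibble(chrom = "c", start = (0:3) * 2e5, end = (0:3) * 2e5 + 1e5)
  # densities 0, 1, 2, 3 peaks per 100 kb -> top25 is the densest LAD only
  pk <- tibble::tibble(chrom = "c",
                       center = c(2e5 + 1e4,
                                  4e5 + c(1e4, 2e4),
                                  6e5 + c(1e4, 2e4, 3e4)))
  cl <- classify_lads_by_peak_density(lads, pk)
  expect_equal(cl$class, c("no_peaks", "has_peaks", "has_peaks",
                           "top25_density"))
  expect_equal(cl$peak_count, c(0, 1, 2, 3))
  expect_equal(cl$density_per_100kb, c(0, 1, 2, 3))

  # no peaks at all: everything no_peaks, top25 empty
  cl0 <- classify_lads_by_peak_density(lads, pk[0, ])
  expect_true(all(cl0$class == "no_peaks"))

  # equal densities everywhere: the tie rule sends every LAD to top25
  pk_eq <- tibble::tibble(chrom = "c", center = (0:3) * 2e5 + 5e4)
  cl_eq <- classify_lads_by_peak_density(lads, pk_eq)
  expect_true(all(cl_eq$class == "top25_density"))
})

test_that("class comparisons use the two-sample rank-sum test", {
  # exact enumeration: {1,2,3} vs {4,5,6} has U = 0 and two-sided p = 0.1
  x <- tibble::tibble(class = rep(c("no_peaks", "has_peaks"), each = 3),
                      delta = c(1, 2, 3, 4, 5, 6))
  res <- suppressWarnings(tidy(compare_lad_classes(x)))
  row <- res[res$class_a == "no_peaks" & res$class_b == "has_peaks", ]
  expect_equal(row$p_value, 0.1)
  expect_equal(row$median_a, 2)
  expect_equal(row$median_b, 5)

  # identical distributions: p well above 0.5
  set.seed(251)
  v <- rnorm(50)
  y <- tibble::tibble(class = rep(c("no_peaks", "has_peaks"), each = 50),
                      delta = c(v, v))
  res_same <- suppressWarnings(tidy(compare_lad_classes(y)))
  expect_gt(res_same$p_value[1], 0.5)

  # clearly separated classes: p below 1e-3
  z <- tibble::tibble(class = rep(c("no_peaks", "has_peaks"), each = 50),
                      delta = c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1)))
  expect_lt(suppressWarnings(tidy(compare_lad_classes(z)))$p_value[1], 1e-3)

  # agreement with exact enumeration for small classes
  set.seed(261)
  a <- rnorm(5); b <- rnorm(6)
  small <- tibble::tibble(class = rep(c("no_peaks", "has_peaks"), c(5, 6)),
                          delta = c(a, b))
  got <- suppressWarnings(tidy(compare_lad_classes(small)))
  got_p <- got$p_value[got$class_a == "no_peaks" & got$class_b == "has_peaks"]
  # full permutation oracle over all choose(11, 5) splits
  pool <- c(a, b)
  u_obs <- sum(rank(pool)[1:5]) - 5 * 6 / 2
  combs <- combn(11, 5)
  u_all <- apply(combs, 2, function(ix) sum(rank(pool)[ix]) - 15)
  p_exact <- mean(abs(u_all - 15) >= abs(u_obs - 15))
  expect_equal(got_p, p_exact)

  # tiny class: NA p with warning
  tiny <- tibble::tibble(class = c("no_peaks", "no_peaks", "has_peaks",
                                   "has_peaks", "has_peaks"),
                         delta = 1:5)
  expect_warning(res_t <- compare_lad_classes(tiny), "< 3 members")
  expect_true(is.na(tidy(res_t)$p_value[1]))
})

test_that("planted knockdown recovers the class ordering and the profile", {
  cfg <- sim_config(chrom_lengths = c(chrA = 8e6, chrB = 8e6, chrC = 8e6),
                    n_lads = 120, lad_size_meanlog = log(1.1e5),
                    lad_size_sdlog = 0.25, n_peaks = 160,
                    peak_frac_border = 0.2, peak_frac_interior = 0.45,
                    peak_frac_uniform = 0.35,
                    perturb_shape = "plateau", seed = 271)
  lay <- simulate_peaks(simulate_layout(cfg))
  lads <- lay$truth$lads
  pks <- tibble::tibble(chrom = lay$truth$peaks$chrom,
                        center = lay$truth$peaks$center)
  pert <- simulate_perturbation(lay, seed = 272)
  ctrl <- simulate_damid_replicates(lay, signal = "lamin", seed = 273)
  dtr <- delta_track(normalize_and_average(pert$track, loess_detrend = FALSE),
                     normalize_and_average(ctrl, loess_detrend = FALSE))
  pl <- per_lad_delta(dtr, lads)
  cl <- classify_lads_by_peak_density(lads, pks)
  cl$delta <- pl$delta

  means <- tapply(cl$delta, cl$class, mean)
  expect_true(means[["no_peaks"]] < means[["has_peaks"]])
  expect_true(means[["has_peaks"]] < means[["top25_density"]])
  res <- tidy(compare_lad_classes(cl))
  p_np_hp <- res$p_value[res$class_a == "no_peaks" & res$class_b == "has_peaks"]
  expect_lt(p_np_hp, 1e-3)

  # distance profile peaks near zero at the planted amplitude and decays
  prof <- delta_vs_peak_distance(dtr, pks, lads)
  inside <- prof[prof$stratum == "inside", ]
  expect_lt(abs(max(inside$value) - cfg$perturb_amplitude),
            0.25 * cfg$perturb_amplitude)
  expect_lt(inside$distance_bp[which.max(inside$value)], 10000)
  expect_lt(abs(median(inside$value[inside$distance_bp > 40000])), 0.05)

  # negative control: shuffled peak positions give a flat profile
  set.seed(281)
  shuf <- pks
  shuf$center <- unlist(lapply(split(pks$center, pks$chrom), function(x) {
    sort(runif(length(x), 0, 8e6))
  }), use.names = FALSE)
  prof_null <- suppressWarnings(delta_vs_peak_distance(dtr, shuf, lads))
  expect_lt(diff(range(prof_null$value[prof_null$stratum == "inside"])), 0.15)

  # zero perturbation: flat zero profiles
  d0 <- dtr; d0$delta <- 0
  prof0 <- suppressWarnings(delta_vs_peak_distance(d0, pks, lads))
  expect_true(all(prof0$value == 0))

  # overexpression mode negates the planted delta exactly
  oe <- simulate_perturbation(lay, mode = "overexpression", seed = 274)
  expect_equal(oe$delta$delta, -pert$delta$delta)
})
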