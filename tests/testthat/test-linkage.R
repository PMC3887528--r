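test_that("genotype_r2 matches hand-computed correlations", {
  expect_equal(genotype_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(genotype_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  # complete-case restriction: value equals Pearson^2 on the first 4 samples
  d1 <- c(0, 1, 2, 1, NA)
  d2 <- c(0, 1, 1, 2, 2)
  expect_equal(genotype_r2(d1, d2),
               stats::cor(c(0, 1, 2, 1), c(0, 1, 1, 2))^2)
  expect_equal(genotype_r2(d1, d2), oracle_r2(d1, d2))
  # undefined when a restricted vector is constant or too short
  expect_true(is.na(genotype_r2(c(0, 0, 0, NA), c(0, 1, 2, 2))))
  expect_true(is.na(genotype_r2(c(0, NA, NA), c(1, 0, 2))))
})

test_that("genotype_r2 is symmetric, flip- and affine-invariant", {
  set.seed(51)
  for (i in 1:50) {
    d1 <- sample(c(0:2, NA), 12, replace = TRUE)
    d2 <- sample(c(0:2, NA), 12, replace = TRUE)
    r <- genotype_r2(d1, d2)
    expect_equal(r, genotype_r2(d2, d1))
    expect_equal(r, genotype_r2(2 - d1, d2))
    expect_equal(r, genotype_r2(d1, 3 * d2 - 1))
  }
})

test_that("ld_decay equals a brute-force double loop over all pairs", {
  set.seed(61)
  for (rep in 1:3) {
    n <- sample(c(60, 120, 200), 1)
    pos <- sort(sample.int(3000, n))
    dos <- matrix(sample(c(0:2, NA), n * 10, replace = TRUE,
                         prob = c(rep(0.3, 3), 0.1)), n, 10)
    chrom <- rep(c("2L", "2R"), length.out = n)
    ord <- order(chrom, pos)
    gm <- genotype_matrix(
      data.frame(chrom = chrom[ord], pos = pos[ord], ref = "A", alt = "T"),
      dos[ord, ], paste0("S", 1:10))
    got <- ld_decay(gm, max_dist = 500, bin_width = 50)
    want <- oracle_ld_decay(gm, 500, 50)
    got <- got[order(got$chrom, got$bin_start), ]
    want <- want[order(want$chrom, want$bin_start), ]
    expect_equal(got$n_pairs, want$n_pairs)
    expect_equal(got$mean_r2, want$mean_r2, tolerance = 1e-10)
  }
})

test_that("pairs land in the bin containing their distance, per chromosome", {
  gm <- genotype_matrix(
    data.frame(chrom = c("2L", "2R", "2R"), pos = c(100, 100, 150),
               ref = "A", alt = "T"),
    rbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0)),
    paste0("S", 1:4))
  curve <- ld_decay(gm, max_dist = 5000, bin_width = 100)
  on_2r <- curve[curve$chrom == "2R", ]
  expect_equal(on_2r$mean_r2[1], 1)   # 50 bp apart, r2 = 1, bin [0,100)
  expect_equal(on_2r$n_pairs[1], 1)
  expect_equal(sum(curve$n_pairs), 1) # the cross-chromosome pair is nowhere
})

test_that("ld_decay warns and returns an empty curve with no eligible pairs", {
  gm <- genotype_matrix(data.frame(chrom = "2R", pos = 100,
                                   ref = "A", alt = "T"),
                        matrix(c(0, 1, 2), 1), paste0("S", 1:3))
  expect_warning(curve <- ld_decay(gm, max_dist = 100, bin_width = 10),
                 "no eligible")
  expect_equal(nrow(curve), 0)
})

test_that("windowed LD honors separation bounds and the min-pairs rule", {
  # 3 sites within one window: pair seps 500 (ignored), 1500, 2000
  gm <- genotype_matrix(
    data.frame(chrom = "2R", pos = c(1000, 1500, 3000), ref = "A", alt = "T"),
    rbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0)), paste0("S", 1:4))
  w <- windowed_ld(gm, c("2R" = 4000), min_sep = 1000, max_sep = 10000,
                   bin = 4000, step = 4000, min_pairs = 1)
  expect_equal(w$n_values, 2L)  # the 500 bp pair is below min_sep
  expect_equal(w$value, 1)      # all qualifying pairs have r2 = 1
  # same data, min_pairs above the count: window excluded
  w2 <- windowed_ld(gm, c("2R" = 4000), min_sep = 1000, max_sep = 10000,
                    bin = 4000, step = 4000, min_pairs = 3)
  expect_true(w2$excluded)
  expect_true(is.na(w2$value))
  expect_error(windowed_ld(gm, c("2R" = 4000), min_sep = 200, max_sep = 100),
               "min_sep")
})

test_that("decay is monotone under mosaic recombination, flat without", {
  cfg <- sim_config(seed = 71, n_sites = 800, chrom_length = 60000,
                    n_founders = 4, panel_size = 4, switch_rate = 1e-3,
                    theta_fst = 0, n_per_pop = c(p = 40),
                    inversions = list(), centromere = NULL, telomere = NULL,
                    missing_rate = 0)
  gm <- simulate_population(simulate_founders(cfg), cfg)$matrix
  curve <- ld_decay(gm, max_dist = 1000, bin_width = 100)
  expect_gt(curve$mean_r2[1], curve$mean_r2[10])

  cfg0 <- sim_config(seed = 72, n_sites = 100, chrom_length = 20000,
                     n_founders = 2, panel_size = 2, switch_rate = 0,
                     theta_fst = 0, n_per_pop = c(p = 12),
                     inversions = list(), centromere = NULL,
                     telomere = NULL, missing_rate = 0)
  gm0 <- simulate_population(simulate_founders(cfg0), cfg0)$matrix
  pr <- vcfpopgen:::pair_r2_table(gm0, 1, 20000)
  expect_true(all(abs(pr$r2 - 1) < 1e-12))
})
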