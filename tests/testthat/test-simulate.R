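test_that("founder frequencies follow the neutral SFS", {
  # with 2 founders every polymorphic site has founder frequency 1/2
  cfg2 <- small_sim_config(seed = 1, n_sites = 50, n_per_pop = c(p = 4),
                           n_founders = 2)
  f2 <- simulate_founders(cfg2)
  expect_true(all(f2$p_anc == 0.5))
  # with 20 founders the singleton fraction tends to 1 / H_19
  cfg20 <- sim_config(seed = 2, n_sites = 20000, chrom_length = 1e6,
                      n_founders = 20, n_per_pop = c(p = 4),
                      inversions = list(), centromere = NULL,
                      telomere = NULL)
  f20 <- simulate_founders(cfg20)
  h19 <- sum(1 / (1:19))
  expect_equal(mean(f20$p_anc == 1 / 20), 1 / h19, tolerance = 0.05)
  expect_error(simulate_founders(
    small_sim_config(seed = 1, n_sites = 1e6, chrom_length = 100)),
    "exceeds")
})

test_that("identical config and seed reproduce files byte for byte", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- function() small_sim_config(seed = 33, n_sites = 60,
                                     missing_rate = 0.05)
  simulate_dataset(cfg(), dir = d1)
  simulate_dataset(cfg(), dir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_true(all(unname(tools::md5sum(f1)) == unname(tools::md5sum(f2))))
})

test_that("divergence limits behave as the Balding-Nichols model dictates", {
  f <- simulate_founders(small_sim_config(seed = 3, theta_fst = 0))
  p0 <- simulate_population(f, small_sim_config(seed = 3, theta_fst = 0))
  expect_equal(unname(p0$truth$p_pop[, 1]), f$p_anc)  # theta -> 0: p_k = p
  p1 <- simulate_population(f, small_sim_config(seed = 3, theta_fst = 1))
  expect_true(all(p1$truth$p_pop %in% c(0, 1)))       # theta -> 1: fixation
})

test_that("switch rate zero copies whole founder haplotypes", {
  cfg <- small_sim_config(seed = 4, switch_rate = 0, missing_rate = 0)
  p <- simulate_population(simulate_founders(cfg), cfg)
  expect_true(all(p$truth$n_switches == 0))
})

test_that("seed is mandatory and invalid geometry is rejected", {
  expect_error(sim_config(), "seed")
  expect_error(small_sim_config(seed = 1, switch_rate = 2), "rates")
  expect_error(sim_config(seed = 1, inversions = list(
    list(name = "x", start = 5e5, end = 2e6, suppression = 0))),
    "inversion")
  expect_error(sim_config(seed = 1, inversions = list(
    list(name = "x", start = 1e5, end = 2e5, suppression = 0,
         karyotypes = rep(3, 24)))),
    "karyotype")
})

test_that("emitted VCF round-trips through read_vcf", {
  ds <- simulate_dataset(small_sim_config(seed = 6, missing_rate = 0.03),
                         dir = tempfile())
  y <- read_vcf(ds$files$paths$low)
  x <- ds$files$low
  expect_identical(y$pos, x$pos)
  expect_identical(y$gt1, x$gt1)
  expect_identical(y$gt2, x$gt2)
  expect_equal(y$info, x$info)
})

test_that("engineered failures are excluded at exactly their stage", {
  cfg <- small_sim_config(seed = 8, n_sites = 200, chrom_length = 50000,
                          missing_rate = 0,
                          engineered = list(qd = 0.1, mq = 0, fs = 0,
                                            haplotype_score = 0,
                                            mq_rank_sum = 0,
                                            read_pos_rank_sum = 0,
                                            low_qual = 0, missing = 0.05,
                                            not_in_hc = 0.1,
                                            low_carrier = 0.05,
                                            multiallelic = 0.05))
  ds <- simulate_dataset(cfg)
  out <- cascade_filter(ds$files$low, ds$files$hc_keys)
  truth <- ds$files$truth
  # stages that cannot occur naturally here match the engineered set exactly
  expect_equal(which(out$stage == "hard_filter"),
               which(truth$engineered_stage == "hard_filter"))
  expect_equal(which(out$stage == "not_called_in_all"),
               which(truth$engineered_stage == "not_called_in_all"))
  expect_equal(which(out$stage == "not_in_high_confidence"),
               which(truth$engineered_stage == "not_in_high_confidence"))
  expect_equal(which(out$stage == "multiallelic"),
               which(truth$engineered_stage == "multiallelic"))
  # engineered low-carrier sites all land at the carrier rule (natural
  # low-frequency sites may join them there)
  eng_lc <- which(truth$engineered_stage == "minor_allele_carriers")
  expect_true(all(out$stage[eng_lc] == "minor_allele_carriers"))
})

test_that("with no missing data the called-in-all rule excludes nothing", {
  cfg <- small_sim_config(seed = 9, missing_rate = 0,
                          engineered = list(missing = 0))
  ds <- simulate_dataset(cfg)
  out <- cascade_filter(ds$files$low, ds$files$hc_keys)
  led <- out$ledger
  expect_equal(led$sites_excluded[led$stage == "not_called_in_all"], 0L)
})

test_that("simulated depth is depressed in centromere and telomere", {
  cfg <- sim_config(seed = 10, n_sites = 10, chrom_length = 30000,
                    n_per_pop = c(p = 4), inversions = list(),
                    centromere = list(start = 25000, end = 30000,
                                      suppression = 0.1),
                    telomere = list(start = 0, end = 2000))
  d <- simulate_depth(cfg, mean_depth = 40, suppressed_mean = 0.5)
  s <- depth_summary(d, chrom_lengths = c("2R" = 30000))
  inside <- d$pos > 25000
  background <- d$pos > 2000 & d$pos <= 25000
  expect_gt(mean(d$depth[background]), 30)
  expect_lt(sum(d$depth[inside]) / 5000, 2)
  expect_gt(s$pct_zero, 5)  # suppressed zones contribute zero-depth bases
})
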