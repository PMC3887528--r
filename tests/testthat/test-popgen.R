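test_that("site_pi equals the exhaustive allele-pair mismatch fraction", {
  # worked example: dosages [0,1,1,2] -> n = 8, j = 4 -> 32/56
  expect_equal(site_pi(c(0, 1, 1, 2)), 32 / 56)
  expect_equal(oracle_pi(c(0, 1, 1, 2)), 32 / 56)
  expect_equal(site_pi(c(0, 0, 0, 0)), 0)
  expect_true(is.na(site_pi(c(2, NA))) == FALSE)  # n = 2 called, j = 2
  expect_equal(site_pi(c(2, NA)), 0)
  expect_true(is.na(site_pi(c(NA, NA))))

  set.seed(11)
  for (i in 1:200) {
    d <- sample(c(0:2, NA), sample(2:12, 1), replace = TRUE)
    expect_equal(site_pi(d), oracle_pi(d), tolerance = 1e-12)
  }
})

test_that("site_pi is invariant under dosage flip", {
  set.seed(12)
  for (i in 1:50) {
    d <- sample(c(0:2, NA), 10, replace = TRUE)
    expect_equal(site_pi(d), site_pi(2 - d))
  }
})

test_that("site_pi_table flags undefined sites and matches site_pi", {
  gm <- records_to_matrix(mk_sites(c(100, 200),
                                   c("0/1", "./.", "./.", "./.")))
  expect_message(tab <- site_pi_table(gm), "skipped")
  expect_equal(tab$pi[1], site_pi(c(1, NA)))
  expect_true(is.na(tab$pi[2]))
  expect_equal(tab$n_alleles, c(2L, 0L))
})

test_that("windowed pi divides summed site pi by window length", {
  pi_df <- data.frame(chrom = "2R", pos = c(50, 60), pi = c(0.5, 0.25))
  w <- windowed_pi(pi_df, c("2R" = 100), bin = 100)
  expect_equal(w$value, 0.0075)
  # empty window reports 0, not exclusion: pi is defined over all bases
  w2 <- windowed_pi(pi_df, c("2R" = 300), bin = 100)
  expect_equal(w2$value, c(0.0075, 0, 0))
  expect_false(any(w2$excluded))
  # adjacent disjoint windows are independent (brute-force check)
  pi_df3 <- data.frame(chrom = "2R", pos = c(50, 150), pi = c(0.4, 0.8))
  w3 <- windowed_pi(pi_df3, c("2R" = 200), bin = 100)
  expect_equal(w3$value, c(0.004, 0.008))
})

test_that("snp_density reports 1 SNP per X bases", {
  expect_equal(snp_density(seq_len(10), 2270), 227)
  expect_equal(snp_density(1, 318), 318)
  expect_true(is.na(snp_density(integer(0), 1000)))
  expect_error(snp_density(1:3, 0), "positive")
})

test_that("Weir-Cockerham components match an independent transcription", {
  # fixed difference: F_ST exactly 1 regardless of sample size
  for (n in c(2, 10, 25)) {
    comp <- wc_fst_site(list(rep(0, n), rep(2, n)))
    expect_equal(unname(comp["a"] / sum(comp)), 1)
  }
  # global monomorphism: zero components, aggregate undefined
  comp0 <- wc_fst_site(list(rep(0, 5), rep(0, 5)))
  expect_equal(unname(comp0), c(0, 0, 0))
  expect_true(is.na(wc_fst_aggregate(
    data.frame(a = comp0[1], b = comp0[2], c = comp0[3]))))

  # spec-style worked case plus randomized cases vs the scalar oracle
  ex <- list(c(0, 1, 2, 1), c(0, 0, 1, 0))
  expect_equal(wc_fst_site(ex), oracle_wc(ex), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:100) {
    r <- sample(2:4, 1)
    dos <- lapply(seq_len(r), function(k)
      sample(c(0:2, NA), sample(3:10, 1), replace = TRUE))
    if (any(vapply(dos, function(d) all(is.na(d)), TRUE))) next
    expect_equal(wc_fst_site(dos), oracle_wc(dos), tolerance = 1e-10)
  }
})

test_that("components from a genotype matrix match per-site computation", {
  set.seed(31)
  ds <- simulate_dataset(small_sim_config(seed = 31, n_sites = 40,
                                          missing_rate = 0.1))
  gm <- ds$population$matrix
  comp <- wc_fst_components(gm)
  pops <- unique(gm$populations)
  for (i in c(1, 7, 20, 40)) {
    dos <- lapply(pops, function(p) gm$dosage[i, gm$populations == p])
    expect_equal(unname(unlist(comp[i, c("a", "b", "c")])),
                 unname(wc_fst_site(dos)), tolerance = 1e-10)
  }
})

test_that("identical frequencies with equal n give non-positive F_ST", {
  # same allele frequency and heterozygosity in both populations
  d <- c(0, 0, 1, 1, 2, 2)
  comp <- wc_fst_site(list(d, d))
  fst <- wc_fst_aggregate(data.frame(a = comp[1], b = comp[2], c = comp[3]))
  expect_lte(fst, 0)  # negative estimates are reported, not clamped
})

test_that("ratio-of-sums aggregation is additive over concatenation", {
  set.seed(41)
  mk <- function(n) data.frame(
    a = stats::rnorm(n, 0.01), b = abs(stats::rnorm(n)), c = abs(stats::rnorm(n)))
  A <- mk(50); B <- mk(30)
  both <- rbind(A, B)
  sa <- function(d) { s <- d$a + d$b + d$c; u <- s > 0
                      c(sum(d$a[u]), sum(s[u])) }
  expect_equal(wc_fst_aggregate(both),
               (sa(A)[1] + sa(B)[1]) / (sa(A)[2] + sa(B)[2]))
})
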