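test_that("hard filters use strict inequalities and list every reason", {
  x <- mk_sites(
    c(100, 200, 300, 400, 500),
    rep(c("0/1", "1/1"), each = 5),
    info = list(QD = c(1.5, 2.0, NA, 1.9, 25),
                MQ = c(50, 40, NA, 39, 50),
                FS = c(10, 60, NA, 61, 10),
                HaplotypeScore = c(1, 13, NA, 14, 1),
                MQRankSum = c(0, -12.5, NA, -12.6, 0),
                ReadPosRankSum = c(0, -8.0, NA, -8.1, 0)))
  hf <- hard_filter(x)
  # QD = 1.5 fails; boundary values (MQ = 40, FS = 60, ...) all pass;
  # absent tags never fail; every violated tag listed
  expect_equal(hf$pass, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(hf$reasons[[1]], "QD")
  expect_setequal(hf$reasons[[4]],
                  c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                    "ReadPosRankSum"))
  expect_length(hf$reasons[[3]], 0)
})

test_that("high-confidence set enforces strict QUAL/DP bounds and SNP-ness", {
  x <- mk_sites(c(100, 200, 300, 400, 500),
                rep(c("0/1", "1/1"), each = 5),
                ref = c("A", "A", "A", "A", "A"),
                alt = c("T", "T", "T", "AT", "T"),
                qual = c(31, 30, 31, 31, 31),
                info = list(DP = c(31, 31, 30, 31, 31),
                            QD = c(10, 10, 10, 10, 1)))
  hc <- build_high_confidence_set(x)
  expect_equal(hc, "2R:100:A:T")  # QUAL=30, DP=30, indel, QD-fail excluded
})

test_that("cascade rules fire in order with exact boundary behavior", {
  # 6 samples; sites crafted to fail exactly one rule each
  gts <- function(...) c(...)
  x <- mk_sites(
    pos = c(100, 200, 300, 400, 500, 600, 700),
    gt = rbind(
      gts("0/1", "0/1", "0/1", "1/1", "0/0", "0/1"),  # retained
      gts("./.", "0/1", "0/1", "1/1", "0/0", "0/1"),  # rule 1: missing
      gts("0/1", "0/1", "0/1", "1/1", "0/0", "0/1"),  # rule 2: not in hc
      gts("0/1", "0/1", "0/1", "0/1", "0/0", "0/0"),  # minor in 4 carriers
      gts("0/1", "0/1", "0/1", "0/1", "0/1", "0/0"),  # minor in 5: retained
      gts("1/1", "1/2", "1/2", "1/2", "1/2", "1/2"),  # rule 4: two non-ref
      gts("0/1", "0/1", "0/1", "1/1", "0/0", "0/1")), # hard filter (QD)
    alt = c("T", "T", "T", "T", "T", "T,G", "T"),
    info = list(QD = c(NA, NA, NA, NA, NA, NA, 0.5)),
    samples = paste0("S", 1:6))
  hc <- c("2R:100:A:T", "2R:200:A:T", "2R:400:A:T", "2R:500:A:T",
          "2R:600:A:T", "2R:700:A:T")
  out <- cascade_filter(x, hc, min_carriers = 5)
  expect_equal(as.character(out$stage),
               c("retained", "not_called_in_all", "not_in_high_confidence",
                 "minor_allele_carriers", "retained", "multiallelic",
                 "hard_filter"))
  expect_equal(out$retained$pos, c(100L, 500L))
  expect_error(cascade_filter(x, hc, n_samples = 24), "24")
})

test_that("a site failing several rules is charged to the first stage only", {
  x <- mk_sites(100, c("./.", "0/1", "0/1", "0/1"),
                info = list(QD = 0.1), samples = paste0("S", 1:4))
  out <- cascade_filter(x, hc = character(0), min_carriers = 5)
  expect_equal(as.character(out$stage), "hard_filter")
  # and the retained set is order-independent: it passes all rules jointly
  expect_equal(n_sites(out$retained), 0)
})

test_that("cascade conservation holds and the cascade is idempotent", {
  for (s in 1:10) {
    cfg <- small_sim_config(seed = 100 + s, n_sites = 50,
                            missing_rate = stats::runif(1, 0, 0.1))
    ds <- simulate_dataset(cfg)
    out <- cascade_filter(ds$files$low, ds$files$hc_keys)
    led <- out$ledger
    expect_equal(attr(led, "n_input"),
                 attr(led, "n_retained") + sum(led$sites_excluded))
    expect_silent(vcfpopgen:::validate_ledger(led))
    # idempotence: re-filtering the retained set excludes nothing
    again <- cascade_filter(out$retained, ds$files$hc_keys)
    expect_equal(sum(again$ledger$sites_excluded), 0)
  }
})

test_that("ledger_report prints conserved accounting and refuses bad ledgers", {
  stage <- factor(c(rep("hard_filter", 10), rep("not_called_in_all", 5),
                    rep("retained", 85)),
                  levels = c(vcfpopgen:::cascade_stages, "retained"))
  led <- vcfpopgen:::filter_ledger(stage)
  lines <- capture.output(rep <- ledger_report(led))
  expect_match(lines[length(lines)], "total\\s+100\\s+15\\s+85")

  bad <- led
  bad$sites_excluded[1] <- 99L
  expect_error(ledger_report(bad), "conservation|inconsistent")
})

test_that("an empty stream yields an all-zero conserved ledger", {
  x <- mk_sites(100, c("0/1", "1/1"))[integer(0)]
  out <- cascade_filter(x, hc = character(0))
  expect_equal(sum(out$ledger$sites_excluded), 0)
  expect_equal(attr(out$ledger, "n_input"), 0L)
  expect_silent(vcfpopgen:::validate_ledger(out$ledger))
})
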