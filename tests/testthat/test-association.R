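test_that("exact 2x2 results match the published burden and large-CNV examples", {
  f <- fisher_2x2(82, 6442, 74, 9164)
  expect_equal(f$or_cmle, 1.57, tolerance = 0.005)
  expect_equal(f$p, 0.0053, tolerance = 0.01)
  expect_equal(fisher_2x2(11, 6513, 1, 9237)$or_sample, 15.60,
               tolerance = 0.001)
  sym <- fisher_2x2(5, 95, 5, 95)
  expect_equal(sym$or_sample, 1); expect_equal(sym$or_cmle, 1, tolerance = 1e-6)
  expect_equal(sym$p, 1)
  small <- fisher_2x2(2, 3, 1, 4)
  expect_equal(small$p, 1.0, tolerance = 1e-12)
  expect_equal(small$or_sample, 8 / 3, tolerance = 1e-12)
  expect_error(fisher_2x2(-1, 2, 3, 4), "negative")
})

test_that("p-values and CMLE agree with hypergeometric enumeration oracles", {
  set.seed(46)
  for (rep in 1:80) {
    N <- sample(8:200, 1)
    a <- sample(0:(N %/% 4), 1); b <- sample(1:(N %/% 4), 1)
    c <- sample(0:(N %/% 4), 1); d <- N - a - b - c
    if (d < 1) next
    f <- fisher_2x2(a, b, c, d)
    expect_equal(f$p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    orc <- oracle_fisher_cmle(a, b, c, d)
    if (is.finite(orc) && orc > 0)
      expect_equal(f$or_cmle, orc, tolerance = 1e-6)
  }
})

test_that("zero cells yield a p-value but no sample OR or confidence interval", {
  f <- fisher_2x2(5, 95, 0, 100)
  expect_true(is.na(f$or_sample))
  expect_true(is.na(f$ci_low) && is.na(f$ci_high))
  expect_false(is.na(f$p))
})

test_that("burden strata reproduce the published length-bin odds ratios", {
  ## deletions >400 kb: 82 case events vs 74 control events
  b <- burden_test(82, 6524, 74, 9238, ">400kb")
  expect_equal(b$or_cmle, 1.57, tolerance = 0.005)
  b2 <- burden_test(570, 6524, 820, 9238, "0-20kb")
  expect_equal(b2$or_cmle, 0.98, tolerance = 0.005)
  eq <- burden_test(50, 1000, 50, 1000, "flat")
  expect_equal(eq$or_sample, 1); expect_equal(eq$p, 1)
})

test_that("burden_strata bins calls by length with half-open boundaries", {
  ids <- c(paste0("ca", 1:40), paste0("co", 1:40))
  sheet <- sample_sheet(data.frame(
    sample_id = ids, phenotype = rep(c("case", "control"), each = 40),
    plate_id = "P1", cohort_id = "c", dna_source = "genomic", sex = "F"))
  calls <- cnv_calls(data.frame(
    sample_id = c("ca1", "ca2", "co1", "ca3", "co2"),
    chrom = "1",
    start_bp = c(1, 1, 1, 1, 1),
    end_bp = c(20000, 20001, 400000, 400001, 500000),
    copy_number = 1, n_snps = 10, quality = 1))
  bs <- burden_strata(calls, sheet)
  del <- bs[bs$class == "DEL", ]
  expect_equal(del$events_case[del$stratum == "0-20kb"], 1)   # 20000 in bin 1
  expect_equal(del$events_case[del$stratum == "20-400kb"], 1) # 20001 in bin 2
  expect_equal(del$events_control[del$stratum == "20-400kb"], 1)
  expect_equal(del$events_case[del$stratum == ">400kb"], 1)   # 400001 strict
  expect_equal(del$events_control[del$stratum == ">400kb"], 1)
  expect_equal(del$bonferroni_m[del$stratum == ">400kb"], 6L)
})

test_that("the regional Bonferroni threshold for 383 tests is 1.31e-4", {
  expect_equal(bonferroni_threshold(383), 1.31e-4, tolerance = 0.005)
  expect_error(bonferroni_threshold(0), "m")
})

test_that("null CNVR scans produce uniform p-values", {
  set.seed(47)
  ok <- 0
  for (rep in 1:10) {
    ## 200 null CNVRs: carriers split binomially between equal-size groups
    tot <- rpois(200, 8) + 1
    cc <- rbinom(200, tot, 0.5)
    cnvrs <- structure(data.frame(
      cnvr_id = paste0("r", 1:200), chrom = "1", start_bp = 1:200 * 1000,
      end_bp = 1:200 * 1000 + 500, cnv_class = "DEL",
      carriers_case = cc, carriers_control = tot - cc,
      frequency = tot / 2000), class = c("cnvr_table", "data.frame"))
    sc <- cnvr_scan(cnvrs, 1000, 1000)
    ## exact-test p-values are discrete and conservative, so only the
    ## inflation side is informative: the empirical CDF must not run above
    ## the uniform by more than the one-sided 5% KS band, and small
    ## p-values must not be over-represented
    p <- sort(sc$table$p)
    d_plus <- max(seq_along(p) / length(p) - p)
    ok <- ok + (d_plus < 1.22 / sqrt(length(p)) && mean(p < 0.05) <= 0.07)
  }
  expect_gte(ok, 9)
})

test_that("transmission tallies follow the children-times-carrier-parents rule", {
  ped <- pedigree(data.frame(
    family_id = "F1",
    individual_id = c("fa", "mo", "k1", "k2", "k3"),
    father_id = c(NA, NA, "fa", "fa", "fa"),
    mother_id = c(NA, NA, "mo", "mo", "mo"),
    sex = c("M", "F", "M", "F", "M"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  "affected")))
  ## one carrier parent, three children, two carrying
  calls <- cnv_calls(data.frame(
    sample_id = c("fa", "k1", "k2"), chrom = "1", start_bp = c(100, 100, 110),
    end_bp = c(1000, 1000, 990), copy_number = 1, n_snps = 10, quality = 1))
  tc <- transmission_counts(calls, ped)
  agg <- tc$aggregate
  expect_equal(agg$possible[agg$affection == "affected"], 3)
  expect_equal(agg$transmitted[agg$affection == "affected"], 2)
  ## both parents carriers, two children, each carrying once -> 2/4
  ped2 <- pedigree(data.frame(
    family_id = "F2", individual_id = c("fa2", "mo2", "c1", "c2"),
    father_id = c(NA, NA, "fa2", "fa2"), mother_id = c(NA, NA, "mo2", "mo2"),
    sex = c("M", "F", "F", "M"),
    affection = c("unaffected", "unaffected", "affected", "affected")))
  calls2 <- cnv_calls(data.frame(
    sample_id = c("fa2", "mo2", "c1", "c2"), chrom = "1",
    start_bp = c(100, 105, 100, 102), end_bp = c(1000, 995, 1000, 1001),
    copy_number = 1, n_snps = 10, quality = 1))
  tc2 <- transmission_counts(calls2, ped2)
  agg2 <- tc2$aggregate
  expect_equal(agg2$possible[agg2$affection == "affected"], 4)
  expect_equal(agg2$transmitted[agg2$affection == "affected"], 2)
})

test_that("the published transmission rates give a burden ratio of 1.01", {
  expect_equal(transmission_burden_ratio(44.2, 43.8), 1.01, tolerance = 0.005)
  expect_equal(transmission_burden_ratio(42.3, 46.4), 0.91, tolerance = 0.005)
  expect_error(transmission_burden_ratio(10, 0), "positive")
})

test_that("the exact TDT doubles the smaller binomial tail and caps at one", {
  expect_equal(tdt_exact(5, 5), 0.0625, tolerance = 1e-12)
  expect_equal(tdt_exact(10, 20), 1.0)
  expect_equal(tdt_exact(28, 81), oracle_tdt(28, 81), tolerance = 1e-12)
  set.seed(48)
  for (rep in 1:40) {
    n <- sample(1:500, 1); t <- sample(0:n, 1)
    expect_equal(tdt_exact(t, n), oracle_tdt(t, n), tolerance = 1e-12)
  }
  expect_error(tdt_exact(1, 0), "possible")
})

test_that("overlapping parental calls disqualify a child call from de novo status", {
  man <- tiny_manifest(60, pfb = 0.5)
  ped <- pedigree(data.frame(
    family_id = "F1", individual_id = c("fa", "mo", "kid"),
    father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
    sex = c("M", "F", "M"),
    affection = c("unaffected", "unaffected", "affected")))
  lrr <- matrix(rnorm(3 * 60, 0, 0.16), 3, 60,
                dimnames = list(c("fa", "mo", "kid"), man$snp_id))
  baf <- matrix(0.5, 3, 60, dimnames = dimnames(lrr))
  gt <- matrix("AB", 3, 60, dimnames = dimnames(lrr))
  panel <- intensity_panel(lrr, baf, gt, man)
  calls <- cnv_calls(data.frame(
    sample_id = c("kid", "fa"), chrom = "1", start_bp = c(10000, 15000),
    end_bp = c(20000, 25000), copy_number = 1, n_snps = 10, quality = 1))
  dn <- denovo_burden(calls, ped, panel)
  expect_equal(dn$calls$denovo_status[dn$calls$sample_id == "kid"],
               "inherited")
  ## diploid parents -> the same child call is de novo
  calls2 <- calls[calls$sample_id == "kid", ]
  dn2 <- denovo_burden(calls2, ped, panel)
  expect_equal(dn2$calls$denovo_status, "de_novo")
  ## a parent absent from the panel -> unknown, excluded from the test
  panel3 <- subset_panel(panel, c("mo", "kid"))
  dn3 <- denovo_burden(calls2, ped, panel3)
  expect_equal(dn3$calls$denovo_status, "unknown")
})

test_that("the affected-only de novo excess is significant at the published counts", {
  f <- fisher_2x2(18, 5077 - 18, 0, 1282)
  expect_lte(f$p, 0.05)
})

test_that("required sample sizes shrink with effect size and frequency", {
  pg <- power_grid(c(1, 1.5, 2, 3), c(0.001, 0.005, 0.02))
  m <- pg$required_units
  expect_true(all(is.na(m[, "or1"])))
  for (i in seq_len(nrow(m)))
    expect_true(all(diff(m[i, -1]) <= 0, na.rm = TRUE))
  for (j in 2:ncol(m))
    expect_true(all(diff(m[, j]) <= 0, na.rm = TRUE))
})

test_that("Monte-Carlo power increases with N and brackets the normal method", {
  set.seed(49)
  p40 <- rarecnv:::.power_mc(40000, 0.05, 1.25, 5e-5, 1, n_rep = 150)
  p30 <- rarecnv:::.power_mc(30000, 0.05, 1.25, 5e-5, 1, n_rep = 150)
  expect_gte(p40, p30)
  pg_n <- power_grid(1.25, 0.05)$required_units[1, 1]
  set.seed(50)
  pg_mc <- power_grid(1.25, 0.05, method = "montecarlo", max_units = 16,
                      n_rep = 120)$required_units[1, 1]
  expect_lte(max(pg_n, pg_mc) / min(pg_n, pg_mc), 2)
})

test_that("the large-CNV report applies a strict 3 Mb rule and the carrier test", {
  ids <- c(paste0("ca", 1:20), paste0("co", 1:20))
  sheet <- sample_sheet(data.frame(
    sample_id = ids, phenotype = rep(c("case", "control"), each = 20),
    plate_id = "P1", cohort_id = "c", dna_source = "genomic", sex = "M"))
  calls <- cnv_calls(data.frame(
    sample_id = c("ca1", "ca2", "co1"), chrom = "1", start_bp = 1,
    end_bp = c(3000001, 2999999, 4e6), copy_number = 1, n_snps = 300,
    quality = 1))
  r <- large_cnv_table(calls, sheet)
  expect_equal(nrow(r$table), 2)               # 3,000,001 in; 2,999,999 out
  expect_equal(sort(r$table$sample_id), c("ca1", "co1"))
  expect_equal(r$test$a, 1); expect_equal(r$test$c, 1)
  empty <- large_cnv_table(calls[0, ], sheet)
  expect_equal(nrow(empty$table), 0)
})
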