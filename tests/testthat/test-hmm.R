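# emissions/transitions shared with the oracles come from the package's
# exported C++ kernels; the oracles re-derive the dynamic programming by
# explicit path enumeration.

em_of <- function(lrr, baf, pfb, params = hmm_params()) {
  rarecnv:::cpp_emission_loglik(lrr, baf, pfb, params$lrr_mean, params$lrr_sd,
                                params$baf_sd, params$eps_out)
}

test_that("transition rows sum to one for any inter-marker distance", {
  p <- hmm_params()
  for (d in c(1, 100, 1e4, 1e5, 1e7)) {
    A <- oracle_trans(d, p$D, p$pi)
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("an all-diploid sample yields no calls", {
  man <- tiny_manifest(200, pfb = runif(200, 0.05, 0.95))
  set.seed(33)
  lrr <- rnorm(200, 0, 0.16)
  gtc <- rbinom(200, 2, man$pfb)
  baf <- pmin(1, pmax(0, gtc / 2 + rnorm(200, 0, 0.03)))
  calls <- viterbi_segments(lrr, baf, man, sample_id = "x")
  expect_equal(nrow(calls), 0)
})

test_that("planted deletion runs are recovered with near-exact boundaries", {
  p <- hmm_params()
  hits <- 0
  set.seed(34)
  for (rep in 1:200) {
    n <- 150
    man <- tiny_manifest(n, pfb = runif(n, 0.05, 0.95))
    lrr <- rnorm(n, 0, 0.16)
    gtc <- rbinom(n, 2, man$pfb)
    baf <- pmin(1, pmax(0, gtc / 2 + rnorm(n, 0, 0.03)))
    i0 <- 51; i1 <- 100
    lrr[i0:i1] <- rnorm(50, -0.67, 0.16)
    hap <- rbinom(50, 1, man$pfb[i0:i1])
    baf[i0:i1] <- pmin(1, pmax(0, hap + rnorm(50, 0, 0.03)))
    calls <- viterbi_segments(lrr, baf, man, p, "x")
    del <- calls[calls$copy_number == 1, ]
    ok <- nrow(del) == 1 &&
      abs(match(del$start_bp, man$pos_bp) - i0) <= 2 &&
      abs(match(del$end_bp, man$pos_bp) - i1) <= 2
    hits <- hits + ok
  }
  expect_gte(hits / 200, 0.95)
})

test_that("posterior rows sum to one and match path enumeration on short windows", {
  p <- hmm_params()
  set.seed(35)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    man <- tiny_manifest(n, pfb = runif(n, 0.1, 0.9),
                         spacing = sample(c(1e3, 5e4), 1))
    lrr <- rnorm(n, sample(c(0, -0.67, 0.4), 1), 0.2)
    baf <- runif(n)
    post <- state_posteriors(lrr, baf, man, p)
    expect_equal(unname(rowSums(post)), rep(1, n), tolerance = 1e-9)
    logem <- em_of(lrr, baf, man$pfb, p)
    orc <- oracle_posteriors(logem, man$pos_bp, p$pi, p$D)
    expect_equal(unname(post), orc, tolerance = 1e-9)
  }
})

test_that("the Viterbi path is never beaten by an enumerated path", {
  p <- hmm_params()
  set.seed(36)
  for (rep in 1:5) {
    n <- 5
    man <- tiny_manifest(n, pfb = runif(n, 0.1, 0.9))
    lrr <- rnorm(n, sample(c(-0.67, 0, 0.68), 1), 0.3)
    baf <- runif(n)
    logem <- em_of(lrr, baf, man$pfb, p)
    path <- rarecnv:::cpp_viterbi(logem, as.numeric(man$pos_bp), p$pi, p$D)
    lp <- rarecnv:::cpp_path_loglik(path, logem, as.numeric(man$pos_bp),
                                    p$pi, p$D)
    expect_gte(lp + 1e-9, oracle_best_path(logem, man$pos_bp, p$pi, p$D))
  }
})

test_that("overwhelming single-state evidence saturates the interior posterior", {
  p <- hmm_params()
  n <- 50
  man <- tiny_manifest(n, pfb = 0.5)
  lrr <- rep(-0.67, n) + runif(n, -0.001, 0.001)   # |LRR - mean| < 0.01 SD
  baf <- rep(0, n)
  post <- state_posteriors(lrr, baf, man, p)
  expect_true(all(post[5:45, "CN1"] > 0.999))
})

test_that("score ties decode deterministically to the lower copy number", {
  man <- tiny_manifest(2, pfb = 0.5)
  ## with no data at all the prior dominates: diploid everywhere
  expect_equal(nrow(viterbi_segments(c(NA, NA), c(NA, NA), man,
                                     hmm_params(), "x")), 0)
  ## constructed exact tie: CN1 and CN3 sit symmetrically around the
  ## observations with equal SDs and equal priors, CN2 is implausible;
  ## the tie-break must pick the lower copy number, reproducibly
  p <- hmm_params(lrr_mean = c(-5, -0.5, 5, 0.5, 6),
                  lrr_sd = c(1, 0.2, 0.2, 0.2, 0.2),
                  pi = c(0.001, 0.024, 0.95, 0.024, 0.001))
  calls <- viterbi_segments(c(0, 0), c(NA, NA), man, p, "x")
  expect_equal(unique(calls$copy_number), 1L)
  expect_identical(calls, viterbi_segments(c(0, 0), c(NA, NA), man, p, "x"))
})

test_that("fragment merging follows the strict 20% gap rule", {
  a <- make_calls(c(1, 140001), c(100000, 240000))
  m <- merge_fragments(a)                          # gap 40000/240000 = 0.167
  expect_equal(nrow(m), 1)
  expect_equal(m$start_bp, 1); expect_equal(m$end_bp, 240000)
  b <- make_calls(c(1, 150001), c(100000, 250000)) # gap 50000/250000 = 0.2
  expect_equal(nrow(merge_fragments(b)), 2)
  cc <- make_calls(c(1, 140001), c(100000, 240000), cn = c(1, 3))
  expect_equal(nrow(merge_fragments(cc)), 2)       # class mismatch
  expect_error(merge_fragments(make_calls(c(1, 50), c(100, 150))), "overlap")
})

test_that("merging is idempotent and never shrinks covered bases", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    lens <- sample(1e3:5e4, n)
    gaps <- sample(1e2:5e4, n)
    starts <- cumsum(c(1, head(lens + gaps, -1)))
    ends <- starts + lens - 1
    calls <- make_calls(starts, ends, cn = sample(c(1, 3), n, TRUE))
    m1 <- merge_fragments(calls)
    m2 <- merge_fragments(m1)
    expect_equal(m1$start_bp, m2$start_bp)
    expect_equal(m1$end_bp, m2$end_bp)
    expect_gte(sum(m1$length_bp), sum(calls$length_bp))
  }
})

test_that("quality equals the mean posterior of the called state", {
  p <- hmm_params()
  n <- 40
  man <- tiny_manifest(n, pfb = 0.5)
  set.seed(38)
  lrr <- c(rnorm(10, 0, 0.16), rnorm(20, -0.67, 0.16), rnorm(10, 0, 0.16))
  baf <- c(runif(10, 0.45, 0.55), rbinom(20, 1, 0.5) + rnorm(20, 0, 0.02),
           runif(10, 0.45, 0.55))
  baf <- pmin(1, pmax(0, baf))
  post <- state_posteriors(lrr, baf, man, p)
  call <- list(chrom = "1", start_bp = man$pos_bp[11], end_bp = man$pos_bp[30],
               copy_number = 1)
  q <- score_quality(call, post, man)
  logem <- em_of(lrr, baf, man$pfb, p)
  expect_lte(q, 1); expect_gte(q, 0)
  expect_equal(q, mean(post[11:30, "CN1"]), tolerance = 1e-12)
  ## perfect posteriors give quality 1
  fake <- post; fake[, ] <- 0; fake[, "CN1"] <- 1
  expect_equal(score_quality(call, fake, man), 1)
  expect_error(score_quality(list(chrom = "9", start_bp = 1, end_bp = 2,
                                  copy_number = 1), post, man), "supporting")
})

test_that("median call quality decreases as emission noise grows", {
  p <- hmm_params()
  med_q <- vapply(c(0.10, 0.22, 0.34), function(sigma) {
    set.seed(39)
    qs <- replicate(60, {
      n <- 60
      man <- tiny_manifest(n, pfb = 0.5)
      lrr <- rnorm(n, 0, sigma)
      lrr[21:40] <- rnorm(20, -0.67, sigma)
      baf <- pmin(1, pmax(0, rbinom(n, 2, 0.5) / 2 + rnorm(n, 0, 0.03)))
      baf[21:40] <- pmin(1, pmax(0, rbinom(20, 1, 0.5) + rnorm(20, 0, 0.03)))
      post <- state_posteriors(lrr, baf, man, p)
      mean(post[21:40, "CN1"])
    })
    median(qs)
  }, numeric(1))
  expect_true(all(diff(med_q) < 0))
})

test_that("parental evidence vetting separates carrier from diploid parents", {
  p <- hmm_params()
  n <- 60
  man <- tiny_manifest(n, pfb = 0.5)
  call <- list(chrom = "1", start_bp = man$pos_bp[21],
               end_bp = man$pos_bp[40], copy_number = 1)
  set.seed(40)
  supported <- 0; unsupported <- 0
  for (rep in 1:200) {
    carrier_lrr <- rnorm(n, 0, 0.16); carrier_lrr[21:40] <- rnorm(20, -0.67, 0.16)
    carrier_baf <- pmin(1, pmax(0, rbinom(n, 2, 0.5) / 2 + rnorm(n, 0, 0.03)))
    carrier_baf[21:40] <- pmin(1, pmax(0, rbinom(20, 1, 0.5) + rnorm(20, 0, 0.03)))
    supported <- supported +
      (parent_state_evidence(call, carrier_lrr, carrier_baf, man, p) == "supported")
    dip_lrr <- rnorm(n, 0, 0.16)
    dip_baf <- pmin(1, pmax(0, rbinom(n, 2, 0.5) / 2 + rnorm(n, 0, 0.03)))
    unsupported <- unsupported +
      (parent_state_evidence(call, dip_lrr, dip_baf, man, p) == "unsupported")
  }
  expect_gte(supported / 200, 0.99)
  expect_gte(unsupported / 200, 0.95)
  expect_equal(parent_state_evidence(call, rep(NA_real_, n), rep(NA_real_, n),
                                     man, p), "unknown")
})

test_that("calls never span chromosome boundaries", {
  man <- build_manifest(600, c(`1` = 1, `2` = 1), seed = 41)
  set.seed(42)
  lrr <- rnorm(600, 0, 0.16)
  half <- which(man$chrom == "1")
  lrr[(max(half) - 19):(min(which(man$chrom == "2")) + 19)] <- -0.67
  baf <- rep(NA_real_, 600)
  calls <- viterbi_segments(lrr, baf, man, sample_id = "x")
  for (r in seq_len(nrow(calls))) {
    idx <- man$chrom == calls$chrom[r]
    expect_true(calls$start_bp[r] >= min(man$pos_bp[idx]))
    expect_true(calls$end_bp[r] <= max(man$pos_bp[idx]))
  }
  expect_gte(nrow(calls), 2)  # the run is split at the boundary
})
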