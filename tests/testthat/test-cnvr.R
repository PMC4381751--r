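default_sheet <- function(ids, plates = "P1", pheno = "control") {
  sample_sheet(data.frame(sample_id = ids, phenotype = pheno,
                          plate_id = plates, cohort_id = "c1",
                          dna_source = "genomic", sex = "M"))
}

test_that("CNV-level filters enforce the SNP-count, telomere and count rules", {
  ids <- paste0("s", 1:60)
  sheet <- default_sheet(ids)
  calls <- cnv_calls(data.frame(
    sample_id = c("s1", "s2", "s3"), chrom = "1",
    start_bp = c(100, 5000, 9000), end_bp = c(200, 6000, 10000),
    copy_number = 1, n_snps = c(5, 6, 20), quality = c(0.99, 0.99, 0.5)))
  res <- apply_cnv_level_filters(calls, sheet)
  expect_false("s1" %in% res$calls$sample_id)   # 5 SNPs dropped
  expect_true("s2" %in% res$calls$sample_id)    # 6 SNPs kept
  ## low quality flagged, not dropped
  expect_true(res$calls$quality_flag[res$calls$sample_id == "s3"])
  ## telomere overlap by a single bp drops the call
  telo <- region_set("1", 200, 300, "telomere")
  res2 <- apply_cnv_level_filters(calls, sheet, telo)
  expect_false(any(res2$calls$start_bp == 100))
  expect_error(apply_cnv_level_filters(
    cnv_calls(data.frame(sample_id = "ghost", chrom = "1", start_bp = 1,
                         end_bp = 2, copy_number = 1, n_snps = 6,
                         quality = 1)), sheet), "ghost")
})

test_that("the per-sample CNV-count fence follows the mean + 3 SD arithmetic", {
  ids <- paste0("s", 1:51)
  sheet <- default_sheet(ids)
  ## counts {2 x 50, 60}: mean 3.14, sd 8.12 -> fence 27.5 -> s51 dropped
  rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    k <- if (i == 51) 60 else 2
    data.frame(sample_id = ids[i], chrom = "1",
               start_bp = seq(1e4, by = 1e5, length.out = k),
               end_bp = seq(1e4, by = 1e5, length.out = k) + 5e4,
               copy_number = 1, n_snps = 10, quality = 1)
  }))
  res <- apply_cnv_level_filters(cnv_calls(rows), sheet)
  expect_false("s51" %in% res$calls$sample_id)
  expect_true("s1" %in% res$calls$sample_id)
  ## counts {2,2,2,2,30}: mean 7.6, sd 12.5 -> fence 45.1 -> none dropped
  ids5 <- paste0("t", 1:5)
  rows5 <- do.call(rbind, lapply(seq_along(ids5), function(i) {
    k <- if (i == 5) 30 else 2
    data.frame(sample_id = ids5[i], chrom = "1",
               start_bp = seq(1e4, by = 1e5, length.out = k),
               end_bp = seq(1e4, by = 1e5, length.out = k) + 5e4,
               copy_number = 1, n_snps = 10, quality = 1)
  }))
  res5 <- apply_cnv_level_filters(cnv_calls(rows5), default_sheet(ids5))
  expect_setequal(unique(res5$calls$sample_id), ids5)
})

test_that("segment-group semantics give shared membership for chained overlaps", {
  calls <- make_calls(c(100, 150, 250), c(200, 300, 400),
                      sample_id = c("a", "b", "c"))
  g <- group_cnvrs(calls, n_samples = 100)
  expect_equal(nrow(g), 2)
  sizes <- sort(vapply(g$members, length, 0L))
  expect_equal(sizes, c(2L, 2L))
  ## b belongs to both groups
  cc <- attr(g, "calls")
  mem_samples <- lapply(g$members, function(m) sort(cc$sample_id[m]))
  expect_true(any(vapply(mem_samples, identical, TRUE, y = c("a", "b"))))
  expect_true(any(vapply(mem_samples, identical, TRUE, y = c("b", "c"))))
  single <- group_cnvrs(make_calls(5, 10), n_samples = 10)
  expect_equal(nrow(single), 1)
  expect_equal(single$start_bp, 5); expect_equal(single$end_bp, 10)
  expect_error(group_cnvrs(make_calls(c(1, 10), c(5, 20), cn = c(1, 3))),
               "separately")
})

test_that("random instances reproduce the maximal common-point-set oracle", {
  set.seed(43)
  for (rep in 1:60) {
    n <- sample(2:25, 1)
    s <- sample(1:60, n, replace = TRUE)
    e <- s + sample(0:40, n, replace = TRUE)
    calls <- cnv_calls(data.frame(
      sample_id = paste0("s", 1:n), chrom = "1", start_bp = s, end_bp = e,
      copy_number = 1, n_snps = 1, quality = 1))
    g <- group_cnvrs(calls, n_samples = n)
    cc <- attr(g, "calls")
    key0 <- paste(s, e, paste0("s", 1:n))
    ids <- lapply(g$members, function(m)
      sort(match(paste(cc$start_bp[m], cc$end_bp[m], cc$sample_id[m]), key0)))
    ## every group shares a common nucleotide
    for (m in ids) expect_lte(max(s[m]), min(e[m]))
    ## no emitted group is a strict subset of another
    for (i in seq_along(ids)) for (j in seq_along(ids))
      if (i != j) expect_false(length(ids[[i]]) < length(ids[[j]]) &&
                                 all(ids[[i]] %in% ids[[j]]))
    ## and the emitted set equals the brute-force maximal sets
    orc <- oracle_interval_groups(s, e)
    expect_equal(length(ids), length(orc))
    for (m in ids)
      expect_true(any(vapply(orc, identical, TRUE, x = m)))
    ## every call appears in at least one group
    expect_setequal(sort(unique(unlist(ids))), 1:n)
  }
})

test_that("grouping is invariant to input permutation", {
  set.seed(44)
  n <- 15
  s <- sample(1:50, n, replace = TRUE); e <- s + sample(5:30, n, replace = TRUE)
  calls <- cnv_calls(data.frame(sample_id = paste0("s", 1:n), chrom = "1",
                                start_bp = s, end_bp = e, copy_number = 3,
                                n_snps = 1, quality = 1))
  g1 <- group_cnvrs(calls, n)
  g2 <- group_cnvrs(calls[sample(n), ], n)
  k1 <- sort(paste(g1$start_bp, g1$end_bp, g1$n_members))
  k2 <- sort(paste(g2$start_bp, g2$end_bp, g2$n_members))
  expect_identical(k1, k2)
})

test_that("the rarity filter applies the strict 1% rule on distinct carriers", {
  calls <- make_calls(c(100, 120), c(200, 220), sample_id = c("a", "b"))
  g <- group_cnvrs(calls, n_samples = 100)
  expect_equal(nrow(filter_rare_cnvrs(g, 100)), 0)       # 2/100 > 0.01
  g2 <- group_cnvrs(make_calls(100, 200), n_samples = 101)
  expect_equal(nrow(filter_rare_cnvrs(g2, 101)), 1)      # 1/101 < 0.01
  expect_error(filter_rare_cnvrs(g, 0), "positive")
  ## a sample with two member calls counts once
  calls3 <- make_calls(c(100, 150), c(200, 260), sample_id = c("a", "a"))
  g3 <- group_cnvrs(calls3, n_samples = 150)
  expect_equal(g3$n_carriers, 1L)
})

test_that("CNVRs with too many low-quality members are removed entirely", {
  ## 3 of 4 members below 0.95 -> 75% failing > 20% -> CNVR dropped
  calls <- make_calls(c(100, 110, 120, 130), c(300, 310, 320, 330),
                      sample_id = paste0("s", 1:4),
                      quality = c(0.99, 0.5, 0.6, 0.7))
  g <- group_cnvrs(calls, n_samples = 1000)
  expect_equal(nrow(filter_rare_cnvrs(g, 1000)), 0)
  ## 1 of 6 failing (17%) -> member dropped, CNVR kept
  calls2 <- make_calls(seq(100, 150, by = 10), seq(300, 350, by = 10),
                       sample_id = paste0("s", 1:6),
                       quality = c(0.5, rep(0.99, 5)))
  g2 <- group_cnvrs(calls2, n_samples = 1000)
  f2 <- filter_rare_cnvrs(g2, 1000)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$n_members, 5L)
})

test_that("annotation overlap uses the 1-bp rule and matches a pairwise oracle", {
  genes <- region_set(c("1", "1"), c(200, 1000), c(300, 2000), "genes")
  genes$name <- c("GENE1", "GENE2")
  calls <- make_calls(c(100, 100), c(200, 199), sample_id = c("a", "b"))
  ann <- annotate_overlaps(calls, list(genes = genes))
  expect_true(ann$overlaps_genes[1])    # touches at 200
  expect_false(ann$overlaps_genes[2])   # ends at 199
  expect_equal(ann$genes_hits[[1]], "GENE1")
  set.seed(45)
  s <- sample(1:500, 30, TRUE); e <- s + sample(0:100, 30, TRUE)
  rcalls <- cnv_calls(data.frame(sample_id = "x", chrom = "1", start_bp = s,
                                 end_bp = e, copy_number = 1, n_snps = 1,
                                 quality = 1))
  rg <- region_set("1", rs <- sample(1:500, 10), rs + sample(0:100, 10, TRUE))
  ann2 <- annotate_overlaps(rcalls, list(r = rg))
  brute <- vapply(seq_len(30), function(i)
    any(s[i] <= rg$end_bp & e[i] >= rg$start_bp), logical(1))
  expect_equal(ann2$overlaps_r, brute)
})
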