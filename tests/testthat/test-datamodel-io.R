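test_that("long intensity files round-trip through the panel, preserving missingness", {
  man <- tiny_manifest(3)
  sheet <- sample_sheet(data.frame(
    sample_id = c("a", "b"), phenotype = c("case", "control"),
    plate_id = "P1", cohort_id = "c1", dna_source = "genomic", sex = "M"))
  lrr <- matrix(c(0.1, -0.2, NA, 0, 0.3, -0.1), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), man$snp_id))
  baf <- matrix(c(0, 0.5, NA, 1, NA, 0.33), 2, 3, byrow = TRUE,
                dimnames = dimnames(lrr))
  gt <- matrix(c("AA", "AB", "NC", "BB", "NC", "AB"), 2, 3, byrow = TRUE,
               dimnames = dimnames(lrr))
  p <- intensity_panel(lrr, baf, gt, man)
  f <- tempfile()
  write_intensity_long(p, f)
  p2 <- read_intensity_long(f, man, sheet)
  expect_equal(p2$lrr, p$lrr)
  expect_equal(p2$baf, p$baf)
  expect_equal(p2$genotype, p$genotype)
})

test_that("the literal NA sentinel gives a missing BAF while keeping the LRR", {
  man <- tiny_manifest(1)
  sheet <- sample_sheet(data.frame(
    sample_id = "a", phenotype = "case", plate_id = "P1", cohort_id = "c1",
    dna_source = "genomic", sex = "F"))
  f <- tempfile()
  writeLines(c("sample_id\tsnp_id\tlrr\tbaf\tgenotype",
               paste("a", man$snp_id[1], "0.25", "NA", "AB", sep = "\t")), f)
  p <- read_intensity_long(f, man, sheet)
  expect_equal(unname(p$lrr[1, 1]), 0.25)
  expect_true(is.na(p$baf[1, 1]))
})

test_that("unknown identifiers in a long file are hard errors naming the offender", {
  man <- tiny_manifest(2)
  sheet <- sample_sheet(data.frame(
    sample_id = "a", phenotype = "case", plate_id = "P1", cohort_id = "c1",
    dna_source = "genomic", sex = "F"))
  f <- tempfile()
  writeLines(c("sample_id\tsnp_id\tlrr\tbaf\tgenotype",
               "a\tnot_a_snp\t0.1\t0.5\tAB"), f)
  expect_error(read_intensity_long(f, man, sheet), "not_a_snp")
  writeLines(c("sample_id\tsnp_id\tlrr\tbaf\tgenotype",
               paste("ghost", man$snp_id[1], "0.1", "0.5", "AB", sep = "\t")), f)
  expect_error(read_intensity_long(f, man, sheet), "ghost")
})

test_that("BED input converts to 1-based inclusive coordinates and back", {
  f <- tempfile()
  writeLines(c("chr1\t99\t200", "chr2\t0\t1"), f)
  rs <- read_regions_bed(f, "test")
  expect_equal(rs$start_bp, c(100, 1))
  expect_equal(rs$end_bp, c(200, 1))
  f2 <- tempfile()
  write_regions_bed(rs, f2)
  rs2 <- read_regions_bed(f2, "test")
  expect_equal(rs2$start_bp, rs$start_bp)
  expect_equal(rs2$end_bp, rs$end_bp)
  writeLines("chr1\t50\t40", f)
  expect_error(read_regions_bed(f), "end < start")
})

test_that("CNV call text round-trips exactly and malformed input errors with a line number", {
  calls <- make_calls(c(100, 5000), c(500, 9000), cn = c(1, 3),
                      n_snps = c(12, 20), quality = c(0.99, 0.9513),
                      chrom = "chr8")
  f <- tempfile()
  write_cnv_calls(calls, f)
  expect_equal(readLines(f)[1],
               "chr8:100-500 numsnp=12 cn=1 sample=s1 quality=0.990000")
  back <- read_cnv_calls(f)
  expect_equal(back$start_bp, calls$start_bp)
  expect_equal(back$end_bp, calls$end_bp)
  expect_equal(back$copy_number, calls$copy_number)
  expect_equal(back$quality, calls$quality, tolerance = 1e-6)
  writeLines(c("chr8:100-500 numsnp=12 cn=1 sample=s1 quality=0.990000",
               "garbage line"), f)
  expect_error(read_cnv_calls(f), "line 2")
  writeLines("chr8:100-500 numsnp=12 cn=1 sample=s1 quality=1.500000", f)
  expect_error(read_cnv_calls(f), "quality")
})

test_that("BED export of a call uses 0-based half-open coordinates and scaled quality", {
  calls <- make_calls(100, 500, cn = 1, n_snps = 12, quality = 0.99,
                      chrom = "chr8")
  f <- tempfile()
  write_cnv_bed(calls, f)
  expect_equal(readLines(f)[1], "chr8\t99\t500\ts1;cn=1\t990")
})

test_that("random valid call tables survive a write/read cycle unchanged", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:20, 1)
    df <- data.frame(
      sample_id = paste0("s", sample(1:5, n, replace = TRUE)),
      chrom = sample(c("1", "7", "X"), n, replace = TRUE),
      start_bp = st <- sample(1:1e6, n),
      end_bp = st + sample(0:1e5, n),
      copy_number = sample(c(0, 1, 3, 4), n, replace = TRUE),
      n_snps = sample(1:500, n),
      quality = round(runif(n), 6))
    calls <- cnv_calls(df)
    f <- tempfile()
    write_cnv_calls(calls, f)
    back <- read_cnv_calls(f)
    ord <- order(back$sample_id, back$chrom, back$start_bp)
    ord0 <- order(calls$sample_id, calls$chrom, calls$start_bp)
    expect_equal(back[ord, c("sample_id", "chrom", "start_bp", "end_bp",
                             "copy_number", "n_snps", "quality")],
                 as.data.frame(calls)[ord0, c("sample_id", "chrom", "start_bp",
                                              "end_bp", "copy_number",
                                              "n_snps", "quality")],
                 ignore_attr = TRUE)
  }
})

test_that("FAM pedigrees round-trip and reject impossible parent links", {
  ped <- pedigree(data.frame(
    family_id = c("F1", "F1", "F1"), individual_id = c("fa", "mo", "kid"),
    father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
    sex = c("M", "F", "F"),
    affection = c("unaffected", "unaffected", "affected")))
  f <- tempfile()
  write_fam(ped, f)
  ped2 <- read_fam(f)
  expect_equal(ped2$individual_id, ped$individual_id)
  expect_equal(ped2$father_id, ped$father_id)
  expect_equal(ped2$affection, ped$affection)
  expect_error(pedigree(data.frame(
    family_id = "F1", individual_id = "a", father_id = "missing_parent",
    mother_id = NA, sex = "M", affection = "unknown")), "absent")
})

test_that("manifest and sample-sheet validation enforce the documented invariants", {
  df <- data.frame(snp_id = c("a", "b"), chrom = "1", pos_bp = c(200, 100),
                   gc_fraction = 0.5, pfb = 0.5)
  m <- snp_manifest(df)
  expect_equal(m$pos_bp, c(100L, 200L))  # sorted on construction
  df$snp_id <- c("a", "a")
  expect_error(snp_manifest(df), "duplicate")
  df2 <- data.frame(snp_id = "a", chrom = "1", pos_bp = 1, gc_fraction = 1.5,
                    pfb = 0.5)
  expect_error(snp_manifest(df2), "gc_fraction")
  expect_error(sample_sheet(data.frame(
    sample_id = "s", phenotype = "kase", plate_id = "P", cohort_id = "c",
    dna_source = "genomic", sex = "M")), "phenotype")
})

test_that("PFB files expose the standard Name/Chr/Position/PFB columns", {
  man <- tiny_manifest(5, pfb = c(0.1, 0.2, 0.3, 0.4, 0.5))
  f <- tempfile()
  write_pfb(man, f)
  m2 <- read_pfb(f)
  expect_equal(m2$snp_id, man$snp_id)
  expect_equal(m2$pfb, man$pfb)
})
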