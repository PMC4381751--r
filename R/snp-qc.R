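## Marker-level QC: call rates, exact Hardy-Weinberg tests, heterozygosity
## outliers, and exclusion of SNPs with differential intensity between
## nuisance groups (DNA source, phenotype-confounded cohorts).

#' Two-pass call-rate filter
#'
#' Samples with call rate strictly below `sample_threshold` are excluded
#' first; SNP call rates are then recomputed on the surviving samples and
#' SNPs strictly below `snp_threshold` excluded. Rates equal to the
#' threshold are kept.
#'
#' @param genotype character matrix of AA/AB/BB/NC (samples x SNPs).
#' @param snp_threshold,sample_threshold minimum call rates.
#' @return list with `sample_call_rate`, `snp_call_rate`,
#'   `excluded_samples`, `excluded_snps`.
#' @export
call_rate_filter <- function(genotype, snp_threshold = 0.95,
                             sample_threshold = 0.95) {
  if (!is.matrix(genotype) || nrow(genotype) == 0 || ncol(genotype) == 0)
    stop("empty genotype matrix")
  called <- genotype != "NC"
  sample_cr <- rowMeans(called)
  bad_s <- sample_cr < sample_threshold
  if (all(bad_s)) warning("all samples fail the call-rate threshold")
  keep <- !bad_s
  snp_cr <- if (any(keep)) colMeans(called[keep, , drop = FALSE]) else
    rep(0, ncol(genotype))
  names(snp_cr) <- colnames(genotype)
  bad_m <- snp_cr < snp_threshold
  list(sample_call_rate = sample_cr, snp_call_rate = snp_cr,
       excluded_samples = rownames(genotype)[bad_s],
       excluded_snps = colnames(genotype)[bad_m])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the allele
#' counts. The two-sided p-value sums the conditional probabilities of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return p-value.
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("negative genotype counts")
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  ## log P(het = h | nA, nB) up to a shared constant:
  ##   n! / (nAA! nAB! nBB!) * 2^nAB
  aa <- (nA - hets) / 2; bb <- (nB - hets) / 2
  logw <- hets * log(2) - lfactorial(aa) - lfactorial(hets) - lfactorial(bb)
  w <- exp(logw - max(logw))
  p_h <- w / sum(w)
  obs <- p_h[match(n_AB, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p_h[p_h <= obs * (1 + 1e-12)]))
}

#' Per-SNP HWE screen
#'
#' Applies [hwe_exact_test()] to every SNP using the given samples
#' (typically controls only) and reports SNPs below the threshold.
#'
#' @param genotype character matrix (samples x SNPs).
#' @param samples sample ids to count genotypes on (default all rows).
#' @param p_threshold exclusion threshold (default 1e-10).
#' @return list with `hwe_p` (named vector) and `excluded_snps`.
#' @export
hwe_filter <- function(genotype, samples = rownames(genotype),
                       p_threshold = 1e-10) {
  gm <- genotype[samples, , drop = FALSE]
  nAA <- colSums(gm == "AA"); nAB <- colSums(gm == "AB"); nBB <- colSums(gm == "BB")
  p <- vapply(seq_len(ncol(gm)), function(j) {
    if (nAA[j] + nAB[j] + nBB[j] == 0) return(NA_real_)
    hwe_exact_test(nAA[j], nAB[j], nBB[j])
  }, numeric(1))
  names(p) <- colnames(gm)
  list(hwe_p = p, excluded_snps = colnames(gm)[!is.na(p) & p < p_threshold])
}

#' Heterozygosity-outlier sample filter
#'
#' Excludes samples whose heterozygous-call rate lies more than `k` SDs from
#' the mean (two-sided). With zero SD no sample is excluded.
#'
#' @param het_rates named numeric vector of per-sample heterozygosity.
#' @param k SD multiplier (default 3.5).
#' @return character vector of excluded sample ids.
#' @export
het_outlier_filter <- function(het_rates, k = 3.5) {
  if (length(het_rates) < 10) stop("need >= 10 samples for a stable fence")
  if (!is.finite(k)) return(character(0))
  mu <- mean(het_rates); s <- sd(het_rates)
  if (s == 0) return(character(0))
  names(het_rates)[abs(het_rates - mu) > k * s]
}

#' Per-sample heterozygosity rates
#' @param genotype character matrix (samples x SNPs).
#' @return named numeric vector (heterozygous calls / called genotypes).
#' @export
het_rate <- function(genotype) {
  called <- genotype != "NC"
  rowSums(genotype == "AB") / pmax(1, rowSums(called))
}

#' Differential-intensity SNP filter
#'
#' Per-SNP Welch (unequal-variance) t-test of LRR between two nuisance
#' groups; SNPs significant after Bonferroni correction over the tested
#' SNPs are excluded. SNPs with fewer than two observations in a group, or
#' zero variance in both, are skipped and flagged.
#'
#' @param lrr numeric matrix (samples x SNPs).
#' @param group_labels two-level factor/character vector along rows.
#' @param alpha_family family-wise error rate (default 0.05).
#' @return list with `p` (named vector), `excluded_snps`, `skipped_snps`.
#' @export
differential_intensity_filter <- function(lrr, group_labels,
                                          alpha_family = 0.05) {
  gl <- as.character(group_labels)
  lev <- unique(gl[!is.na(gl)])
  if (length(lev) != 2) stop("group_labels must have exactly two levels")
  g1 <- lrr[gl == lev[1], , drop = FALSE]
  g2 <- lrr[gl == lev[2], , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  m1 <- colMeans(g1, na.rm = TRUE); m2 <- colMeans(g2, na.rm = TRUE)
  v1 <- .colVars(g1, m1); v2 <- .colVars(g2, m2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  skipped <- n1 < 2 | n2 < 2 | se2 == 0 | !is.finite(p)
  names(p) <- colnames(lrr)
  m_tested <- sum(!skipped)
  cut <- alpha_family / max(1, m_tested)
  list(p = p, excluded_snps = colnames(lrr)[!skipped & p < cut],
       skipped_snps = colnames(lrr)[skipped])
}

.colVars <- function(x, mu = colMeans(x, na.rm = TRUE)) {
  n <- colSums(!is.na(x))
  sq <- colSums(sweep(x, 2, mu)^2, na.rm = TRUE)
  sq / pmax(1, n - 1)
}

#' Marker-level QC report
#'
#' Runs call-rate, HWE, heterozygosity and (optionally, on corrected data)
#' differential-intensity filters in that order and collects exclusions with
#' reason codes.
#'
#' @param panel `intensity_panel`.
#' @param sheet `sample_sheet`.
#' @param snp_threshold,sample_threshold call-rate thresholds.
#' @param hwe_p HWE exclusion threshold (computed on controls).
#' @param het_k heterozygosity fence multiplier.
#' @return list of class `snp_qc_report`: per-SNP and per-sample tables and
#'   exclusion lists with a single primary reason code each.
#' @export
snp_qc <- function(panel, sheet, snp_threshold = 0.95, sample_threshold = 0.95,
                   hwe_p = 1e-10, het_k = 3.5) {
  cr <- call_rate_filter(panel$genotype, snp_threshold, sample_threshold)
  keep_s <- setdiff(panel$samples, cr$excluded_samples)
  ctrl <- intersect(keep_s, sheet$sample_id[sheet$phenotype == "control"])
  hwe_samples <- if (length(ctrl) >= 10) ctrl else keep_s
  keep_m <- setdiff(panel$manifest$snp_id, cr$excluded_snps)
  hw <- hwe_filter(panel$genotype[hwe_samples, keep_m, drop = FALSE],
                   p_threshold = hwe_p)
  het <- het_rate(panel$genotype[keep_s, keep_m, drop = FALSE])
  het_bad <- if (length(keep_s) >= 10) het_outlier_filter(het, het_k) else character(0)
  excl_s <- data.frame(
    sample_id = c(cr$excluded_samples, het_bad),
    reason = c(rep("call_rate", length(cr$excluded_samples)),
               rep("het_outlier", length(het_bad))), stringsAsFactors = FALSE)
  excl_m <- data.frame(
    snp_id = c(cr$excluded_snps, hw$excluded_snps),
    reason = c(rep("call_rate", length(cr$excluded_snps)),
               rep("hwe", length(hw$excluded_snps))), stringsAsFactors = FALSE)
  structure(list(sample_call_rate = cr$sample_call_rate,
                 snp_call_rate = cr$snp_call_rate,
                 hwe_p = hw$hwe_p, het_rate = het,
                 excluded_samples = excl_s[!duplicated(excl_s$sample_id), ],
                 excluded_snps = excl_m[!duplicated(excl_m$snp_id), ]),
            class = "snp_qc_report")
}
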