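## Principal-component correction of the LRR matrix. Scores are fit on a
## masked, thinned marker subset (so rare CNV signal cannot dominate the
## components) and then regressed out of every manifest SNP, intercept
## included, leaving per-SNP residuals with mean ~0.

#' Select markers for PC fitting
#'
#' Removes markers inside any exclusion region (immunoglobulin, telomeric,
#' centromeric, MHC masks) and thins the remainder to a uniform random
#' subset of `floor(n_eligible * thin_fraction)` markers.
#'
#' @param manifest `snp_manifest`.
#' @param exclusion_regions `region_set` or list of them (optional).
#' @param thin_fraction fraction kept after masking (default 0.15).
#' @param seed integer seed for the thinning draw.
#' @return character vector of selected snp_ids (manifest order).
#' @export
select_correction_markers <- function(manifest, exclusion_regions = NULL,
                                      thin_fraction = 0.15, seed = 1) {
  eligible <- rep(TRUE, nrow(manifest))
  if (!is.null(exclusion_regions)) {
    if (inherits(exclusion_regions, "region_set"))
      exclusion_regions <- list(exclusion_regions)
    snp_gr <- GenomicRanges::GRanges(
      manifest$chrom, IRanges::IRanges(manifest$pos_bp, manifest$pos_bp))
    for (rs in exclusion_regions) {
      hit <- GenomicRanges::countOverlaps(snp_gr, .regions_gr(rs)) > 0
      eligible <- eligible & !hit
    }
  }
  ids <- manifest$snp_id[eligible]
  n_keep <- floor(length(ids) * thin_fraction)
  if (n_keep < 2) stop("marker selection produced fewer than 2 markers")
  set.seed(seed)
  keep <- sort(sample(length(ids), n_keep))
  ids[keep]
}

#' Fit leading principal components and regress them out
#'
#' Sample scores are the leading `k` left singular directions of the
#' column-centred samples x subset LRR matrix (missing values mean-imputed
#' per SNP for the fit). Every manifest SNP is then replaced by the
#' residual of its least-squares regression on the scores plus intercept,
#' so per-SNP means are removed along with the batch components. `k = 0`
#' returns the input unchanged.
#'
#' @param lrr numeric matrix (samples x SNPs), QC-passing samples only.
#' @param subset character vector of snp_ids (columns of `lrr`) to fit on.
#' @param k number of components (default 24).
#' @return list of class `pc_model` with `corrected` (matrix), `scores`,
#'   `subset`, `k`.
#' @export
fit_and_remove_components <- function(lrr, subset, k = 24) {
  if (k == 0) {
    return(structure(list(corrected = lrr, scores = NULL, subset = subset,
                          k = 0L), class = "pc_model"))
  }
  sub <- lrr[, subset, drop = FALSE]
  if (anyNA(sub)) {
    mu <- colMeans(sub, na.rm = TRUE)
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    sub[na_idx] <- mu[na_idx[, 2]]
  }
  sub <- sweep(sub, 2, colMeans(sub))
  r <- min(dim(sub))
  if (k > r) stop("k exceeds the rank bound of the subset matrix")
  sv <- svd(sub, nu = k, nv = 0)
  scores <- sv$u[, seq_len(k), drop = FALSE]
  X <- cbind(1, scores)
  qx <- qr(X)
  if (anyNA(lrr)) {
    ## fit on mean-imputed copy, subtract fitted values, keep NAs missing
    imp <- lrr
    mu <- colMeans(imp, na.rm = TRUE)
    na_idx <- which(is.na(imp), arr.ind = TRUE)
    imp[na_idx] <- mu[na_idx[, 2]]
    beta <- qr.coef(qx, imp)
    corrected <- lrr - X %*% beta
  } else {
    beta <- qr.coef(qx, lrr)
    corrected <- lrr - X %*% beta
  }
  dimnames(corrected) <- dimnames(lrr)
  structure(list(corrected = corrected, scores = scores, subset = subset,
                 k = as.integer(k)), class = "pc_model")
}

#' PC-correct an intensity panel
#'
#' Convenience wrapper: marker selection on the panel's manifest, component
#' fit and removal, returning a panel whose LRR matrix is the corrected
#' residual (BAF and genotypes unchanged).
#'
#' @param panel `intensity_panel` (QC-passing samples only).
#' @param exclusion_regions mask regions for [select_correction_markers()].
#' @param k components to remove (default 24).
#' @param thin_fraction marker thinning fraction (default 0.15).
#' @param seed seed for thinning.
#' @return list with `panel` (corrected) and `model` (`pc_model`).
#' @export
pc_correct_panel <- function(panel, exclusion_regions = NULL, k = 24,
                             thin_fraction = 0.15, seed = 1) {
  subset <- select_correction_markers(panel$manifest, exclusion_regions,
                                      thin_fraction, seed)
  model <- fit_and_remove_components(panel$lrr, subset, k)
  out <- intensity_panel(model$corrected, panel$baf, panel$genotype,
                         panel$manifest)
  list(panel = out, model = model)
}
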