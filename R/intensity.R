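## IntensityPanel: samples x SNPs LRR/BAF/genotype matrices aligned to a
## manifest. Genotypes are stored as a character matrix with values
## AA/AB/BB/NC. Missing LRR/BAF are NA, never 0 (0 is a valid diploid LRR).

#' Construct an intensity panel
#'
#' @param lrr,baf numeric matrices (samples x SNPs), row names = sample ids,
#'   column names = SNP ids in manifest order. `NA` marks missing.
#' @param genotype character matrix of AA/AB/BB/NC, same shape.
#' @param manifest `snp_manifest` defining marker order.
#' @return list of class `intensity_panel`.
#' @export
intensity_panel <- function(lrr, baf, genotype, manifest) {
  stopifnot(is.matrix(lrr), is.matrix(baf), is.matrix(genotype))
  if (!identical(dim(lrr), dim(baf)) || !identical(dim(lrr), dim(genotype)))
    stop("lrr/baf/genotype shapes disagree")
  if (ncol(lrr) != nrow(manifest)) stop("panel width != manifest length")
  if (!identical(colnames(lrr), manifest$snp_id))
    stop("panel columns must follow manifest SNP order")
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) stop("BAF outside [0,1]")
  if (!all(genotype %in% c("AA", "AB", "BB", "NC")))
    stop("genotype values must be AA/AB/BB/NC")
  structure(list(samples = rownames(lrr), manifest = manifest,
                 lrr = lrr, baf = baf, genotype = genotype),
            class = "intensity_panel")
}

## construction without re-validation, for internal code paths that already
## hold a valid panel (subsetting, simulator assembly)
.new_panel <- function(lrr, baf, genotype, manifest) {
  structure(list(samples = rownames(lrr), manifest = manifest,
                 lrr = lrr, baf = baf, genotype = genotype),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat("intensity_panel:", length(x$samples), "samples x",
      nrow(x$manifest), "SNPs on",
      length(unique(x$manifest$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset an intensity panel by samples and/or SNPs
#'
#' @param panel `intensity_panel`.
#' @param samples character vector of sample ids to keep (default all).
#' @param snps character vector of SNP ids to keep (default all).
#' @return `intensity_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(panel$samples) else {
    m <- match(samples, panel$samples)
    if (anyNA(m)) stop("unknown sample id: ", samples[which(is.na(m))[1]])
    m
  }
  mi <- if (is.null(snps)) seq_len(nrow(panel$manifest)) else {
    m <- match(snps, panel$manifest$snp_id)
    if (anyNA(m)) stop("unknown snp id: ", snps[which(is.na(m))[1]])
    sort(m)
  }
  man <- panel$manifest[mi, , drop = FALSE]
  rownames(man) <- NULL
  class(man) <- c("snp_manifest", "data.frame")
  .new_panel(panel$lrr[si, mi, drop = FALSE],
             panel$baf[si, mi, drop = FALSE],
             panel$genotype[si, mi, drop = FALSE], man)
}

#' Read a long-format intensity file into a panel
#'
#' The long format is tab-delimited with a header naming the columns
#' `sample_id`, `snp_id`, `lrr`, `baf`, `genotype` (any column order).
#' Cells absent from the file become missing; the literal "NA" in lrr/baf is
#' a missing-value sentinel. Genotypes default to NC when absent.
#'
#' @param path file path.
#' @param manifest `snp_manifest`; defines column order of the panel.
#' @param sheet `sample_sheet`; defines the sample set and row order.
#' @return `intensity_panel`.
#' @export
read_intensity_long <- function(path, manifest, sheet) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c("sample_id", "snp_id", "genotype"),
                                            character = c()),
                          na.strings = "NA")
  need <- c("sample_id", "snp_id", "lrr", "baf", "genotype")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("long file missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(dt$lrr)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$lrr))) & !is.na(dt$lrr) & dt$lrr != "NA")
    stop("non-numeric lrr at line ", bad[1] + 1L)
  }
  si <- match(dt$sample_id, sheet$sample_id)
  if (anyNA(si)) stop("unknown sample_id in long file: ",
                      paste(unique(dt$sample_id[is.na(si)])[1:min(5, sum(is.na(si)))], collapse = ", "))
  mi <- match(dt$snp_id, manifest$snp_id)
  if (anyNA(mi)) stop("unknown snp_id in long file: ",
                      paste(unique(dt$snp_id[is.na(mi)])[1:min(5, sum(is.na(mi)))], collapse = ", "))
  n_s <- nrow(sheet); n_m <- nrow(manifest)
  lrr <- matrix(NA_real_, n_s, n_m, dimnames = list(sheet$sample_id, manifest$snp_id))
  baf <- lrr
  gt <- matrix("NC", n_s, n_m, dimnames = list(sheet$sample_id, manifest$snp_id))
  idx <- cbind(si, mi)
  lrr[idx] <- as.numeric(dt$lrr)
  baf[idx] <- as.numeric(dt$baf)
  g <- as.character(dt$genotype)
  g[is.na(g) | !(g %in% c("AA", "AB", "BB"))] <- "NC"
  gt[idx] <- g
  intensity_panel(lrr, baf, gt, manifest)
}

#' Write a panel in long format
#'
#' One row per (sample, SNP) cell with a non-missing LRR or BAF or a called
#' genotype; the inverse of [read_intensity_long()].
#'
#' @param panel `intensity_panel`.
#' @param path output path.
#' @export
write_intensity_long <- function(panel, path) {
  n_s <- length(panel$samples); n_m <- nrow(panel$manifest)
  keep <- !(is.na(panel$lrr) & is.na(panel$baf) & panel$genotype == "NC")
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(sample_id = panel$samples[idx[, 1]],
                    snp_id = panel$manifest$snp_id[idx[, 2]],
                    lrr = panel$lrr[keep], baf = panel$baf[keep],
                    genotype = panel$genotype[keep])
  out <- out[order(idx[, 1], idx[, 2]), ]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
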