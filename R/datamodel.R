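## Core domain types: SNP manifest, sample sheet, region sets, pedigrees.
## All internal coordinates are 1-based inclusive; BED I/O converts at the
## boundary.

CHROM_ORDER <- c(as.character(1:22), "X", "Y", "MT")

.chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- match(x, CHROM_ORDER)
  ifelse(is.na(r), length(CHROM_ORDER) + as.integer(factor(x)), r)
}

#' Construct and validate a SNP manifest
#'
#' A manifest holds one row per array marker: identifier, chromosome,
#' 1-based position, GC fraction of the probe's surrounding window, and the
#' population B-allele frequency (PFB) used to weight BAF emission mixtures.
#' Rows are sorted by (chromosome, position).
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `gc_fraction`, `pfb`.
#' @return A validated, sorted data.frame of class `snp_manifest`.
#' @export
snp_manifest <- function(df) {
  need <- c("snp_id", "chrom", "pos_bp", "gc_fraction", "pfb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos_bp <- as.integer(df$pos_bp)
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in manifest")
  if (any(df$pos_bp < 1L)) stop("manifest pos_bp must be >= 1")
  ok_unit <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok_unit(df$gc_fraction)) stop("gc_fraction outside [0,1]")
  if (!ok_unit(df$pfb)) stop("pfb outside [0,1]")
  df <- df[order(.chrom_rank(df$chrom), df$pos_bp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("snp_manifest", "data.frame")
  df
}

#' Read a tab-delimited SNP manifest
#'
#' Expects a header with columns snp_id, chrom, pos_bp, gc_fraction, pfb.
#'
#' @param path file path.
#' @return `snp_manifest`.
#' @export
read_manifest <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  snp_manifest(df)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t")
  invisible(path)
}

#' Read a PFB file (columns: Name, Chr, Position, PFB)
#'
#' The standard caller input giving the population B-allele frequency per
#' marker. GC fractions are not part of this format; `gc_fraction` is set
#' to `NA` unless supplied.
#'
#' @param path file path.
#' @param gc_fraction optional numeric vector aligned to the file rows.
#' @return `snp_manifest`.
#' @export
read_pfb <- function(path, gc_fraction = NA_real_) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  names(df) <- tolower(names(df))
  need <- c("name", "chr", "position", "pfb")
  if (!all(need %in% names(df))) stop("PFB file must have columns Name, Chr, Position, PFB")
  snp_manifest(data.frame(
    snp_id = df$name, chrom = df$chr, pos_bp = df$position,
    gc_fraction = gc_fraction, pfb = df$pfb, stringsAsFactors = FALSE))
}

#' @rdname read_pfb
#' @export
write_pfb <- function(manifest, path) {
  out <- data.frame(Name = manifest$snp_id, Chr = manifest$chrom,
                    Position = manifest$pos_bp, PFB = manifest$pfb)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' One row per sample: phenotype (case/control/unknown), plate, cohort
#' (typing centre or batch), DNA source and sex.
#'
#' @param df data.frame with columns `sample_id`, `phenotype`, `plate_id`,
#'   `cohort_id`, `dna_source`, `sex`.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "phenotype", "plate_id", "cohort_id", "dna_source", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(df$phenotype %in% c("case", "control", "unknown")))
    stop("phenotype must be case/control/unknown")
  if (!all(df$dna_source %in% c("cell_line", "genomic")))
    stop("dna_source must be cell_line/genomic")
  if (!all(df$sex %in% c("M", "F", "unknown"))) stop("sex must be M/F/unknown")
  if (any(!nzchar(df$plate_id)) || any(!nzchar(df$cohort_id)))
    stop("every sample needs plate_id and cohort_id")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read/write a CSV sample sheet
#' @param path file path.
#' @return `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(data.table::fread(path, sep = ",", data.table = FALSE))
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(as.data.frame(sheet), path, sep = ",")
  invisible(path)
}

#' Construct a region set (1-based inclusive intervals)
#'
#' @param chrom,start_bp,end_bp interval coordinates, 1-based inclusive.
#' @param label single string naming the set (e.g. "MHC", "telomeres").
#' @return data.frame of class `region_set` with a `label` attribute.
#' @export
region_set <- function(chrom, start_bp, end_bp, label = "regions") {
  chrom <- as.character(chrom)
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (any(start_bp > end_bp)) stop("region start_bp > end_bp")
  if (any(start_bp < 1)) stop("region start_bp < 1")
  df <- data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                   stringsAsFactors = FALSE)
  attr(df, "label") <- label
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file as a region set
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive, so
#' a BED line `chr1 99 200` becomes the interval (chr1, 100, 200).
#'
#' @param path BED file (first three columns used).
#' @param label name for the set.
#' @return `region_set`.
#' @export
read_regions_bed <- function(path, label = basename(path)) {
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  s0 <- as.numeric(df[[2]]); e0 <- as.numeric(df[[3]])
  if (any(e0 < s0)) stop("BED end < start at line ", which(e0 < s0)[1])
  region_set(df[[1]], s0 + 1, e0, label = label)
}

#' @rdname read_regions_bed
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(regions$chrom, format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                    format(regions$end_bp, scientific = FALSE, trim = TRUE))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start_bp, regions$end_bp))
}

#' Construct and validate a pedigree
#'
#' @param df data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affection`. Missing parents are `NA`
#'   or `"0"`.
#' @return data.frame of class `pedigree`.
#' @export
pedigree <- function(df) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  df$father_id[df$father_id %in% c("0", "")] <- NA
  df$mother_id[df$mother_id %in% c("0", "")] <- NA
  if (!all(df$affection %in% c("affected", "unaffected", "unknown")))
    stop("affection must be affected/unaffected/unknown")
  if (anyDuplicated(df$individual_id)) stop("duplicate individual_id in pedigree")
  known <- df$individual_id
  bad <- stats::na.omit(setdiff(c(df$father_id, df$mother_id), known))
  if (length(bad)) stop("parent ids absent from pedigree: ", paste(bad, collapse = ", "))
  ## cycle check: follow parent links; depth cannot exceed n
  idx <- stats::setNames(seq_len(nrow(df)), df$individual_id)
  for (i in seq_len(nrow(df))) {
    seen <- character(0); j <- i
    repeat {
      p <- df$father_id[j]
      if (is.na(p)) break
      if (p %in% seen || p == df$individual_id[i]) stop("pedigree cycle at ", df$individual_id[i])
      seen <- c(seen, p); j <- idx[[p]]
      if (length(seen) > nrow(df)) stop("pedigree cycle")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a PLINK 6-column FAM file as a pedigree
#'
#' Columns: family, individual, father, mother, sex (1=M, 2=F), phenotype
#' (1=unaffected, 2=affected, 0/-9=unknown).
#'
#' @param path FAM file path.
#' @return `pedigree`.
#' @export
read_fam <- function(path) {
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(df) < 6) stop("FAM file needs 6 columns")
  sex <- c("1" = "M", "2" = "F")[as.character(df[[5]])]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[as.character(df[[6]])]
  aff[is.na(aff)] <- "unknown"
  pedigree(data.frame(
    family_id = df[[1]], individual_id = df[[2]], father_id = df[[3]],
    mother_id = df[[4]], sex = sex, affection = aff, stringsAsFactors = FALSE))
}

#' @rdname read_fam
#' @export
write_fam <- function(ped, path) {
  sex <- c(M = 1L, F = 2L, unknown = 0L)[ped$sex]
  aff <- c(unaffected = 1L, affected = 2L, unknown = 0L)[ped$affection]
  out <- data.frame(ped$family_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sex, aff)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
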