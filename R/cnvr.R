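## CNV-level QC filters, CNVR grouping with segment-group semantics
## (every member shares at least one common nucleotide), two-stage rarity
## filtering and annotation overlap.

#' CNV-level QC filters
#'
#' Applied in a fixed order: (1) drop calls with fewer than `min_snps`
#' SNPs; (2) drop all calls of samples whose total, DEL or DUP call count
#' strictly exceeds the cohort mean + `count_sd` SD (counts computed on the
#' current call set); (3) drop all calls on plates whose mean CNV count per
#' sample strictly exceeds the global mean + `plate_sd` SD; (4) drop calls
#' overlapping any mask region by >= 1 bp; (5) flag (not drop) calls with
#' quality below `quality_min` - quality-based dropping happens at the
#' CNVR stage.
#'
#' @param calls `cnv_calls`.
#' @param sheet `sample_sheet` (plate map; must cover all call samples).
#' @param mask_regions `region_set` or list of them (optional).
#' @param min_snps minimum supporting SNPs (default 6).
#' @param count_sd,plate_sd SD multipliers (default 3).
#' @param quality_min quality flag threshold (default 0.95).
#' @return list with `calls` (kept, with `quality_flag` column) and
#'   `report` (exclusion counts by rule, per-sample and per-plate counts).
#' @export
apply_cnv_level_filters <- function(calls, sheet, mask_regions = NULL,
                                    min_snps = 6, count_sd = 3, plate_sd = 3,
                                    quality_min = 0.95) {
  pm <- match(calls$sample_id, sheet$sample_id)
  if (anyNA(pm)) stop("sample missing from sample sheet: ",
                      calls$sample_id[which(is.na(pm))[1]])
  report <- list()
  drop <- rep(FALSE, nrow(calls))

  small <- calls$n_snps < min_snps
  report$min_snp <- sum(small)
  drop <- drop | small

  cur <- calls[!drop, , drop = FALSE]
  count_of <- function(x) table(factor(x, levels = unique(cur$sample_id)))
  tot <- count_of(cur$sample_id)
  del <- count_of(cur$sample_id[cur$cnv_class == "DEL"])
  dup <- count_of(cur$sample_id[cur$cnv_class == "DUP"])
  over <- function(v) names(v)[v > mean(v) + count_sd * sd(v) & sd(v) > 0]
  bad_samples <- unique(c(over(tot), over(del), over(dup)))
  hit <- !drop & calls$sample_id %in% bad_samples
  report$sample_count <- sum(hit)
  drop <- drop | hit

  cur <- calls[!drop, , drop = FALSE]
  plate_of_sample <- setNames(sheet$plate_id, sheet$sample_id)
  samples_per_plate <- table(sheet$plate_id)
  cnv_per_plate <- table(factor(plate_of_sample[cur$sample_id],
                                levels = names(samples_per_plate)))
  rate <- as.numeric(cnv_per_plate) / as.numeric(samples_per_plate)
  bad_plates <- names(samples_per_plate)[rate > mean(rate) + plate_sd * sd(rate) &
                                           sd(rate) > 0]
  hit <- !drop & plate_of_sample[calls$sample_id] %in% bad_plates
  report$plate_rate <- sum(hit)
  drop <- drop | hit

  if (!is.null(mask_regions)) {
    if (inherits(mask_regions, "region_set")) mask_regions <- list(mask_regions)
    masked <- rep(FALSE, nrow(calls))
    gr <- .calls_gr(calls)
    for (rs in mask_regions)
      masked <- masked | GenomicRanges::countOverlaps(gr, .regions_gr(rs)) > 0
    hit <- !drop & masked
    report$region_mask <- sum(hit)
    drop <- drop | hit
  } else report$region_mask <- 0L

  kept <- calls[!drop, , drop = FALSE]
  kept$quality_flag <- !is.na(kept$quality) & kept$quality < quality_min
  report$quality_flagged <- sum(kept$quality_flag)
  rownames(kept) <- NULL
  class(kept) <- c("cnv_calls", "data.frame")
  list(calls = kept,
       report = list(excluded = report,
                     sample_counts = as.data.frame(tot, stringsAsFactors = FALSE),
                     plate_rates = data.frame(plate_id = names(samples_per_plate),
                                              rate = rate),
                     bad_samples = bad_samples, bad_plates = bad_plates))
}

#' Group CNV calls into CNVRs (segment-group semantics)
#'
#' Sweeps calls of one class sorted by (chrom, start) while maintaining the
#' running common intersection of the open group. A call joins the open
#' group iff it intersects that common interval; otherwise the group closes
#' and a new one opens seeded with the incoming call plus any members of
#' the previous group that still overlap it (so a single call may belong to
#' more than one CNVR). Emitted groups that are strict subsets of another
#' are removed. CNVR bounds are the min start / max end of members.
#'
#' @param calls `cnv_calls`, all of one class (DEL or DUP).
#' @param n_samples total post-QC samples (for the frequency field).
#' @param sheet optional `sample_sheet` for case/control carrier counts.
#' @return data.frame of class `cnvr_table`: one row per CNVR with bounds,
#'   member indices (list column), carrier counts and frequency.
#' @export
group_cnvrs <- function(calls, n_samples = NA_integer_, sheet = NULL) {
  if (length(unique(calls$cnv_class)) > 1)
    stop("group DEL and DUP calls separately")
  if (nrow(calls) == 0)
    return(structure(data.frame(cnvr_id = character(), chrom = character(),
                                start_bp = numeric(), end_bp = numeric()),
                     class = c("cnvr_table", "data.frame")))
  ord <- order(.chrom_rank(calls$chrom), calls$start_bp, calls$end_bp)
  calls <- calls[ord, , drop = FALSE]
  groups <- list()
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    open <- ci[1]; lo <- calls$start_bp[ci[1]]; hi <- calls$end_bp[ci[1]]
    for (i in ci[-1]) {
      s <- calls$start_bp[i]; e <- calls$end_bp[i]
      if (s <= hi && e >= lo) {
        open <- c(open, i); lo <- max(lo, s); hi <- min(hi, e)
      } else {
        groups[[length(groups) + 1]] <- open
        ## seed the next group with previous members still overlapping the
        ## incoming call (shared membership)
        keep <- open[calls$start_bp[open] <= e & calls$end_bp[open] >= s]
        open <- c(keep, i)
        lo <- max(calls$start_bp[open]); hi <- min(calls$end_bp[open])
      }
    }
    groups[[length(groups) + 1]] <- open
  }
  ## drop strict subsets
  keys <- lapply(groups, sort)
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[i] &&
          length(keys[[i]]) < length(keys[[j]]) &&
          all(keys[[i]] %in% keys[[j]])) keep[i] <- FALSE
    }
  }
  groups <- groups[keep]
  rows <- lapply(seq_along(groups), function(g) {
    m <- groups[[g]]
    carriers <- unique(calls$sample_id[m])
    cc <- if (!is.null(sheet)) {
      ph <- sheet$phenotype[match(carriers, sheet$sample_id)]
      c(sum(ph == "case", na.rm = TRUE), sum(ph == "control", na.rm = TRUE))
    } else c(NA_integer_, NA_integer_)
    data.frame(cnvr_id = sprintf("%s_%s_%d", unique(calls$cnv_class),
                                 calls$chrom[m[1]], g),
               chrom = calls$chrom[m[1]],
               start_bp = min(calls$start_bp[m]),
               end_bp = max(calls$end_bp[m]),
               n_members = length(m), n_carriers = length(carriers),
               carriers_case = cc[1], carriers_control = cc[2],
               frequency = length(carriers) / n_samples,
               cnv_class = unique(calls$cnv_class),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- groups
  out$member_samples <- lapply(groups, function(m) unique(calls$sample_id[m]))
  attr(out, "calls") <- calls
  class(out) <- c("cnvr_table", "data.frame")
  out
}

#' Rarity and quality filtering of CNVRs
#'
#' Implements the two-stage rare logic: calls are retained upstream up to
#' `call_stage_max` frequency (avoiding boundary artefacts near common
#' variants), then CNVRs with frequency above `rare_max` are removed here.
#' Member calls with quality below `quality_min` are dropped, and CNVRs
#' where more than `max_fail_frac` of members fail on quality are removed
#' entirely.
#'
#' @param cnvrs `cnvr_table` from [group_cnvrs()].
#' @param n_samples total post-QC samples.
#' @param rare_max maximum CNVR frequency (default 0.01, strict `>`
#'   removal).
#' @param quality_min member quality threshold (default 0.95).
#' @param max_fail_frac maximum tolerated fraction of quality-failing
#'   members (default 0.2, strict `>` removal).
#' @return filtered `cnvr_table` with updated carrier counts/frequency.
#' @export
filter_rare_cnvrs <- function(cnvrs, n_samples, rare_max = 0.01,
                              quality_min = 0.95, max_fail_frac = 0.2) {
  if (is.na(n_samples) || n_samples == 0) stop("n_samples must be positive")
  if (nrow(cnvrs) == 0) return(cnvrs)
  calls <- attr(cnvrs, "calls")
  keep <- rep(TRUE, nrow(cnvrs))
  for (g in seq_len(nrow(cnvrs))) {
    m <- cnvrs$members[[g]]
    q <- calls$quality[m]
    fail <- !is.na(q) & q < quality_min
    if (mean(fail) > max_fail_frac) { keep[g] <- FALSE; next }
    m2 <- m[!fail]
    if (!length(m2)) { keep[g] <- FALSE; next }
    carriers <- unique(calls$sample_id[m2])
    cnvrs$members[[g]] <- m2
    cnvrs$member_samples[[g]] <- carriers
    cnvrs$n_members[g] <- length(m2)
    cnvrs$n_carriers[g] <- length(carriers)
    cnvrs$frequency[g] <- length(carriers) / n_samples
    cnvrs$start_bp[g] <- min(calls$start_bp[m2])
    cnvrs$end_bp[g] <- max(calls$end_bp[m2])
  }
  keep <- keep & cnvrs$frequency <= rare_max
  out <- cnvrs[keep, , drop = FALSE]
  attr(out, "calls") <- calls
  class(out) <- c("cnvr_table", "data.frame")
  out
}

#' Annotate calls with region-set overlaps
#'
#' Adds one logical flag per region set (overlap = shared bp >= 1) and,
#' when the set carries names (4th BED column), a per-call list of
#' overlapped feature names.
#'
#' @param calls `cnv_calls` (or `cnvr_table`).
#' @param region_sets named list of `region_set`s (e.g. genes, exons,
#'   reference CNVs); names become flag columns.
#' @return input with added `overlaps_<name>` logical columns and
#'   `<name>_hits` list columns when feature names are present.
#' @export
annotate_overlaps <- function(calls, region_sets) {
  gr <- .calls_gr(calls)
  for (nm in names(region_sets)) {
    rs <- region_sets[[nm]]
    rgr <- .regions_gr(rs)
    calls[[paste0("overlaps_", nm)]] <- GenomicRanges::countOverlaps(gr, rgr) > 0
    if (!is.null(rs$name)) {
      ov <- GenomicRanges::findOverlaps(gr, rgr)
      hits <- split(rs$name[S4Vectors::subjectHits(ov)],
                    factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(calls))))
      calls[[paste0(nm, "_hits")]] <- lapply(hits, unique)
    }
  }
  calls
}
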