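## End-to-end orchestration: fixed stage order (marker QC -> sample QC ->
## PC correction -> differential-intensity exclusion -> calling -> CNV/CNVR
## QC -> association), with reason-coded exclusion logging, plus the
## QC-sensitivity sweep harness.

.qc_bundles <- list(
  sample = list(low = list(mean_k = 2.0, dlrs_k = 4.0, wave_k = 4.0),
                medium = list(mean_k = 1.5, dlrs_k = 3.5, wave_k = 3.5),
                high = list(mean_k = 1.0, dlrs_k = 3.0, wave_k = 3.0)),
  snp = list(low = list(call_rate = 0.90, hwe_p = 1e-12),
             medium = list(call_rate = 0.95, hwe_p = 1e-10),
             high = list(call_rate = 0.98, hwe_p = 1e-8)))

#' Pipeline configuration
#'
#' Threshold bundles for the QC levels, the number of PC components, the
#' CNV-QC switch, HMM parameters and rarity thresholds. Defaults are the
#' recommended final configuration: medium SNP and sample QC, the largest
#' PC level (24), and all CNV-QC filters on.
#'
#' @param sample_qc,snp_qc QC levels: "low", "medium" or "high".
#' @param pc_components components removed by PC correction (default 24).
#' @param cnv_qc logical: apply CNV-level filters (default TRUE).
#' @param hmm `hmm_params`.
#' @param min_snps minimum SNPs per call when `cnv_qc` is on.
#' @param quality_min CNVR-stage quality threshold.
#' @param call_stage_max,rare_max two-stage rarity thresholds.
#' @param merge_rho fragment-merge threshold.
#' @param thin_fraction PC marker thinning fraction.
#' @param seed integer seed (thinning and any stochastic stage).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_qc = "medium", snp_qc = "medium",
                            pc_components = 24, cnv_qc = TRUE,
                            hmm = hmm_params(), min_snps = 6,
                            quality_min = 0.95, call_stage_max = 0.05,
                            rare_max = 0.01, merge_rho = 0.2,
                            thin_fraction = 0.15, seed = 1) {
  stopifnot(sample_qc %in% names(.qc_bundles$sample),
            snp_qc %in% names(.qc_bundles$snp))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full CNV pipeline
#'
#' Stages execute in a fixed order; every excluded sample, SNP or call is
#' logged with a reason code. Deterministic for a given configuration.
#'
#' @param panel `intensity_panel` (raw).
#' @param sheet `sample_sheet`.
#' @param config `pipeline_config`.
#' @param mask_regions regions excluded from PC fitting and from calls
#'   (`region_set` or list; optional).
#' @param annotation_sets named list of `region_set`s for overlap flags
#'   (optional).
#' @param out_dir when given, results are written there (calls text, QC
#'   metrics, CNVR and burden tables, exclusion log).
#' @return list with `calls`, `cnvrs` (per class), `burden`, `scan` (per
#'   class), `qc` (reports), `panel` (corrected, post-QC), `log`.
#' @export
run_pipeline <- function(panel, sheet, config = pipeline_config(),
                         mask_regions = NULL, annotation_sets = NULL,
                         out_dir = NULL) {
  sb <- .qc_bundles$sample[[config$sample_qc]]
  nb <- .qc_bundles$snp[[config$snp_qc]]
  log <- list()
  note <- function(stage, type, ids, reason) if (length(ids))
    log[[length(log) + 1]] <<- data.frame(stage = stage, type = type,
                                          id = ids, reason = reason,
                                          stringsAsFactors = FALSE)

  ## 1. marker QC
  sqc <- snp_qc(panel, sheet, snp_threshold = nb$call_rate,
                sample_threshold = nb$call_rate, hwe_p = nb$hwe_p)
  note("snp_qc", "sample", sqc$excluded_samples$sample_id,
       sqc$excluded_samples$reason)
  note("snp_qc", "snp", sqc$excluded_snps$snp_id, sqc$excluded_snps$reason)
  keep_s <- setdiff(panel$samples, sqc$excluded_samples$sample_id)
  keep_m <- setdiff(panel$manifest$snp_id, sqc$excluded_snps$snp_id)
  p1 <- subset_panel(panel, keep_s, keep_m)

  ## 2. intensity sample QC
  smq <- sample_qc(p1, sheet, mean_k = sb$mean_k, dlrs_k = sb$dlrs_k,
                   wave_k = sb$wave_k,
                   prior_failures = sqc$excluded_samples$sample_id)
  note("sample_qc", "sample", smq$exclusions$sample_id, smq$exclusions$reason)
  keep_s <- setdiff(p1$samples, smq$exclusions$sample_id)
  p2 <- subset_panel(p1, keep_s)
  rm(p1)

  ## 3. PC correction
  pc <- pc_correct_panel(p2, mask_regions, k = config$pc_components,
                         thin_fraction = config$thin_fraction,
                         seed = config$seed)
  p3 <- pc$panel
  rm(p2)
  pc$model$corrected <- NULL   # the corrected matrix lives in the panel
  gc(FALSE)

  ## 4. differential-intensity SNP exclusion (post-correction)
  sheet_now <- sheet[match(p3$samples, sheet$sample_id), ]
  drop_m <- character(0)
  for (grouping in list(sheet_now$dna_source, sheet_now$phenotype)) {
    lv <- unique(grouping[grouping != "unknown"])
    if (length(lv) != 2 || min(table(grouping[grouping %in% lv])) < 2) next
    di <- differential_intensity_filter(
      p3$lrr[grouping %in% lv, , drop = FALSE], grouping[grouping %in% lv])
    drop_m <- union(drop_m, di$excluded_snps)
  }
  note("differential_intensity", "snp", drop_m, "differential_intensity")
  if (length(drop_m))
    p3 <- subset_panel(p3, snps = setdiff(p3$manifest$snp_id, drop_m))

  ## 5. HMM calling
  calls <- call_cnvs(p3, config$hmm, config$merge_rho)

  ## 6. CNV-level QC
  if (config$cnv_qc && nrow(calls)) {
    fl <- apply_cnv_level_filters(calls, sheet, mask_regions,
                                  min_snps = config$min_snps,
                                  quality_min = config$quality_min)
    kept_keys <- paste(fl$calls$sample_id, fl$calls$chrom, fl$calls$start_bp)
    all_keys <- paste(calls$sample_id, calls$chrom, calls$start_bp)
    note("cnv_qc", "call", setdiff(all_keys, kept_keys), "cnv_filter")
    calls <- fl$calls
    cnv_report <- fl$report
  } else cnv_report <- NULL

  if (!is.null(annotation_sets) && nrow(calls))
    calls <- annotate_overlaps(calls, annotation_sets)

  ## 7. CNVR construction + rarity, per class
  n_total <- length(p3$samples)
  cnvrs <- list(); scans <- list()
  n_case <- sum(sheet_now$phenotype == "case")
  n_control <- sum(sheet_now$phenotype == "control")
  for (cls in c("DEL", "DUP")) {
    sub <- calls[calls$cnv_class == cls, , drop = FALSE]
    if (!nrow(sub)) next
    gr <- group_cnvrs(sub, n_total, sheet_now)
    ## call-stage retention: drop members of clearly common CNVRs
    common <- gr$frequency > config$call_stage_max
    if (any(common)) {
      drop_idx <- unique(unlist(gr$members[common]))
      sub2 <- attr(gr, "calls")[-drop_idx, , drop = FALSE]
      gr <- if (nrow(sub2)) group_cnvrs(cnv_calls(
        sub2[, c("sample_id", "chrom", "start_bp", "end_bp", "copy_number",
                 "n_snps", "quality")]), n_total, sheet_now) else gr[0, ]
    }
    rare <- if (nrow(gr)) {
      if (config$cnv_qc)
        filter_rare_cnvrs(gr, n_total, rare_max = config$rare_max,
                          quality_min = config$quality_min)
      else filter_rare_cnvrs(gr, n_total, rare_max = config$rare_max,
                             quality_min = 0, max_fail_frac = 1)
    } else gr
    cnvrs[[cls]] <- rare
    if (nrow(rare) && n_case > 0 && n_control > 0)
      scans[[cls]] <- cnvr_scan(rare, n_case, n_control)
  }

  ## 8. burden
  burden <- if (nrow(calls) && n_case > 0 && n_control > 0) {
    rare_calls <- calls
    if (length(cnvrs)) {
      keep_idx <- unlist(lapply(cnvrs, function(g) {
        cc <- attr(g, "calls")
        if (!nrow(g)) return(character(0))
        idx <- unique(unlist(g$members))
        paste(cc$sample_id[idx], cc$chrom[idx], cc$start_bp[idx], cc$end_bp[idx])
      }))
      rc_keys <- paste(calls$sample_id, calls$chrom, calls$start_bp, calls$end_bp)
      rare_calls <- calls[rc_keys %in% keep_idx, , drop = FALSE]
    }
    burden_strata(rare_calls, sheet_now)
  } else NULL

  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(stage = character(), type = character(), id = character(),
               reason = character())
  res <- list(calls = calls, cnvrs = cnvrs, scans = scans, burden = burden,
              qc = list(snp = sqc, sample = smq, cnv = cnv_report,
                        pc_model = pc$model),
              panel = p3, log = log_df, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(calls)) write_cnv_calls(calls, file.path(out_dir, "calls.txt"))
    write.table(smq$metrics, file.path(out_dir, "sample_metrics.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(burden))
      write.table(burden, file.path(out_dir, "burden.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    write.table(log_df, file.path(out_dir, "exclusions.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  res
}

#' The default QC sweep grid
#'
#' Cross product of three sample-QC levels, three SNP-QC levels, three PC
#' levels (0, half, full) and the CNV-QC switch: 54 configurations.
#'
#' @param pc_levels PC component levels (default c(0, 12, 24)).
#' @return data.frame with one row per configuration.
#' @export
sweep_grid <- function(pc_levels = c(0, 12, 24)) {
  expand.grid(sample_qc = c("low", "medium", "high"),
              snp_qc = c("low", "medium", "high"),
              pc_components = pc_levels,
              cnv_qc = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}

#' QC-sensitivity sweep
#'
#' Runs the pipeline once per grid row on shared inputs and collects, per
#' run, the mean call quality score, the all-CNV burden odds ratios and -
#' when simulator truth is supplied - sensitivity and precision against
#' the true spiked events.
#'
#' @param panel,sheet shared inputs.
#' @param grid data.frame from [sweep_grid()] (or a subset).
#' @param truth_cnv optional truth table (`truth$cnv` from
#'   [simulate_cohort()]).
#' @param base_config `pipeline_config` supplying the non-swept settings.
#' @param ... passed to [run_pipeline()].
#' @return data.frame: the grid plus `mean_quality`, `burden_or_del`,
#'   `burden_or_dup`, `sensitivity`, `precision`, `failed`.
#' @export
qc_sweep <- function(panel, sheet, grid = sweep_grid(), truth_cnv = NULL,
                     base_config = pipeline_config(), ...) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$sample_qc <- grid$sample_qc[i]; cfg$snp_qc <- grid$snp_qc[i]
    cfg$pc_components <- grid$pc_components[i]; cfg$cnv_qc <- grid$cnv_qc[i]
    res <- tryCatch(run_pipeline(panel, sheet, cfg, ...),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(cbind(grid[i, ], mean_quality = NA, burden_or_del = NA,
                   burden_or_dup = NA, sensitivity = NA, precision = NA,
                   failed = TRUE))
    or_of <- function(cls) {
      b <- res$burden
      if (is.null(b)) return(NA_real_)
      v <- b$or_cmle[b$class == cls & b$stratum == "all"]
      if (length(v)) v else NA_real_
    }
    perf <- if (!is.null(truth_cnv))
      call_performance(res$calls, truth_cnv, samples = res$panel$samples)
    else list(sensitivity = NA_real_, precision = NA_real_)
    cbind(grid[i, ],
          mean_quality = mean(res$calls$quality, na.rm = TRUE),
          burden_or_del = or_of("DEL"), burden_or_dup = or_of("DUP"),
          sensitivity = perf$sensitivity, precision = perf$precision,
          failed = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity and precision of calls against truth intervals
#'
#' A truth event is recovered when a call of the same sample and class
#' overlaps it by >= 1 bp; a call is a true positive when it overlaps any
#' truth event of its sample and class. Truth events below `min_snps` are
#' ignored on the sensitivity side.
#'
#' @param calls `cnv_calls`.
#' @param truth_cnv truth table with sample_id, chrom, start_bp, end_bp,
#'   copy_number, n_snps.
#' @param min_snps minimum truth-event size counted (default 6).
#' @param samples when given, truth events are restricted to these samples
#'   (use the QC-surviving set: excluded samples cannot carry calls).
#' @return list with `sensitivity`, `precision`, `n_truth`, `n_calls`.
#' @export
call_performance <- function(calls, truth_cnv, min_snps = 6, samples = NULL) {
  truth_cnv$cnv_class <- ifelse(truth_cnv$copy_number < 2, "DEL", "DUP")
  tr <- truth_cnv[truth_cnv$n_snps >= min_snps, , drop = FALSE]
  if (!is.null(samples)) tr <- tr[tr$sample_id %in% samples, , drop = FALSE]
  hit_truth <- vapply(seq_len(nrow(tr)), function(i) {
    cc <- calls[calls$sample_id == tr$sample_id[i] &
                  calls$cnv_class == tr$cnv_class[i] &
                  calls$chrom == tr$chrom[i], , drop = FALSE]
    nrow(cc) > 0 && any(cc$start_bp <= tr$end_bp[i] & cc$end_bp >= tr$start_bp[i])
  }, logical(1))
  hit_call <- vapply(seq_len(nrow(calls)), function(i) {
    tt <- truth_cnv[truth_cnv$sample_id == calls$sample_id[i] &
                      truth_cnv$cnv_class == calls$cnv_class[i] &
                      truth_cnv$chrom == calls$chrom[i], , drop = FALSE]
    nrow(tt) > 0 && any(tt$start_bp <= calls$end_bp[i] & tt$end_bp >= calls$start_bp[i])
  }, logical(1))
  list(sensitivity = if (nrow(tr)) mean(hit_truth) else NA_real_,
       precision = if (nrow(calls)) mean(hit_call) else NA_real_,
       n_truth = nrow(tr), n_calls = nrow(calls))
}
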