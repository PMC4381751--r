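## Intensity-level sample QC: LRR mean fences, derivative log-ratio spread
## (DLRS), signed GC wave factor, whole-chromosome aberration screen, and
## plate-level exclusion. The exclusion order is fixed: call-rate (marker
## module) -> mean fence -> DLRS -> wave -> aberration -> plate.

#' Tukey-fence exclusion on per-sample LRR means
#'
#' Samples outside \[Q1 - k IQR, Q3 + k IQR\] are excluded; quantiles use
#' R's default linear interpolation (type 7). Values exactly on a fence are
#' retained.
#'
#' @param means named numeric vector of per-sample LRR means.
#' @param k fence multiplier (default 1.5).
#' @param min_n minimum cohort size for a stable fence (default 10).
#' @return character vector of excluded sample ids.
#' @export
lrr_mean_fence <- function(means, k = 1.5, min_n = 10) {
  if (length(means) < min_n) stop("need >= ", min_n, " samples for a stable fence")
  q <- quantile(means, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
  names(means)[!is.na(means) & (means < lo | means > hi)]
}

#' Derivative log-ratio spread of one sample
#'
#' Sample SD (n-1 denominator) of LRR differences between successive
#' markers, divided by sqrt(2). Differences are taken within chromosomes
#' only and pooled; missing values are skipped so a difference spans the
#' gap.
#'
#' @param lrr numeric vector in manifest order.
#' @param chrom chromosome per marker (same length); a single chromosome is
#'   assumed when omitted.
#' @return non-negative scalar.
#' @export
dlrs <- function(lrr, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("1", length(lrr))
  d <- unlist(lapply(split(lrr, factor(chrom, levels = unique(chrom))),
                     function(x) diff(x[!is.na(x)])), use.names = FALSE)
  if (sum(!is.na(lrr)) < 3 || length(d) < 2) stop("need >= 3 usable values")
  sd(d) / sqrt(2)
}

## vectorised DLRS across a samples x SNPs matrix
.dlrs_matrix <- function(lrr, chrom) {
  chroms <- unique(chrom)
  ss <- 0; n <- 0; s1 <- 0
  out_ss <- rep(0, nrow(lrr)); out_s <- rep(0, nrow(lrr)); out_n <- rep(0, nrow(lrr))
  for (ch in chroms) {
    idx <- which(chrom == ch)
    x <- lrr[, idx, drop = FALSE]
    ## per-row diffs skipping NA: fall back to apply when missing present
    if (anyNA(x)) {
      d <- apply(x, 1, function(r) { r <- r[!is.na(r)]; diff(r) })
      if (is.matrix(d)) {
        out_n <- out_n + nrow(d); out_s <- out_s + colSums(d)
        out_ss <- out_ss + colSums(d^2)
      } else {
        out_n <- out_n + vapply(d, length, 0L)
        out_s <- out_s + vapply(d, sum, 0)
        out_ss <- out_ss + vapply(d, function(v) sum(v^2), 0)
      }
    } else {
      d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
      out_n <- out_n + ncol(d); out_s <- out_s + rowSums(d)
      out_ss <- out_ss + rowSums(d^2)
    }
  }
  v <- (out_ss - out_s^2 / out_n) / (out_n - 1)
  sqrt(pmax(0, v) / 2)
}

#' Signed GC wave factor of one sample
#'
#' Magnitude is the unscaled median absolute deviation of per-window median
#' LRR (non-overlapping windows, default 1 Mb) around the overall median of
#' window medians; the sign is that of the Pearson correlation between
#' window medians and window mean GC fraction.
#'
#' @param lrr numeric vector in manifest order.
#' @param manifest `snp_manifest` (chrom, pos_bp, gc_fraction used).
#' @param window_bp window width (default 1e6).
#' @param min_snps_per_window windows with fewer markers are dropped.
#' @param min_windows required usable windows (default 10).
#' @return signed scalar.
#' @export
wave_factor <- function(lrr, manifest, window_bp = 1e6,
                        min_snps_per_window = 10, min_windows = 10) {
  w <- .window_stats(lrr, manifest, window_bp, min_snps_per_window)
  if (nrow(w) < min_windows) stop("insufficient windows for wave factor")
  .swf_from_windows(w$med, w$gc)
}

.swf_from_windows <- function(med, gc) {
  mag <- median(abs(med - median(med)))
  if (mag == 0) return(0)
  r <- suppressWarnings(cor(med, gc))
  if (is.na(r) || r == 0) return(mag)
  sign(r) * mag
}

.window_index <- function(manifest, window_bp) {
  paste0(manifest$chrom, ":", (manifest$pos_bp - 1) %/% window_bp)
}

## wave factors for all rows of an LRR matrix, with the window layout
## computed once
.swf_matrix <- function(lrr, manifest, window_bp = 1e6,
                        min_snps_per_window = 10, min_windows = 10) {
  win <- .window_index(manifest, window_bp)
  idx_by_win <- split(seq_len(nrow(manifest)), win)
  idx_by_win <- idx_by_win[vapply(idx_by_win, length, 0L) >= min_snps_per_window]
  gc <- vapply(idx_by_win, function(ii) mean(manifest$gc_fraction[ii]), 0)
  vapply(seq_len(nrow(lrr)), function(s) {
    med <- vapply(idx_by_win, function(ii) median(lrr[s, ii], na.rm = TRUE), 0)
    ok <- !is.na(med)
    if (sum(ok) < min_windows) return(NA_real_)
    .swf_from_windows(med[ok], gc[ok])
  }, numeric(1))
}

.window_stats <- function(lrr, manifest, window_bp, min_snps_per_window) {
  win <- .window_index(manifest, window_bp)
  ok <- !is.na(lrr)
  med <- tapply(lrr[ok], win[ok], median)
  gc <- tapply(manifest$gc_fraction[ok], win[ok], mean)
  n <- tapply(lrr[ok], win[ok], length)
  keep <- n >= min_snps_per_window
  data.frame(window = names(med)[keep], med = as.numeric(med[keep]),
             gc = as.numeric(gc[keep]), n = as.integer(n[keep]),
             stringsAsFactors = FALSE)
}

#' Whole-chromosome aberration screen
#'
#' Flags (sample, chromosome) pairs where the chromosome's mean LRR deviates
#' from the sample's autosomal mean by more than `z_threshold` cohort SDs of
#' that chromosome's deviation, and the deviation persists (same sign,
#' magnitude above half the chromosomal deviation) over at least
#' `min_fraction` of the chromosome's windows.
#'
#' @param panel `intensity_panel`.
#' @param z_threshold cohort-SD multiplier (default 5).
#' @param min_fraction fraction of windows that must carry the deviation.
#' @param window_bp window width for the persistence check.
#' @param chrom_sd named per-chromosome deviation SDs from a previous run
#'   (the `chrom_sd` attribute of its result); reused instead of recomputed.
#' @return data.frame with `sample_id`, `chrom`, `z`, `window_fraction`,
#'   carrying the per-chromosome SDs as attribute `chrom_sd`.
#' @export
detect_aberrant_chromosomes <- function(panel, z_threshold = 5,
                                        min_fraction = 0.5, window_bp = 1e6,
                                        chrom_sd = NULL) {
  man <- panel$manifest
  chroms <- unique(man$chrom)
  auto_mean <- rowMeans(panel$lrr, na.rm = TRUE)
  flags <- list()
  sd_out <- setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    idx <- which(man$chrom == ch)
    dev <- rowMeans(panel$lrr[, idx, drop = FALSE], na.rm = TRUE) - auto_mean
    s <- if (!is.null(chrom_sd)) chrom_sd[[ch]] else sd(dev, na.rm = TRUE)
    sd_out[ch] <- s
    if (is.na(s) || s == 0) next
    z <- dev / s
    hits <- which(abs(z) > z_threshold)
    for (i in hits) {
      win <- .window_index(man[idx, ], window_bp)
      wmed <- tapply(panel$lrr[i, idx], win, mean, na.rm = TRUE)
      frac <- mean(sign(wmed - auto_mean[i]) == sign(dev[i]) &
                     abs(wmed - auto_mean[i]) > abs(dev[i]) / 2, na.rm = TRUE)
      if (!is.na(frac) && frac >= min_fraction)
        flags[[length(flags) + 1]] <- data.frame(
          sample_id = panel$samples[i], chrom = ch, z = z[i],
          window_fraction = frac, stringsAsFactors = FALSE)
    }
  }
  out <- if (!length(flags)) data.frame(sample_id = character(),
                                        chrom = character(), z = numeric(),
                                        window_fraction = numeric())
         else do.call(rbind, flags)
  attr(out, "chrom_sd") <- sd_out
  out
}

#' Plate-level exclusion by sample failure rate
#'
#' All samples on a plate are excluded when the fraction of its samples
#' failing QC strictly exceeds `failure_threshold`.
#'
#' @param failed_samples character vector of failing sample ids.
#' @param plate_map named character vector: plate id per sample id (must
#'   cover all samples).
#' @param failure_threshold default 0.40.
#' @return list with `excluded_plates` and a per-plate summary table.
#' @export
exclude_failing_plates <- function(failed_samples, plate_map,
                                   failure_threshold = 0.40) {
  if (is.null(names(plate_map)) || any(!nzchar(plate_map)))
    stop("plate_map must be a named, complete sample -> plate vector")
  tab <- table(plate_map)
  if (any(tab == 0)) stop("plate with zero samples")
  failed <- names(plate_map) %in% failed_samples
  frac <- tapply(failed, plate_map, mean)
  bad <- names(frac)[frac > failure_threshold]
  list(excluded_plates = bad,
       plate_summary = data.frame(plate_id = names(frac),
                                  n = as.integer(tab[names(frac)]),
                                  failure_fraction = as.numeric(frac),
                                  excluded = names(frac) %in% bad,
                                  stringsAsFactors = FALSE))
}

#' Intensity-based sample QC
#'
#' Computes per-sample LRR mean, DLRS and signed wave factor, applies the
#' fixed exclusion sequence (mean fence, per-cohort DLRS fence at
#' `dlrs_k` SD above the cohort mean, global |wave| fence at `wave_k` SD
#' above the mean, aberrant-chromosome screen, plate exclusion), and
#' returns metrics plus reason-coded exclusions.
#'
#' @param panel `intensity_panel`.
#' @param sheet `sample_sheet`.
#' @param mean_k LRR-mean IQR fence multiplier.
#' @param dlrs_k,wave_k SD fence multipliers.
#' @param plate_failure_threshold plate exclusion threshold.
#' @param aberration_z,aberration_fraction aberration screen parameters.
#' @param prior_failures sample ids already failed upstream (counted for the
#'   plate rule).
#' @param fences a `fences` element from a previous report; when supplied,
#'   exclusion thresholds are reused instead of recomputed, making a re-run
#'   on the surviving set a no-op.
#' @return list of class `sample_qc_report` with `metrics`, `exclusions`,
#'   `aberrations`, `plate_summary`, `excluded_plates`, `fences`.
#' @export
sample_qc <- function(panel, sheet, mean_k = 1.5, dlrs_k = 3.5, wave_k = 3.5,
                      plate_failure_threshold = 0.40, aberration_z = 5,
                      aberration_fraction = 0.5,
                      prior_failures = character(0), fences = NULL) {
  man <- panel$manifest
  lrr_mean <- rowMeans(panel$lrr, na.rm = TRUE)
  dl <- .dlrs_matrix(panel$lrr, man$chrom)
  swf <- .swf_matrix(panel$lrr, man)
  names(lrr_mean) <- names(dl) <- names(swf) <- panel$samples
  cohort <- sheet$cohort_id[match(panel$samples, sheet$sample_id)]

  if (is.null(fences)) {
    q <- quantile(lrr_mean, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    ## location/scale for the k-SD fences come from median and scaled MAD:
    ## plate-level contamination (10% of a cohort at twice the noise)
    ## inflates mean and SD enough to mask its own outliers entirely,
    ## while the robust fence is unaffected and agrees with mean + k*SD on
    ## clean cohorts
    robust_fence <- function(x, k) {
      x <- x[!is.na(x)]
      median(x) + k * mad(x)
    }
    dlrs_fence <- vapply(unique(cohort), function(co)
      robust_fence(dl[cohort == co], dlrs_k), numeric(1))
    fences <- list(mean_lo = q[1] - mean_k * iqr, mean_hi = q[2] + mean_k * iqr,
                   dlrs = dlrs_fence,
                   wave = robust_fence(abs(swf), wave_k))
  }

  excl <- list()
  add <- function(ids, reason) if (length(ids))
    excl[[length(excl) + 1]] <<- data.frame(sample_id = ids, reason = reason,
                                            stringsAsFactors = FALSE)
  add(panel$samples[!is.na(lrr_mean) &
                      (lrr_mean < fences$mean_lo | lrr_mean > fences$mean_hi)],
      "lrr_mean")
  for (co in unique(cohort)) {
    ii <- which(cohort == co)
    fence <- fences$dlrs[[co]]
    if (is.null(fence) || is.na(fence)) next
    add(panel$samples[ii][!is.na(dl[ii]) & dl[ii] > fence], "dlrs")
  }
  aw <- abs(swf)
  add(panel$samples[!is.na(aw) & aw > fences$wave], "wave")

  ab <- detect_aberrant_chromosomes(panel, aberration_z, aberration_fraction,
                                    chrom_sd = fences$aberration_sd)
  fences$aberration_sd <- attr(ab, "chrom_sd")
  add(unique(ab$sample_id), "chrom_aberration")

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(), reason = character())
  exclusions <- exclusions[!duplicated(exclusions$sample_id), , drop = FALSE]

  plate_map <- setNames(sheet$plate_id[match(panel$samples, sheet$sample_id)],
                        panel$samples)
  failed <- union(exclusions$sample_id, prior_failures)
  pl <- exclude_failing_plates(failed, plate_map, plate_failure_threshold)
  on_bad <- panel$samples[plate_map %in% pl$excluded_plates &
                            !(panel$samples %in% exclusions$sample_id)]
  if (length(on_bad))
    exclusions <- rbind(exclusions,
                        data.frame(sample_id = on_bad, reason = "plate",
                                   stringsAsFactors = FALSE))
  structure(list(
    metrics = data.frame(sample_id = panel$samples, lrr_mean = lrr_mean,
                         dlrs = dl, swf = swf, row.names = NULL,
                         stringsAsFactors = FALSE),
    exclusions = exclusions, aberrations = ab,
    plate_summary = pl$plate_summary, excluded_plates = pl$excluded_plates,
    fences = fences),
    class = "sample_qc_report")
}
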