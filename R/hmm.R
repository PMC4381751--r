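## Hidden-Markov-model CNV caller: five states ordered by copy number
## (CN0, CN1, CN2, CN3, CN4), Gaussian LRR emissions, PFB-weighted BAF band
## mixtures with clipped tails, and distance-dependent transitions.

#' HMM parameters for the copy-number caller
#'
#' @param lrr_mean,lrr_sd per-state LRR emission mean/SD for copy numbers
#'   0,1,2,3,4. Defaults: means (-3.5, -0.67, 0, 0.40, 0.68), SDs
#'   (1.3, 0.28, 0.16, 0.21, 0.24).
#' @param baf_sd BAF band SD (default 0.03).
#' @param eps_out uniform BAF outlier weight (default 0.01).
#' @param pi stationary state prior, diploid-dominant.
#' @param D transition distance scale in bp (default 1e5): the probability
#'   of leaving state i over distance d is (1 - exp(-d/D)) * (1 - pi_i).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(lrr_mean = c(-3.5, -0.67, 0, 0.40, 0.68),
                       lrr_sd = c(1.3, 0.28, 0.16, 0.21, 0.24),
                       baf_sd = 0.03, eps_out = 0.01,
                       pi = c(5e-4, 4.5e-3, 0.99, 4.5e-3, 5e-4),
                       D = 1e5) {
  stopifnot(length(lrr_mean) == 5, length(lrr_sd) == 5, length(pi) == 5)
  if (any(lrr_sd <= 0)) stop("lrr_sd must be positive")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (eps_out < 0 || eps_out >= 1) stop("eps_out must lie in [0,1)")
  structure(list(lrr_mean = lrr_mean, lrr_sd = lrr_sd, baf_sd = baf_sd,
                 eps_out = eps_out, pi = pi, D = D,
                 copy_numbers = c(0L, 1L, 2L, 3L, 4L)), class = "hmm_params")
}

.check_manifest_order <- function(manifest) {
  for (ch in unique(manifest$chrom)) {
    p <- manifest$pos_bp[manifest$chrom == ch]
    if (is.unsorted(p, strictly = FALSE)) stop("manifest not ordered by position")
  }
}

.emissions <- function(lrr, baf, pfb, params) {
  cpp_emission_loglik(as.numeric(lrr), as.numeric(baf), as.numeric(pfb),
                      params$lrr_mean, params$lrr_sd, params$baf_sd,
                      params$eps_out)
}

#' Viterbi segmentation of one sample into CNV calls
#'
#' Decodes the most probable state path per chromosome and returns maximal
#' runs of non-diploid states as calls, with boundaries at the first and
#' last SNP of each run. Path-score ties prefer the lower copy number.
#' Missing LRR or BAF at a SNP contributes only the non-missing term.
#'
#' @param lrr,baf numeric vectors in manifest order.
#' @param manifest `snp_manifest` (pfb column used).
#' @param params `hmm_params`.
#' @param sample_id id recorded in the calls.
#' @return `cnv_calls` (quality `NA`, to be filled by [score_quality()]).
#' @export
viterbi_segments <- function(lrr, baf, manifest, params = hmm_params(),
                             sample_id = "sample") {
  .check_manifest_order(manifest)
  out <- list()
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    logem <- .emissions(lrr[idx], baf[idx], manifest$pfb[idx], params)
    path <- cpp_viterbi(logem, as.numeric(manifest$pos_bp[idx]), params$pi,
                        params$D)
    cn <- params$copy_numbers[path + 1L]
    r <- rle(cn)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values != 2L)) {
      i0 <- idx[starts[j]]; i1 <- idx[ends[j]]
      out[[length(out) + 1]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start_bp = manifest$pos_bp[i0], end_bp = manifest$pos_bp[i1],
        copy_number = r$values[j], n_snps = ends[j] - starts[j] + 1L,
        quality = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(cnv_calls(data.frame()))
  cnv_calls(do.call(rbind, out))
}

#' Forward-backward state posteriors for one sample
#'
#' @inheritParams viterbi_segments
#' @return numeric matrix (SNPs x 5) of state posteriors, columns named
#'   CN0..CN4; each row sums to 1.
#' @export
state_posteriors <- function(lrr, baf, manifest, params = hmm_params()) {
  .check_manifest_order(manifest)
  post <- matrix(NA_real_, nrow(manifest), 5,
                 dimnames = list(manifest$snp_id, paste0("CN", 0:4)))
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    logem <- .emissions(lrr[idx], baf[idx], manifest$pfb[idx], params)
    post[idx, ] <- cpp_forward_backward(logem, as.numeric(manifest$pos_bp[idx]),
                                        params$pi, params$D)
  }
  post
}

#' Merge adjacent same-state call fragments
#'
#' Consecutive calls of equal copy number on one chromosome are merged when
#' gap / (left + gap + right) < `rho`, where the gap is the base pairs
#' strictly between the bounding SNP positions. Applied left-to-right and
#' iterated to a fixed point. With a manifest, `n_snps` is recomputed as
#' the number of manifest SNPs inside the merged interval.
#'
#' @param calls `cnv_calls` for one sample (any mix of chromosomes).
#' @param rho merge threshold (default 0.2, strict `<`).
#' @param manifest optional `snp_manifest` for recomputing `n_snps`.
#' @return merged `cnv_calls`.
#' @export
merge_fragments <- function(calls, rho = 0.2, manifest = NULL) {
  if (nrow(calls) < 2) return(calls)
  pieces <- list()
  for (key in unique(paste(calls$sample_id, calls$chrom))) {
    cc <- calls[paste(calls$sample_id, calls$chrom) == key, , drop = FALSE]
    cc <- cc[order(cc$start_bp), , drop = FALSE]
    if (any(cc$start_bp[-1] <= cc$end_bp[-nrow(cc)]))
      stop("overlapping input calls")
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < nrow(cc)) {
        same <- cc$copy_number[i] == cc$copy_number[i + 1]
        gap <- cc$start_bp[i + 1] - cc$end_bp[i] - 1
        len_l <- cc$end_bp[i] - cc$start_bp[i] + 1
        len_r <- cc$end_bp[i + 1] - cc$start_bp[i + 1] + 1
        if (same && gap / (len_l + gap + len_r) < rho) {
          cc$end_bp[i] <- cc$end_bp[i + 1]
          cc$n_snps[i] <- cc$n_snps[i] + cc$n_snps[i + 1]
          cc$quality[i] <- NA_real_
          cc <- cc[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else i <- i + 1
      }
      if (!merged_any) break
    }
    pieces[[length(pieces) + 1]] <- cc
  }
  out <- do.call(rbind, pieces)
  if (!is.null(manifest)) {
    out$n_snps <- vapply(seq_len(nrow(out)), function(r)
      sum(manifest$chrom == out$chrom[r] & manifest$pos_bp >= out$start_bp[r] &
            manifest$pos_bp <= out$end_bp[r]), 0L)
  }
  cnv_calls(out[, setdiff(names(out), c("cnv_class", "length_bp"))])
}

#' Posterior quality score of a call
#'
#' The mean forward-backward posterior probability of the called state over
#' the call's supporting SNPs; lies in \[0,1\] and is thresholded at 0.95
#' downstream.
#'
#' @param call one-row `cnv_calls` slice (or list with chrom, start_bp,
#'   end_bp, copy_number).
#' @param posteriors matrix from [state_posteriors()] for the same sample.
#' @param manifest `snp_manifest` aligned to `posteriors` rows.
#' @return scalar quality in \[0,1\].
#' @export
score_quality <- function(call, posteriors, manifest) {
  idx <- which(manifest$chrom == call$chrom &
                 manifest$pos_bp >= call$start_bp &
                 manifest$pos_bp <= call$end_bp)
  if (!length(idx)) stop("call has no supporting SNPs in the manifest")
  col <- paste0("CN", call$copy_number)
  mean(posteriors[idx, col], na.rm = TRUE)
}

#' Call CNVs for one sample: segment, merge, score
#'
#' @inheritParams viterbi_segments
#' @param merge_rho fragment-merge threshold (default 0.2).
#' @return `cnv_calls` with quality filled.
#' @export
call_sample <- function(lrr, baf, manifest, params = hmm_params(),
                        sample_id = "sample", merge_rho = 0.2) {
  .check_manifest_order(manifest)
  out <- vector("list", 8); k <- 0
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    pos <- as.numeric(manifest$pos_bp[idx])
    logem <- .emissions(lrr[idx], baf[idx], manifest$pfb[idx], params)
    path <- cpp_viterbi(logem, pos, params$pi, params$D)
    cn <- params$copy_numbers[path + 1L]
    r <- rle(cn)
    runs <- which(r$values != 2L)
    if (!length(runs)) next
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seg <- data.frame(i0 = starts[runs], i1 = ends[runs],
                      cn = r$values[runs])
    ## merge same-state fragments to a fixed point (local indices)
    repeat {
      merged <- FALSE; i <- 1
      while (i < nrow(seg)) {
        gap <- pos[seg$i0[i + 1]] - pos[seg$i1[i]] - 1
        tot <- pos[seg$i1[i + 1]] - pos[seg$i0[i]] + 1
        if (seg$cn[i] == seg$cn[i + 1] && gap / tot < merge_rho) {
          seg$i1[i] <- seg$i1[i + 1]
          seg <- seg[-(i + 1), , drop = FALSE]
          merged <- TRUE
        } else i <- i + 1
      }
      if (!merged) break
    }
    post <- cpp_forward_backward(logem, pos, params$pi, params$D)
    state_of <- match(seg$cn, params$copy_numbers)
    q <- vapply(seq_len(nrow(seg)), function(s)
      mean(post[seg$i0[s]:seg$i1[s], state_of[s]]), numeric(1))
    k <- k + 1
    out[[k]] <- data.frame(
      sample_id = sample_id, chrom = ch,
      start_bp = manifest$pos_bp[idx[seg$i0]],
      end_bp = manifest$pos_bp[idx[seg$i1]],
      copy_number = seg$cn, n_snps = seg$i1 - seg$i0 + 1L,
      quality = q, stringsAsFactors = FALSE)
  }
  if (!k) return(cnv_calls(data.frame()))
  cnv_calls(do.call(rbind, out[seq_len(k)]))
}

#' Call CNVs across an intensity panel
#'
#' @param panel `intensity_panel` (PC-corrected LRR recommended).
#' @param params `hmm_params`.
#' @param merge_rho fragment-merge threshold.
#' @return `cnv_calls` across all samples.
#' @export
call_cnvs <- function(panel, params = hmm_params(), merge_rho = 0.2) {
  res <- lapply(seq_along(panel$samples), function(i)
    call_sample(panel$lrr[i, ], panel$baf[i, ], panel$manifest, params,
                panel$samples[i], merge_rho))
  res <- res[vapply(res, nrow, 0L) > 0]
  if (!length(res)) return(cnv_calls(data.frame()))
  cnv_calls(do.call(rbind, lapply(res, function(x)
    x[, c("sample_id", "chrom", "start_bp", "end_bp", "copy_number",
          "n_snps", "quality")])))
}

#' Parental evidence for a child's call
#'
#' Re-tests the called state on a parent's intensities: the emission
#' log-likelihood ratio of the call's state versus diploid, summed over the
#' call's SNPs. `supported` when the LLR exceeds `llr_threshold` (default
#' 0, i.e. any positive evidence - a deliberately relaxed re-test);
#' `unknown` when the parent has no data at any of the call's SNPs.
#'
#' @param call one-row call (chrom, start_bp, end_bp, copy_number).
#' @param parent_lrr,parent_baf parent intensities in manifest order.
#' @param manifest `snp_manifest`.
#' @param params `hmm_params`.
#' @param llr_threshold support threshold (default 0).
#' @return one of "supported", "unsupported", "unknown".
#' @export
parent_state_evidence <- function(call, parent_lrr, parent_baf, manifest,
                                  params = hmm_params(), llr_threshold = 0) {
  idx <- which(manifest$chrom == call$chrom &
                 manifest$pos_bp >= call$start_bp &
                 manifest$pos_bp <= call$end_bp)
  if (!length(idx)) stop("call has no supporting SNPs in the manifest")
  l <- parent_lrr[idx]; b <- parent_baf[idx]
  if (all(is.na(l) & is.na(b))) return("unknown")
  logem <- .emissions(l, b, manifest$pfb[idx], params)
  state_col <- match(call$copy_number, params$copy_numbers)
  llr <- sum(logem[, state_col] - logem[, 3])
  if (llr > llr_threshold) "supported" else "unsupported"
}
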