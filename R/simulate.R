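## Seeded simulator for intensity panels, cohorts and trios. The generative
## model mirrors the artefact structure the pipeline removes:
##
##   LRR(s,m) = mu_cohort + mu_plate + w_s * g(m) + sum_k u_{s,k} v_{m,k}
##              + delta_state(s,m) + eps_{s,m},   eps ~ N(0, sigma_s^2)
##
## with g(m) the standardized GC profile, w_s a per-sample wave amplitude,
## u/v latent linear batch components, and delta_state the LRR shift inside
## spiked CNVs. BAF is generated from genotypes drawn at the marker PFB and
## transformed inside CNVs. All draws flow from one seeded generator; the
## stream order is: (1) sample attributes, (2) latent loadings,
## (3) genotypes and BAF, (4) CNV truth and spiking, (5) noise,
## (6) missingness.

#' Default per-state LRR shifts (copy numbers 0, 1, 3, 4)
#' @keywords internal
.default_state_shift <- c(`0` = -3.5, `1` = -0.67, `3` = 0.40, `4` = 0.68)

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale analogue of a large case-control array
#' study: three cohorts (cases and controls typed at two centres, mixed
#' cell-line and genomic DNA), 96-well plates with small LRR offsets, a
#' minority of high-noise and strong-wave samples, latent linear batch
#' components, and rare spiked CNVs of known state and length.
#'
#' @param n_case,n_control_a,n_control_b samples per cohort (cohort "a"
#'   shares the typing centre with cases; cohort "b" is a second centre on
#'   genomic DNA).
#' @param plate_size samples per plate.
#' @param cohort_offsets named LRR offsets per cohort.
#' @param plate_offset_sd SD of per-plate LRR offsets.
#' @param noise_sd base per-sample noise SD; `noise_outlier_frac` of samples
#'   instead draw SD `noise_outlier_sd` (the high-noise artefact class).
#' @param wave_sd SD of per-sample wave amplitude w_s; `wave_outlier_frac`
#'   get amplitude `wave_outlier_amp` (strong genomic waves).
#' @param n_latent_factors,latent_sd number of latent batch components and
#'   the per-SNP SD each contributes.
#' @param cnv_rate mean spiked CNVs per sample (Poisson).
#' @param cnv_state_probs probabilities of copy numbers 0/1/3/4.
#' @param cnv_len_snps_mean mean CNV length in SNPs (geometric above
#'   `cnv_len_snps_min`).
#' @param cnv_len_snps_min minimum CNV length in SNPs.
#' @param state_shift named LRR shifts for copy numbers 0/1/3/4; defaults to
#'   the caller's emission means so simulator and caller share one
#'   parameterisation.
#' @param baf_sd BAF band noise SD (bands are clipped normals).
#' @param aberrant_frac fraction of samples given a whole-chromosome
#'   duplication (the aneuploidy artefact class).
#' @param n_bad_plates plates whose samples are predominantly high-noise
#'   (drives the plate-exclusion rule); `bad_plate_noise_frac` of their
#'   samples are high-noise.
#' @param low_callrate_frac fraction of samples with genotype no-call rate
#'   `low_callrate_nc` (vs the base `nc_rate`).
#' @param missing_rate rate of missing LRR/BAF cells.
#' @param n_families,children_affected,unaffected_sib_prob trio structure:
#'   families each have two parents, `children_affected` affected children
#'   and an unaffected sibling with the given probability.
#' @param parent_cnv_rate mean CNVs per parent in trio simulations.
#' @param de_novo_rate probability an affected child carries one de novo CNV.
#' @param seed integer seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_case = 1000, n_control_a = 500, n_control_b = 500,
                       plate_size = 96,
                       cohort_offsets = c(case_centre_a = 0.02, control_centre_a = -0.02,
                                          control_centre_b = 0.04),
                       plate_offset_sd = 0.02,
                       noise_sd = 0.15, noise_outlier_frac = 0.02,
                       noise_outlier_sd = 0.35,
                       wave_sd = 0.04, wave_outlier_frac = 0.01,
                       wave_outlier_amp = 0.20,
                       n_latent_factors = 3, latent_sd = 0.03,
                       cnv_rate = 0.5, cnv_state_probs = c(`0` = 0.05, `1` = 0.55,
                                                         `3` = 0.35, `4` = 0.05),
                       cnv_len_snps_mean = 30, cnv_len_snps_min = 6,
                       state_shift = .default_state_shift,
                       baf_sd = 0.03,
                       aberrant_frac = 0.005,
                       n_bad_plates = 1, bad_plate_noise_frac = 0.5,
                       low_callrate_frac = 0.005, low_callrate_nc = 0.10,
                       nc_rate = 0.005, missing_rate = 0.002,
                       n_families = 200, children_affected = 2,
                       unaffected_sib_prob = 0.5,
                       parent_cnv_rate = 1, de_novo_rate = 0.05,
                       seed) {
  if (missing(seed)) stop("sim_config requires a seed")
  cfg <- as.list(environment())
  fr <- c("noise_outlier_frac", "wave_outlier_frac", "aberrant_frac",
          "low_callrate_frac", "low_callrate_nc", "nc_rate", "missing_rate",
          "unaffected_sib_prob", "de_novo_rate", "bad_plate_noise_frac")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0,1]")
  if (abs(sum(cnv_state_probs) - 1) > 1e-8) stop("cnv_state_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a SNP manifest
#'
#' Positions within each chromosome are cumulative exponential spacings
#' (dense, non-uniform coverage); GC is a smooth low-frequency oscillation
#' plus jitter, clipped to \[0.2, 0.8\]; PFB is a mixture of monomorphic
#' markers (PFB 0.01 or 0.99) and a uniform polymorphic bulk.
#'
#' @param n_snps total markers.
#' @param chrom_layout named numeric vector of per-chromosome marker
#'   fractions (default 4 autosomes of equal weight).
#' @param mean_spacing_bp mean inter-marker spacing.
#' @param monomorphic_frac fraction of monomorphic markers.
#' @param seed integer seed.
#' @return `snp_manifest`.
#' @export
build_manifest <- function(n_snps, chrom_layout = c(`1` = 1, `2` = 1, `3` = 1, `4` = 1),
                           mean_spacing_bp = 3000, monomorphic_frac = 0.15,
                           seed = 1) {
  if (is.null(names(chrom_layout)) || any(chrom_layout <= 0))
    stop("chrom_layout must be a named vector of positive weights")
  n_per <- round(n_snps * chrom_layout / sum(chrom_layout))
  n_per[length(n_per)] <- n_snps - sum(n_per[-length(n_per)])
  if (any(n_per < 2)) stop("need at least 2 SNPs per chromosome")
  set.seed(seed)
  rows <- lapply(seq_along(n_per), function(i) {
    n <- n_per[i]
    pos <- cumsum(pmax(1, round(rexp(n, 1 / mean_spacing_bp))))
    ## smooth GC: two incommensurate low-frequency oscillations + jitter
    t <- pos / max(pos)
    gc <- 0.45 + 0.12 * sin(2 * pi * 3.1 * t) + 0.08 * cos(2 * pi * 7.3 * t) +
      rnorm(n, 0, 0.02)
    gc <- pmin(0.8, pmax(0.2, gc))
    mono <- runif(n) < monomorphic_frac
    pfb <- ifelse(mono, ifelse(runif(n) < 0.5, 0.01, 0.99),
                  runif(n, 0.05, 0.95))
    data.frame(snp_id = sprintf("chr%s_snp%06d", names(n_per)[i], seq_len(n)),
               chrom = names(n_per)[i], pos_bp = pos,
               gc_fraction = gc, pfb = pfb, stringsAsFactors = FALSE)
  })
  snp_manifest(do.call(rbind, rows))
}

## draw genotype allele counts (0/1/2 B alleles) at HWE given pfb,
## as an n x M integer matrix; one uniform draw per cell against the
## cumulative genotype probabilities keeps the memory footprint low
.draw_allele_counts <- function(n, pfb) {
  M <- length(pfb)
  q0 <- rep((1 - pfb)^2, each = n)            # P(AA)
  q1 <- rep(1 - pfb^2, each = n)              # P(AA) + P(AB)
  u <- runif(n * M)
  counts <- (u > q0) + (u > q1)
  dim(counts) <- c(n, M)
  counts
}

## set k ~ Binomial(length, rate) random cells of a matrix to `value`
.sparse_assign <- function(x, rate, value) {
  k <- rbinom(1, length(x), rate)
  if (k > 0) x[sample.int(length(x), k)] <- value
  x
}

.baf_from_counts <- function(counts, total_copies, baf_sd) {
  mu <- counts / total_copies
  pmin(1, pmax(0, mu + rnorm(length(mu), 0, baf_sd)))
}

.gt_from_baf <- function(baf) {
  idx <- 1L + (baf >= 0.25) + (baf > 0.75)
  gt <- c("AA", "AB", "BB")[idx]
  gt[is.na(idx)] <- "NC"
  gt
}

## place random CNV truth intervals on a manifest; returns data.frame of
## (sample index, chrom, start/end SNP index, copy_number)
.spike_truth <- function(sample_ids, manifest, rate, state_probs, len_mean,
                         len_min, n_events = NULL) {
  if (is.null(n_events)) n_events <- rpois(length(sample_ids), rate)
  total <- sum(n_events)
  if (total == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      i_start = integer(), i_end = integer(),
                      copy_number = integer()))
  s_idx <- rep(seq_along(sample_ids), n_events)
  cn <- as.integer(sample(names(state_probs), total, replace = TRUE,
                          prob = state_probs))
  len <- len_min + rpois(total, max(0, len_mean - len_min))
  chroms <- unique(manifest$chrom)
  chrom_of <- sample(chroms, total, replace = TRUE)
  i_start <- integer(total); i_end <- integer(total)
  for (ch in chroms) {
    sel <- which(chrom_of == ch)
    if (!length(sel)) next
    rng <- range(which(manifest$chrom == ch))
    n_ch <- rng[2] - rng[1] + 1
    if (any(len[sel] > n_ch)) stop("CNV length exceeds chromosome extent")
    off <- floor(runif(length(sel)) * (n_ch - len[sel] + 1))
    i_start[sel] <- rng[1] + off
    i_end[sel] <- i_start[sel] + len[sel] - 1
  }
  data.frame(sample_id = sample_ids[s_idx], chrom = chrom_of,
             i_start = i_start, i_end = i_end, copy_number = cn,
             stringsAsFactors = FALSE)
}

## apply CNV state to BAF/genotype rows of one sample given pfb
.cnv_baf <- function(pfb, cn, baf_sd) {
  n <- length(pfb)
  if (cn == 0L) return(runif(n))
  copies <- if (cn == 1L) 1L else cn
  b <- rbinom(n, copies, pfb)
  pmin(1, pmax(0, b / copies + rnorm(n, 0, baf_sd)))
}

#' Simulate a case-control cohort
#'
#' Generates an intensity panel, sample sheet and truth tables under the
#' generative model described in the package vignette: cohort and plate LRR
#' offsets, GC-correlated waves, latent linear batch components,
#' heterogeneous per-sample noise, whole-chromosome aberrations and rare
#' spiked CNVs.
#'
#' @param config `sim_config`.
#' @param manifest `snp_manifest`.
#' @return list with elements `panel` (`intensity_panel`), `sheet`
#'   (`sample_sheet`) and `truth` (list of `samples`, `cnv`, `plates`).
#' @export
simulate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"), inherits(manifest, "snp_manifest"))
  set.seed(config$seed)
  M <- nrow(manifest)
  coh <- rep(names(config$cohort_offsets),
             c(config$n_case, config$n_control_a, config$n_control_b))
  n <- length(coh)
  pheno <- ifelse(grepl("^case", coh), "case", "control")
  dna <- ifelse(coh == "control_centre_b", "genomic", "cell_line")
  sid <- sprintf("S%05d", seq_len(n))
  plate <- sprintf("P%03d", ((seq_len(n) - 1) %/% config$plate_size) + 1)
  sheet <- sample_sheet(data.frame(
    sample_id = sid, phenotype = pheno, plate_id = plate, cohort_id = coh,
    dna_source = dna, sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE))

  ## (1) sample attributes
  plates <- unique(plate)
  plate_off <- rnorm(length(plates), 0, config$plate_offset_sd)
  names(plate_off) <- plates
  bad_plates <- if (config$n_bad_plates > 0)
    sample(plates, min(config$n_bad_plates, length(plates))) else character(0)
  high_noise <- runif(n) < config$noise_outlier_frac
  on_bad <- plate %in% bad_plates
  high_noise[on_bad] <- high_noise[on_bad] |
    (runif(sum(on_bad)) < config$bad_plate_noise_frac)
  sigma_s <- ifelse(high_noise, config$noise_outlier_sd, config$noise_sd)
  wave_out <- runif(n) < config$wave_outlier_frac
  w_s <- rnorm(n, 0, config$wave_sd)
  w_s[wave_out] <- config$wave_outlier_amp * sign(rnorm(sum(wave_out)))
  u <- matrix(rnorm(n * config$n_latent_factors), n, config$n_latent_factors)
  aberrant <- runif(n) < config$aberrant_frac
  chroms <- unique(manifest$chrom)
  ab_chrom <- ifelse(aberrant, sample(chroms, n, replace = TRUE), NA)
  low_cr <- runif(n) < config$low_callrate_frac

  ## (2) latent loadings
  v <- matrix(rnorm(config$n_latent_factors * M, 0, config$latent_sd),
              config$n_latent_factors, M)

  ## (3) genotypes + BAF
  counts <- .draw_allele_counts(n, manifest$pfb)
  baf <- .baf_from_counts(counts, 2L, config$baf_sd)
  dim(baf) <- c(n, M)

  ## (4) CNV truth + spiking of BAF (LRR shift applied in step 5)
  truth_cnv <- .spike_truth(sid, manifest, config$cnv_rate,
                            config$cnv_state_probs, config$cnv_len_snps_mean,
                            config$cnv_len_snps_min)
  s_of <- match(truth_cnv$sample_id, sid)
  if (nrow(truth_cnv)) {
    for (r in seq_len(nrow(truth_cnv))) {
      idx <- truth_cnv$i_start[r]:truth_cnv$i_end[r]
      baf[s_of[r], idx] <- .cnv_baf(manifest$pfb[idx], truth_cnv$copy_number[r],
                                    config$baf_sd)
    }
  }
  for (s in which(aberrant)) {
    idx <- which(manifest$chrom == ab_chrom[s])
    baf[s, idx] <- .cnv_baf(manifest$pfb[idx], 3L, config$baf_sd)
  }

  ## (5) LRR assembly (truth shifts applied in place)
  g <- as.numeric(scale(manifest$gc_fraction))
  lrr <- matrix(rnorm(n * M), n, M) * sigma_s
  lrr <- lrr + (config$cohort_offsets[coh] + plate_off[plate])
  lrr <- lrr + outer(w_s, g)
  lrr <- lrr + u %*% v
  if (nrow(truth_cnv)) {
    for (r in seq_len(nrow(truth_cnv))) {
      idx <- truth_cnv$i_start[r]:truth_cnv$i_end[r]
      lrr[s_of[r], idx] <- lrr[s_of[r], idx] +
        config$state_shift[[as.character(truth_cnv$copy_number[r])]]
    }
  }
  for (s in which(aberrant)) {
    idx <- which(manifest$chrom == ab_chrom[s])
    lrr[s, idx] <- lrr[s, idx] + config$state_shift[["3"]]
  }

  ## (6) genotype calls + missingness
  gt <- .gt_from_baf(baf)
  dim(gt) <- c(n, M)
  if (nrow(truth_cnv)) {
    for (r in which(truth_cnv$copy_number == 0L)) {
      gt[s_of[r], truth_cnv$i_start[r]:truth_cnv$i_end[r]] <- "NC"
    }
  }
  gt <- .sparse_assign(gt, config$nc_rate, "NC")
  extra_nc <- max(0, config$low_callrate_nc - config$nc_rate)
  for (s in which(low_cr)) {
    k <- rbinom(1, M, extra_nc)
    if (k > 0) gt[s, sample.int(M, k)] <- "NC"
  }
  lrr <- .sparse_assign(lrr, config$missing_rate, NA_real_)
  baf <- .sparse_assign(baf, config$missing_rate, NA_real_)

  dimnames(lrr) <- dimnames(baf) <- dimnames(gt) <- list(sid, manifest$snp_id)
  truth_cnv_out <- if (nrow(truth_cnv)) data.frame(
    sample_id = truth_cnv$sample_id, chrom = truth_cnv$chrom,
    start_bp = manifest$pos_bp[truth_cnv$i_start],
    end_bp = manifest$pos_bp[truth_cnv$i_end],
    copy_number = truth_cnv$copy_number,
    n_snps = truth_cnv$i_end - truth_cnv$i_start + 1L,
    stringsAsFactors = FALSE) else
      data.frame(sample_id = character(), chrom = character(),
                 start_bp = numeric(), end_bp = numeric(),
                 copy_number = integer(), n_snps = integer())
  list(panel = intensity_panel(lrr, baf, gt, manifest),
       sheet = sheet,
       truth = list(
         samples = data.frame(sample_id = sid, noise_sd = sigma_s,
                              high_noise = high_noise, wave = w_s,
                              aberrant_chrom = ab_chrom,
                              low_callrate = low_cr,
                              bad_plate = on_bad & plate %in% bad_plates,
                              stringsAsFactors = FALSE),
         cnv = truth_cnv_out,
         plates = data.frame(plate_id = plates,
                             offset = unname(plate_off),
                             bad = plates %in% bad_plates)))
}

#' Simulate family trios with transmission and de novo structure
#'
#' Each family has two parents, `children_affected` affected children and
#' (with probability `unaffected_sib_prob`) one unaffected sibling. Parental
#' CNVs are transmitted to each child independently with probability 0.5;
#' de novo CNVs are spiked in children at the configured rate; genotypes are
#' Mendelian.
#'
#' @param config `sim_config`.
#' @param manifest `snp_manifest`.
#' @return list with `panel`, `ped` (`pedigree`), and `truth` (list with
#'   `cnv`, `transmission`, `de_novo`).
#' @export
simulate_trios <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families < 1) stop("need at least one family")
  set.seed(config$seed + 1L)
  M <- nrow(manifest)
  fam <- sprintf("F%04d", seq_len(config$n_families))
  rows <- list(); k <- 0
  for (f in fam) {
    k <- k + 1
    kids <- config$children_affected
    sib <- runif(1) < config$unaffected_sib_prob
    rows[[k]] <- data.frame(
      family_id = f,
      individual_id = c(paste0(f, "_fa"), paste0(f, "_mo"),
                        paste0(f, "_c", seq_len(kids)),
                        if (sib) paste0(f, "_u1")),
      role = c("father", "mother", rep("child_aff", kids), if (sib) "child_unaff"),
      stringsAsFactors = FALSE)
  }
  ped_df <- do.call(rbind, rows)
  is_child <- grepl("^child", ped_df$role)
  ped <- pedigree(data.frame(
    family_id = ped_df$family_id, individual_id = ped_df$individual_id,
    father_id = ifelse(is_child, paste0(ped_df$family_id, "_fa"), NA),
    mother_id = ifelse(is_child, paste0(ped_df$family_id, "_mo"), NA),
    sex = ifelse(grepl("_fa$", ped_df$individual_id), "M",
                 ifelse(grepl("_mo$", ped_df$individual_id), "F",
                        sample(c("M", "F"), nrow(ped_df), replace = TRUE))),
    affection = ifelse(ped_df$role == "child_aff", "affected",
                       ifelse(ped_df$role == "child_unaff", "unaffected",
                              "unaffected")),
    stringsAsFactors = FALSE))
  sid <- ped_df$individual_id
  n <- length(sid)

  ## Mendelian genotypes: parental allele pairs, children inherit one from each
  p_idx <- which(!is_child)
  a1 <- matrix(0L, n, M); a2 <- matrix(0L, n, M)
  pmat <- matrix(manifest$pfb, length(p_idx), M, byrow = TRUE)
  a1[p_idx, ] <- (matrix(runif(length(p_idx) * M), length(p_idx), M) < pmat) + 0L
  a2[p_idx, ] <- (matrix(runif(length(p_idx) * M), length(p_idx), M) < pmat) + 0L
  fa_of <- match(ifelse(is_child, paste0(ped_df$family_id, "_fa"), NA), sid)
  mo_of <- match(ifelse(is_child, paste0(ped_df$family_id, "_mo"), NA), sid)
  for (i in which(is_child)) {
    pick1 <- runif(M) < 0.5
    a1[i, ] <- ifelse(pick1, a1[fa_of[i], ], a2[fa_of[i], ])
    pick2 <- runif(M) < 0.5
    a2[i, ] <- ifelse(pick2, a1[mo_of[i], ], a2[mo_of[i], ])
  }
  counts <- a1 + a2
  baf <- .baf_from_counts(counts, 2L, config$baf_sd)
  dim(baf) <- c(n, M)

  ## parental CNVs + transmission
  par_truth <- .spike_truth(sid[p_idx], manifest, config$parent_cnv_rate,
                            config$cnv_state_probs, config$cnv_len_snps_mean,
                            config$cnv_len_snps_min)
  if (nrow(par_truth)) par_truth$cnv_id <- sprintf("pcnv%04d", seq_len(nrow(par_truth)))
  events <- list(); trans <- list(); tk <- 0
  if (nrow(par_truth)) {
    child_of_fam <- split(which(is_child), ped_df$family_id[is_child])
    fam_of_parent <- ped_df$family_id[match(par_truth$sample_id, sid)]
    for (r in seq_len(nrow(par_truth))) {
      events[[length(events) + 1]] <- data.frame(
        sample_id = par_truth$sample_id[r], i_start = par_truth$i_start[r],
        i_end = par_truth$i_end[r], copy_number = par_truth$copy_number[r],
        origin = "parental", cnv_id = par_truth$cnv_id[r],
        stringsAsFactors = FALSE)
      for (ci in child_of_fam[[fam_of_parent[r]]]) {
        tr <- runif(1) < 0.5
        tk <- tk + 1
        trans[[tk]] <- data.frame(
          cnv_id = par_truth$cnv_id[r], parent_id = par_truth$sample_id[r],
          child_id = sid[ci], transmitted = tr, stringsAsFactors = FALSE)
        if (tr) events[[length(events) + 1]] <- data.frame(
          sample_id = sid[ci], i_start = par_truth$i_start[r],
          i_end = par_truth$i_end[r], copy_number = par_truth$copy_number[r],
          origin = "transmitted", cnv_id = par_truth$cnv_id[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  ## de novo CNVs in children
  dn_children <- which(is_child & runif(n) < config$de_novo_rate)
  if (length(dn_children)) {
    dn <- .spike_truth(sid[dn_children], manifest, rate = NA,
                       config$cnv_state_probs, config$cnv_len_snps_mean,
                       config$cnv_len_snps_min,
                       n_events = rep(1L, length(dn_children)))
    for (r in seq_len(nrow(dn))) {
      events[[length(events) + 1]] <- data.frame(
        sample_id = dn$sample_id[r], i_start = dn$i_start[r],
        i_end = dn$i_end[r], copy_number = dn$copy_number[r],
        origin = "de_novo", cnv_id = sprintf("dncnv%04d", r),
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(sample_id = character(), i_start = integer(), i_end = integer(),
               copy_number = integer(), origin = character(), cnv_id = character())

  ## LRR + BAF spiking
  sigma_s <- ifelse(runif(n) < config$noise_outlier_frac,
                    config$noise_outlier_sd, config$noise_sd)
  w_s <- rnorm(n, 0, config$wave_sd)
  g <- as.numeric(scale(manifest$gc_fraction))
  lrr <- matrix(rnorm(n * M), n, M) * sigma_s + outer(w_s, g)
  if (nrow(ev)) {
    s_of <- match(ev$sample_id, sid)
    for (r in seq_len(nrow(ev))) {
      idx <- ev$i_start[r]:ev$i_end[r]
      cn <- ev$copy_number[r]
      lrr[s_of[r], idx] <- lrr[s_of[r], idx] + config$state_shift[[as.character(cn)]]
      baf[s_of[r], idx] <- .cnv_baf(manifest$pfb[idx], cn, config$baf_sd)
    }
  }
  gt <- .gt_from_baf(baf); dim(gt) <- c(n, M)
  gt <- .sparse_assign(gt, config$nc_rate, "NC")
  dimnames(lrr) <- dimnames(baf) <- dimnames(gt) <- list(sid, manifest$snp_id)

  ev_out <- if (nrow(ev)) data.frame(
    sample_id = ev$sample_id, chrom = manifest$chrom[ev$i_start],
    start_bp = manifest$pos_bp[ev$i_start], end_bp = manifest$pos_bp[ev$i_end],
    copy_number = ev$copy_number, n_snps = ev$i_end - ev$i_start + 1L,
    origin = ev$origin, cnv_id = ev$cnv_id, stringsAsFactors = FALSE) else ev
  list(panel = intensity_panel(lrr, baf, gt, manifest),
       ped = ped,
       truth = list(
         cnv = ev_out,
         transmission = if (tk) do.call(rbind, trans) else
           data.frame(cnv_id = character(), parent_id = character(),
                      child_id = character(), transmitted = logical()),
         de_novo = ev_out[ev_out$origin == "de_novo", , drop = FALSE]))
}
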