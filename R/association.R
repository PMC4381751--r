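## Exact 2x2 statistics, burden strata, CNVR scans, family transmissions,
## TDT, de novo burden and the large-CNV report.

#' Exact 2x2 test with sample and conditional-MLE odds ratios
#'
#' Two-sided p-value by the minimum-likelihood convention (sum of
#' hypergeometric outcome probabilities no larger than the observed one),
#' conditional maximum-likelihood odds ratio, and the exact conditional
#' confidence interval - the conventions of [stats::fisher.test()]. The
#' sample (cross-product) estimate a*d/(b*c) is reported alongside;
#' it and the CI are `NA` when any cell is zero.
#'
#' @param a,b,c,d cell counts: (events, non-events) in group 1 then group 2.
#' @param conf_level confidence level (default 0.95).
#' @return list with `p`, `or_sample`, `or_cmle`, `ci_low`, `ci_high` and
#'   the counts.
#' @export
fisher_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell counts")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  ft <- fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                    conf.level = conf_level)
  zero <- any(cells == 0)
  list(a = a, b = b, c = c, d = d,
       p = ft$p.value,
       or_sample = if (zero) NA_real_ else (a * d) / (b * c),
       or_cmle = .or_cmle(a, b, c, d),
       ci_low = if (zero) NA_real_ else ft$conf.int[1],
       ci_high = if (zero) NA_real_ else ft$conf.int[2])
}

## conditional MLE of the noncentral hypergeometric odds ratio: the value
## whose conditional expectation of the a-cell equals the observed count
.or_cmle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; s <- a + c
  ks <- max(0, s - r2):min(r1, s)
  if (a == min(ks)) return(0)
  if (a == max(ks)) return(Inf)
  logw0 <- lchoose(r1, ks) + lchoose(r2, s - ks)
  cond_mean <- function(log_or) {
    lw <- logw0 + ks * log_or
    w <- exp(lw - max(lw))
    sum(ks * w) / sum(w)
  }
  exp(stats::uniroot(function(lo) cond_mean(lo) - a, c(-36, 36),
                     tol = .Machine$double.eps^0.5)$root)
}

#' Burden test from event counts and group totals
#'
#' Builds the (events, remaining samples) 2x2 used for burden analysis and
#' runs [fisher_2x2()]: a = case events, b = cases minus case events, and
#' likewise for controls.
#'
#' @param events_case,events_control event counts.
#' @param n_case,n_control post-QC sample totals.
#' @param label stratum label.
#' @return one-row data.frame (a `BurdenResult`).
#' @export
burden_test <- function(events_case, n_case, events_control, n_control,
                        label = "all") {
  f <- fisher_2x2(events_case, n_case - events_case,
                  events_control, n_control - events_control)
  data.frame(stratum = label, events_case = events_case,
             events_control = events_control, n_case = n_case,
             n_control = n_control, or_sample = f$or_sample,
             or_cmle = f$or_cmle, ci_low = f$ci_low, ci_high = f$ci_high,
             p = f$p, stringsAsFactors = FALSE)
}

## length strata: half-open (lo, hi] in bp, strict > for the top bin
.length_bins <- list(
  DEL = data.frame(label = c("0-20kb", "20-400kb", ">400kb"),
                   lo = c(0, 20e3, 400e3), hi = c(20e3, 400e3, Inf)),
  DUP = data.frame(label = c("0-50kb", "50-400kb", ">400kb"),
                   lo = c(0, 50e3, 400e3), hi = c(50e3, 400e3, Inf)))

#' Case-control CNV burden by stratum
#'
#' Tests total CNV-event rates between cases and controls for each class
#' overall, per length bin (deletions: 0-20 kb, 20-400 kb, >400 kb;
#' duplications: 0-50 kb, 50-400 kb, >400 kb - the lower break differs
#' because short duplications are scarcer), and per annotation flag
#' (`overlaps_*` columns) when present. The length analysis carries a
#' Bonferroni m of 6.
#'
#' @param calls filtered `cnv_calls` with phenotype resolvable via `sheet`.
#' @param sheet `sample_sheet` (post-QC samples only; defines totals).
#' @return data.frame of burden results, one row per (class, stratum), with
#'   a `bonferroni_m` column.
#' @export
burden_strata <- function(calls, sheet) {
  ph <- sheet$phenotype
  n_case <- sum(ph == "case"); n_control <- sum(ph == "control")
  call_ph <- sheet$phenotype[match(calls$sample_id, sheet$sample_id)]
  if (anyNA(call_ph)) stop("call sample absent from sample sheet")
  rows <- list()
  flag_cols <- grep("^overlaps_", names(calls), value = TRUE)
  for (cls in c("DEL", "DUP")) {
    sub <- calls[calls$cnv_class == cls, , drop = FALSE]
    sph <- call_ph[calls$cnv_class == cls]
    add <- function(sel, label, m) {
      rows[[length(rows) + 1]] <<- cbind(
        class = cls,
        burden_test(sum(sel & sph == "case"), n_case,
                    sum(sel & sph == "control"), n_control, label),
        bonferroni_m = m, stringsAsFactors = FALSE)
    }
    add(rep(TRUE, nrow(sub)), "all", 1L)
    bins <- .length_bins[[cls]]
    for (i in seq_len(nrow(bins)))
      add(sub$length_bp > bins$lo[i] & sub$length_bp <= bins$hi[i],
          bins$label[i], 6L)
    for (fc in flag_cols)
      add(sub[[fc]], sub("^overlaps_", "", fc), length(flag_cols))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional case-control scan over rare CNVRs
#'
#' One exact test per CNVR of carriers versus non-carriers, with the
#' Bonferroni threshold `fwe / m` over the m tested regions and QQ data
#' (sorted p-values against uniform quantiles).
#'
#' @param cnvrs `cnvr_table` (rare CNVRs, carrier counts filled).
#' @param n_case,n_control post-QC group sizes.
#' @param fwe family-wise error rate (default 0.05).
#' @return list with `table`, `threshold`, `m`, `qq` (data.frame of
#'   expected/observed p).
#' @export
cnvr_scan <- function(cnvrs, n_case, n_control, fwe = 0.05) {
  if (nrow(cnvrs) == 0)
    return(list(table = data.frame(), threshold = NA_real_, m = 0L,
                qq = data.frame(expected = numeric(), observed = numeric())))
  res <- lapply(seq_len(nrow(cnvrs)), function(i) {
    f <- fisher_2x2(cnvrs$carriers_case[i], n_case - cnvrs$carriers_case[i],
                    cnvrs$carriers_control[i],
                    n_control - cnvrs$carriers_control[i])
    data.frame(cnvr_id = cnvrs$cnvr_id[i], chrom = cnvrs$chrom[i],
               start_bp = cnvrs$start_bp[i], end_bp = cnvrs$end_bp[i],
               cnv_class = cnvrs$cnv_class[i],
               carriers_case = cnvrs$carriers_case[i],
               carriers_control = cnvrs$carriers_control[i],
               or_sample = f$or_sample, or_cmle = f$or_cmle, p = f$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  m <- nrow(tab)
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  list(table = tab, threshold = fwe / m, m = m,
       qq = data.frame(expected = (seq_len(m) - 0.5) / m,
                       observed = sort(tab$p)))
}

#' Bonferroni threshold for a regional scan
#' @param m number of tests.
#' @param fwe family-wise error rate (default 0.05).
#' @return numeric threshold `fwe / m`.
#' @export
bonferroni_threshold <- function(m, fwe = 0.05) {
  if (m < 1) stop("m must be >= 1")
  fwe / m
}

## reciprocal-overlap match between one interval and a set of intervals
.matches_any <- function(s, e, starts, ends, min_recip) {
  ov <- pmin(e, ends) - pmax(s, starts) + 1
  ok <- ov >= 1
  if (min_recip > 0) {
    len1 <- e - s + 1; len2 <- ends - starts + 1
    ok <- ok & (ov / len1 >= min_recip) & (ov / len2 >= min_recip)
  }
  ok
}

#' Family transmission tallies
#'
#' Groups parental calls (per class) into loci with segment-group
#' semantics, then counts, for every locus and family: possible
#' transmissions = children x carrier parents, and transmitted = per child
#' the number of its same-class calls matching the locus (>= 1 bp overlap
#' and reciprocal overlap >= `min_recip` against a parental member call),
#' capped at the carrier-parent count. Tallies are split by child
#' affection; the aggregate burden ratio is the affected transmission rate
#' over the unaffected one.
#'
#' @param calls `cnv_calls` for the family dataset.
#' @param ped `pedigree`.
#' @param min_recip reciprocal-overlap requirement (default 0.5).
#' @return list with `per_locus` (one row per locus x affection),
#'   `aggregate` (per class x affection rates) and `ratio` (per class).
#' @export
transmission_counts <- function(calls, ped, min_recip = 0.5) {
  parent_ids <- unique(stats::na.omit(c(ped$father_id, ped$mother_id)))
  children <- ped[!is.na(ped$father_id) | !is.na(ped$mother_id), , drop = FALSE]
  per_locus <- list()
  for (cls in c("DEL", "DUP")) {
    pc <- calls[calls$cnv_class == cls & calls$sample_id %in% parent_ids, ,
                drop = FALSE]
    if (nrow(pc) == 0) next
    cnvrs <- group_cnvrs(pc)
    pcalls <- attr(cnvrs, "calls")
    ccalls <- calls[calls$cnv_class == cls &
                      calls$sample_id %in% children$individual_id, ,
                    drop = FALSE]
    for (g in seq_len(nrow(cnvrs))) {
      m <- cnvrs$members[[g]]
      locus_parents <- unique(pcalls$sample_id[m])
      fam_of <- ped$family_id[match(locus_parents, ped$individual_id)]
      tall <- list()
      for (fam in unique(fam_of)) {
        cp <- locus_parents[fam_of == fam]
        kids <- children[children$family_id == fam, , drop = FALSE]
        if (!nrow(kids)) next
        for (ki in seq_len(nrow(kids))) {
          kc <- ccalls[ccalls$sample_id == kids$individual_id[ki], ,
                       drop = FALSE]
          n_match <- 0L
          if (nrow(kc)) {
            for (r in seq_len(nrow(kc))) {
              hit <- .matches_any(kc$start_bp[r], kc$end_bp[r],
                                  pcalls$start_bp[m], pcalls$end_bp[m],
                                  min_recip)
              if (any(hit)) n_match <- n_match + 1L
            }
          }
          tall[[length(tall) + 1]] <- data.frame(
            affection = kids$affection[ki], possible = length(cp),
            transmitted = min(n_match, length(cp)), stringsAsFactors = FALSE)
        }
      }
      if (!length(tall)) next
      tt <- do.call(rbind, tall)
      agg <- aggregate(cbind(possible, transmitted) ~ affection, tt, sum)
      agg$cnv_class <- cls
      agg$locus_id <- cnvrs$cnvr_id[g]
      agg$chrom <- cnvrs$chrom[g]
      agg$start_bp <- cnvrs$start_bp[g]; agg$end_bp <- cnvrs$end_bp[g]
      per_locus[[length(per_locus) + 1]] <- agg
    }
  }
  if (!length(per_locus))
    return(list(per_locus = data.frame(), aggregate = data.frame(),
                ratio = c(DEL = NA_real_, DUP = NA_real_)))
  pl <- do.call(rbind, per_locus)
  agg <- aggregate(cbind(possible, transmitted) ~ cnv_class + affection, pl, sum)
  agg$rate <- agg$transmitted / agg$possible
  ratio <- sapply(c("DEL", "DUP"), function(cls) {
    ra <- agg$rate[agg$cnv_class == cls & agg$affection == "affected"]
    ru <- agg$rate[agg$cnv_class == cls & agg$affection == "unaffected"]
    if (!length(ra) || !length(ru) || ru == 0) NA_real_ else ra / ru
  })
  list(per_locus = pl, aggregate = agg, ratio = ratio)
}

#' Transmission burden ratio from transmission rates
#'
#' The affected-offspring transmission rate divided by the unaffected one;
#' rates may be given as fractions or percentages (the units cancel).
#'
#' @param rate_affected,rate_unaffected transmission rates.
#' @return scalar ratio.
#' @export
transmission_burden_ratio <- function(rate_affected, rate_unaffected) {
  if (rate_unaffected <= 0) stop("unaffected rate must be positive")
  rate_affected / rate_unaffected
}

#' Exact transmission-disequilibrium test
#'
#' Two-sided exact binomial test of the transmission count against rate
#' 0.5, by doubling the smaller tail and capping at 1.
#'
#' @param transmitted,possible transmission counts, `0 <= transmitted <=
#'   possible`, `possible >= 1`.
#' @return p-value.
#' @export
tdt_exact <- function(transmitted, possible) {
  if (possible < 1) stop("possible must be >= 1")
  if (transmitted < 0 || transmitted > possible)
    stop("transmitted must lie in [0, possible]")
  lower <- pbinom(transmitted, possible, 0.5)
  upper <- pbinom(transmitted - 1, possible, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' TDT scan over transmission loci
#'
#' Applies [tdt_exact()] to the affected-offspring transmissions of every
#' locus from [transmission_counts()], reporting the unaffected rate
#' alongside for interpretation (differential detection sensitivity can
#' depress both).
#'
#' @param trans result of [transmission_counts()].
#' @return data.frame: one row per locus with transmitted/possible by
#'   affection and `p_affected`.
#' @export
tdt_scan <- function(trans) {
  pl <- trans$per_locus
  if (!nrow(pl)) return(data.frame())
  loci <- unique(pl$locus_id)
  rows <- lapply(loci, function(l) {
    sub <- pl[pl$locus_id == l, ]
    g <- function(aff, col) {
      v <- sub[[col]][sub$affection == aff]
      if (length(v)) sum(v) else 0L
    }
    ta <- g("affected", "transmitted"); pa <- g("affected", "possible")
    tu <- g("unaffected", "transmitted"); pu <- g("unaffected", "possible")
    data.frame(locus_id = l, chrom = sub$chrom[1], start_bp = sub$start_bp[1],
               end_bp = sub$end_bp[1], cnv_class = sub$cnv_class[1],
               transmitted_aff = ta, possible_aff = pa,
               transmitted_unaff = tu, possible_unaff = pu,
               p_affected = if (pa >= 1) tdt_exact(ta, pa) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_affected), ]
}

#' De novo CNV vetting and burden
#'
#' A child's call is de novo iff no same-class parental call overlaps it
#' (>= 1 bp) and the parental-evidence re-test ([parent_state_evidence()])
#' is "unsupported" in both parents. Calls where either parent has no
#' intensity data are labelled "unknown" and excluded from the burden test,
#' which compares children carrying >= 1 de novo call between affected and
#' unaffected offspring with [fisher_2x2()].
#'
#' @param calls `cnv_calls` for the family dataset (children and parents).
#' @param ped `pedigree`.
#' @param panel `intensity_panel` holding parental intensities.
#' @param params `hmm_params` for the evidence re-test.
#' @param cnv_class restrict to "DEL" or "DUP" (default both).
#' @return list with `calls` (child calls + `denovo_status`), `counts`, and
#'   `test` (exact p), per class.
#' @export
denovo_burden <- function(calls, ped, panel, params = hmm_params(),
                          cnv_class = c("DEL", "DUP")) {
  kids <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id), , drop = FALSE]
  cc <- calls[calls$sample_id %in% kids$individual_id &
                calls$cnv_class %in% cnv_class, , drop = FALSE]
  status <- character(nrow(cc))
  for (r in seq_len(nrow(cc))) {
    kid <- kids[match(cc$sample_id[r], kids$individual_id), ]
    pids <- c(kid$father_id, kid$mother_id)
    pcalls <- calls[calls$sample_id %in% pids &
                      calls$cnv_class == cc$cnv_class[r] &
                      calls$chrom == cc$chrom[r], , drop = FALSE]
    inherited <- nrow(pcalls) > 0 &&
      any(.matches_any(cc$start_bp[r], cc$end_bp[r], pcalls$start_bp,
                       pcalls$end_bp, 0))
    if (inherited) { status[r] <- "inherited"; next }
    ev <- vapply(pids, function(p) {
      pi <- match(p, panel$samples)
      if (is.na(pi)) return("unknown")
      parent_state_evidence(cc[r, ], panel$lrr[pi, ], panel$baf[pi, ],
                            panel$manifest, params)
    }, character(1))
    status[r] <- if (any(ev == "unknown")) "unknown"
    else if (all(ev == "unsupported")) "de_novo" else "parental_evidence"
  }
  cc$denovo_status <- status
  dn_samples <- unique(cc$sample_id[status == "de_novo"])
  aff <- kids$affection
  n_aff <- sum(aff == "affected"); n_unaff <- sum(aff == "unaffected")
  dn_aff <- sum(kids$individual_id %in% dn_samples & aff == "affected")
  dn_unaff <- sum(kids$individual_id %in% dn_samples & aff == "unaffected")
  test <- if (n_aff > 0 && n_unaff > 0)
    fisher_2x2(dn_aff, n_aff - dn_aff, dn_unaff, n_unaff - dn_unaff) else NULL
  list(calls = cc,
       counts = c(denovo_affected = dn_aff, n_affected = n_aff,
                  denovo_unaffected = dn_unaff, n_unaffected = n_unaff),
       test = test)
}

#' Large-CNV report
#'
#' Tabulates calls strictly longer than `min_len` and tests carrier counts
#' between cases and controls with the exact 2x2 test.
#'
#' @param calls annotated `cnv_calls`.
#' @param sheet `sample_sheet` (post-QC totals).
#' @param min_len length threshold in bp (default 3e6, strict `>`).
#' @return list with `table` (per-call rows) and `test`.
#' @export
large_cnv_table <- function(calls, sheet, min_len = 3e6) {
  big <- calls[calls$length_bp > min_len, , drop = FALSE]
  if (nrow(big) == 0) return(list(table = big, test = NULL))
  ph <- sheet$phenotype[match(big$sample_id, sheet$sample_id)]
  tab <- data.frame(locus = sprintf("%s:%.0f-%.0f", big$chrom, big$start_bp,
                                    big$end_bp),
                    length_mb = big$length_bp / 1e6, cnv_class = big$cnv_class,
                    phenotype = ph, n_snps = big$n_snps,
                    sample_id = big$sample_id, stringsAsFactors = FALSE)
  if (!is.null(big$genes_hits))
    tab$genes <- vapply(big$genes_hits, function(g)
      if (!length(g)) "" else if (length(g) == 1) g else
        sprintf("%s +%d", g[1], length(g) - 1), character(1))
  n_case <- sum(sheet$phenotype == "case")
  n_control <- sum(sheet$phenotype == "control")
  carr_case <- length(unique(big$sample_id[ph == "case"]))
  carr_ctrl <- length(unique(big$sample_id[ph == "control"]))
  test <- fisher_2x2(carr_case, n_case - carr_case,
                     carr_ctrl, n_control - carr_ctrl)
  list(table = tab, test = test)
}
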