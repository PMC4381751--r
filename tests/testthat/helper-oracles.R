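# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: enumeration with log-binomials for the
# exact tests, explicit path sums for the HMM, pairwise scans for interval
# logic.

# hypergeometric enumeration for the 2x2 exact test: two-sided p by the
# minimum-likelihood rule and the conditional-MLE odds ratio by root-finding
# on the conditional expectation
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; s <- a + c
  ks <- max(0, s - r2):min(r1, s)
  logw <- lchoose(r1, ks) + lchoose(r2, s - ks)
  w <- exp(logw - max(logw))
  p_k <- w / sum(w)
  obs <- p_k[match(a, ks)]
  sum(p_k[p_k <= obs * (1 + 1e-7)])
}

oracle_fisher_cmle <- function(a, b, c, d) {
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
  exp(uniroot(function(lo) cond_mean(lo) - a, c(-50, 50), tol = 1e-12)$root)
}

# exact binomial TDT oracle: double the smaller tail by direct summation
oracle_tdt <- function(t, n) {
  probs <- exp(lchoose(n, 0:n) - n * log(2))
  lower <- sum(probs[seq_len(t + 1)])
  upper <- sum(probs[(t + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# full multinomial enumeration oracle for the HWE exact test
oracle_hwe <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  tabs <- list(); probs <- numeric(0)
  for (h in 0:n) {
    aa2 <- nA - h
    if (aa2 < 0 || aa2 %% 2 != 0) next
    aa <- aa2 / 2; bb <- n - aa - h
    if (bb < 0) next
    lw <- lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
    tabs[[length(tabs) + 1]] <- h
    probs <- c(probs, exp(lw))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAB, unlist(tabs))]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# transition matrix of the caller's distance model, independent R build
oracle_trans <- function(d, D, pi) {
  f <- 1 - exp(-d / D)
  A <- outer(rep(1, 5), pi * f)
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  A
}

# forward-backward posteriors by explicit enumeration of all 5^n paths
oracle_posteriors <- function(logem, pos, pi, D) {
  n <- nrow(logem)
  grid <- as.matrix(expand.grid(rep(list(1:5), n)))
  logp <- apply(grid, 1, function(path) {
    lp <- log(pi[path[1]]) + logem[1, path[1]]
    for (t in seq_len(n - 1)) {
      A <- oracle_trans(pos[t + 1] - pos[t], D, pi)
      lp <- lp + log(A[path[t], path[t + 1]]) + logem[t + 1, path[t + 1]]
    }
    lp
  })
  w <- exp(logp - max(logp)); w <- w / sum(w)
  post <- matrix(0, n, 5)
  for (t in 1:n) for (s in 1:5) post[t, s] <- sum(w[grid[, t] == s])
  post
}

# best path log-probability by enumeration
oracle_best_path <- function(logem, pos, pi, D) {
  n <- nrow(logem)
  grid <- as.matrix(expand.grid(rep(list(1:5), n)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    lp <- log(pi[path[1]]) + logem[1, path[1]]
    for (t in seq_len(n - 1)) {
      A <- oracle_trans(pos[t + 1] - pos[t], D, pi)
      lp <- lp + log(A[path[t], path[t + 1]]) + logem[t + 1, path[t + 1]]
    }
    if (lp > best) best <- lp
  }
  best
}

# maximal common-point interval sets by brute force
oracle_interval_groups <- function(s, e) {
  sets <- unique(lapply(sort(unique(s)), function(p) which(s <= p & e >= p)))
  keep <- vapply(seq_along(sets), function(i)
    !any(vapply(seq_along(sets), function(j)
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]]), logical(1))), logical(1))
  lapply(sets[keep], sort)
}

# small helpers shared by tests
tiny_manifest <- function(n = 20, chrom = "1", spacing = 1000, pfb = 0.5,
                          gc = 0.5) {
  snp_manifest(data.frame(
    snp_id = sprintf("%s_s%03d", chrom, 1:n), chrom = chrom,
    pos_bp = seq(spacing, by = spacing, length.out = n),
    gc_fraction = gc, pfb = pfb))
}

make_calls <- function(start, end, sample_id = "s1", chrom = "1", cn = 1,
                       n_snps = 10, quality = 1) {
  cnv_calls(data.frame(sample_id = sample_id, chrom = chrom,
                       start_bp = start, end_bp = end, copy_number = cn,
                       n_snps = n_snps, quality = quality))
}
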