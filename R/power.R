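## Sample-size grids for regional CNV association scans.

.p1_from_or <- function(p0, or) or * p0 / (1 + p0 * (or - 1))

## power of the two-sided carrier-frequency comparison at total N (1:1 split
## unless ratio given), normal approximation on the log odds ratio
.power_normal <- function(total_n, p0, or, alpha, ratio) {
  n_case <- total_n * ratio / (1 + ratio)
  n_ctrl <- total_n / (1 + ratio)
  p1 <- .p1_from_or(p0, or)
  se <- sqrt(1 / (n_case * p1) + 1 / (n_case * (1 - p1)) +
               1 / (n_ctrl * p0) + 1 / (n_ctrl * (1 - p0)))
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(log(or)) / se - z)
}

## Monte-Carlo power of the exact test (oracle-grade, slow)
.power_mc <- function(total_n, p0, or, alpha, ratio, n_rep = 200) {
  n_case <- round(total_n * ratio / (1 + ratio))
  n_ctrl <- round(total_n / (1 + ratio))
  p1 <- .p1_from_or(p0, or)
  hits <- 0
  for (r in seq_len(n_rep)) {
    a <- rbinom(1, n_case, p1); c <- rbinom(1, n_ctrl, p0)
    p <- fisher.test(matrix(c(a, n_case - a, c, n_ctrl - c), 2, 2,
                            byrow = TRUE))$p.value
    if (p < alpha) hits <- hits + 1
  }
  hits / n_rep
}

#' Required sample sizes for a regional CNV scan
#'
#' For each (odds ratio, carrier frequency) pair, the smallest total sample
#' size on the grid 10,000 x {1, 2, 3, ...} achieving the target power for
#' a two-sided comparison of carrier frequencies at level `alpha` (a
#' Bonferroni threshold for ~1000 regions by default). Results are in
#' units of 10,000 samples; odds ratios of 1 or below have no finite
#' requirement and return `NA`.
#'
#' @param or_values odds ratios (> 1).
#' @param freq_values control carrier frequencies in (0, 1).
#' @param alpha significance threshold (default 5e-5).
#' @param power target power (default 0.8).
#' @param ratio case:control ratio (default 1).
#' @param method "normal" (log-OR approximation, default) or "montecarlo"
#'   (exact-test simulation; small grids only).
#' @param max_units search ceiling in units of 10,000 (default 1e5).
#' @param n_rep Monte-Carlo replicates per grid point.
#' @return list of class `power_grid`: `required_units` matrix (frequencies
#'   x odds ratios, units of 10,000) plus the settings.
#' @export
power_grid <- function(or_values, freq_values, alpha = 5e-5, power = 0.8,
                       ratio = 1, method = c("normal", "montecarlo"),
                       max_units = 1e5, n_rep = 200) {
  method <- match.arg(method)
  if (any(freq_values <= 0 | freq_values >= 1)) stop("frequencies must lie in (0,1)")
  pw <- function(units, p0, or) {
    if (method == "normal") .power_normal(units * 1e4, p0, or, alpha, ratio)
    else .power_mc(units * 1e4, p0, or, alpha, ratio, n_rep)
  }
  req <- matrix(NA_real_, length(freq_values), length(or_values),
                dimnames = list(paste0("f", freq_values), paste0("or", or_values)))
  for (i in seq_along(freq_values)) {
    for (j in seq_along(or_values)) {
      or <- or_values[j]
      if (or <= 1) next
      p0 <- freq_values[i]
      if (pw(max_units, p0, or) < power) next
      ## power is monotone in N: bisect on the unit grid
      lo <- 1; hi <- max_units
      if (pw(lo, p0, or) >= power) { req[i, j] <- 1; next }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (pw(mid, p0, or) >= power) hi <- mid else lo <- mid
      }
      req[i, j] <- hi
    }
  }
  structure(list(required_units = req, or_values = or_values,
                 freq_values = freq_values, alpha = alpha, power = power,
                 ratio = ratio, method = method), class = "power_grid")
}
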