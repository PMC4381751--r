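## CNV call container and interchange formats. Calls live in a plain
## data.frame; the text format is one call per line,
##   chrN:start-end numsnp=K cn=C sample=S quality=Q
## with a BED export (0-based half-open) for genome-browser use.

#' Construct and validate a table of CNV calls
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `copy_number` (0/1/3/4), `n_snps`, `quality`. `cnv_class`
#'   (DEL/DUP) and `length_bp` are derived.
#' @return data.frame of class `cnv_calls`.
#' @export
cnv_calls <- function(df) {
  need <- c("sample_id", "chrom", "start_bp", "end_bp", "copy_number", "n_snps", "quality")
  if (nrow(df) == 0 && !all(need %in% names(df))) {
    df <- data.frame(sample_id = character(), chrom = character(),
                     start_bp = numeric(), end_bp = numeric(),
                     copy_number = integer(), n_snps = integer(),
                     quality = numeric())
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calls missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$start_bp <- as.numeric(df$start_bp); df$end_bp <- as.numeric(df$end_bp)
  df$copy_number <- as.integer(df$copy_number)
  df$n_snps <- as.integer(df$n_snps)
  if (any(df$start_bp > df$end_bp)) stop("call start_bp > end_bp")
  if (!all(df$copy_number %in% c(0L, 1L, 3L, 4L))) stop("copy_number must be in {0,1,3,4}")
  if (any(df$n_snps < 1L)) stop("n_snps must be >= 1")
  if (any(df$quality < 0 | df$quality > 1, na.rm = TRUE)) stop("quality outside [0,1]")
  df$cnv_class <- ifelse(df$copy_number < 2L, "DEL", "DUP")
  df$length_bp <- df$end_bp - df$start_bp + 1
  keep <- c(need[1:6], "quality", "cnv_class", "length_bp")
  extra <- setdiff(names(df), keep)
  df <- df[, c(keep, extra)]
  rownames(df) <- NULL
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Write / read CNV calls in the one-line-per-call text format
#'
#' Format: `chrN:start-end numsnp=K cn=C sample=S quality=Q` with quality
#' printed to six decimals. [read_cnv_calls()] is the exact inverse.
#'
#' @param calls `cnv_calls`.
#' @param path file path.
#' @export
write_cnv_calls <- function(calls, path) {
  ff <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- sprintf("%s:%s-%s numsnp=%d cn=%d sample=%s quality=%.6f",
                   calls$chrom, ff(calls$start_bp), ff(calls$end_bp),
                   calls$n_snps, calls$copy_number, calls$sample_id, calls$quality)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cnv_calls
#' @export
read_cnv_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(cnv_calls(data.frame()))
  pat <- "^(\\S+):([0-9]+)-([0-9]+) numsnp=([0-9]+) cn=([0-9]+) sample=(\\S+) quality=([0-9.eE+-]+)$"
  ok <- grepl(pat, lines)
  if (any(!ok)) stop("malformed call line ", which(!ok)[1])
  m <- regmatches(lines, regexec(pat, lines))
  g <- function(i) vapply(m, `[[`, "", i + 1L)
  q <- as.numeric(g(7))
  if (any(is.na(q) | q < 0 | q > 1)) stop("quality outside [0,1] at line ",
                                          which(is.na(q) | q < 0 | q > 1)[1])
  cnv_calls(data.frame(
    sample_id = g(6), chrom = g(1), start_bp = as.numeric(g(2)),
    end_bp = as.numeric(g(3)), copy_number = as.integer(g(5)),
    n_snps = as.integer(g(4)), quality = q, stringsAsFactors = FALSE))
}

#' Export CNV calls as BED (0-based half-open)
#'
#' Name field is `sample;cn=C`; score is `round(1000 * quality)`.
#'
#' @param calls `cnv_calls`.
#' @param path file path.
#' @export
write_cnv_bed <- function(calls, path) {
  ff <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- data.frame(calls$chrom, ff(calls$start_bp - 1), ff(calls$end_bp),
                    sprintf("%s;cn=%d", calls$sample_id, calls$copy_number),
                    round(1000 * calls$quality))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.calls_gr <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start_bp, calls$end_bp))
}
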