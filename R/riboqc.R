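# Ribosome-profiling quality control: read-length filters, 3-nt
# periodicity, and RNA-Ribo sample concordance.

length_filter <- function(reads, min, max) {
  if (min > max) stop_invalid("min length exceeds max length")
  lens <- if (is.data.frame(reads)) reads$length else reads
  keep <- lens >= min & lens <= max
  out <- if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
  if (is.data.frame(reads)) attr(out, "cds_start") <- attr(reads, "cds_start")
  attr(out, "filter_report") <- c(input = length(lens), kept = sum(keep),
                                  removed = sum(!keep))
  if (sum(keep) == 0L && length(lens) > 0L) {
    warning("no reads left after length filter [", min, ", ", max, "]")
  }
  out
}

#' Filter reads by length (inclusive bounds)
#'
#' Retains reads with `min <= length <= max`; both bounds inclusive. The
#' default window `[20, 50]` is the post-trimming length filter; a count
#' report is attached as attribute `"filter_report"`.
#'
#' @param reads data.frame of read records with a `length` column, or a
#'   numeric length vector.
#' @param min,max inclusive bounds in nt.
#' @return filtered reads of the same shape as the input.
#' @export
filter_reads_by_length <- function(reads, min = 20L, max = 50L) {
  length_filter(reads, min, max)
}

#' Select ribosome-protected fragments by length
#'
#' RPF selection window `[30, 40]` nt, inclusive; idempotent.
#'
#' @inheritParams filter_reads_by_length
#' @export
select_rpf <- function(reads, min = 30L, max = 40L) {
  length_filter(reads, min, max)
}

#' Reading-frame periodicity of read 5' ends
#'
#' The frame of a read is `(pos5 - cds_start) mod 3`, computed from raw 5'
#' ends without P-site offsetting. A good Ribo-seq library shows a strong
#' frame-0 excess (3-nt periodicity).
#'
#' @param reads data.frame with a `pos5` column (a `cds_start` attribute, if
#'   present, supplies the default CDS start).
#' @param cds_start 1-based CDS start on the transcript.
#' @return a `periodicity_profile`: `frame_fractions` (f0, f1, f2, summing
#'   to 1) and `n_reads`. Zero reads give an `NA` profile with a warning.
#' @export
compute_periodicity <- function(reads, cds_start = NULL) {
  cds_start <- cds_start %||% attr(reads, "cds_start") %||% 1L
  pos5 <- reads$pos5
  n <- length(pos5)
  if (n == 0L) {
    warning("no reads: periodicity undefined")
    return(structure(list(frame_fractions = rep(NA_real_, 3), n_reads = 0L),
                     class = "periodicity_profile"))
  }
  frame <- (pos5 - cds_start) %% 3L
  fr <- tabulate(frame + 1L, nbins = 3L) / n
  structure(list(frame_fractions = stats::setNames(fr, c("f0", "f1", "f2")),
                 n_reads = n),
            class = "periodicity_profile")
}

#' @export
print.periodicity_profile <- function(x, ...) {
  cat(sprintf("<periodicity_profile> n=%d, frames %.3f / %.3f / %.3f\n",
              x$n_reads, x$frame_fractions[1], x$frame_fractions[2],
              x$frame_fractions[3]))
  invisible(x)
}

#' Between-sample expression concordance
#'
#' Spearman rank correlation (average ranks for ties) of two per-gene
#' expression vectors, plus the ordinary least-squares R-squared of their
#' log-scale values (pairs where either value is non-positive are dropped
#' from the R-squared, which is computed on `log2`).
#'
#' @param expr_a,expr_b paired per-gene expression values, n >= 3.
#' @return list with `spearman_rho`, `r_squared`, `n`, `n_log`.
#' @export
sample_correlation <- function(expr_a, expr_b) {
  keep <- is.finite(expr_a) & is.finite(expr_b)
  a <- expr_a[keep]; b <- expr_b[keep]
  if (length(a) < 3L) stop_invalid("need >= 3 paired finite values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: correlation undefined")
    return(list(spearman_rho = NA_real_, r_squared = NA_real_,
                n = length(a), n_log = 0L))
  }
  rho <- stats::cor(a, b, method = "spearman")
  pos <- a > 0 & b > 0
  r2 <- if (sum(pos) >= 3L) {
    la <- log2(a[pos]); lb <- log2(b[pos])
    if (stats::sd(la) == 0) NA_real_ else stats::cor(la, lb)^2
  } else NA_real_
  list(spearman_rho = rho, r_squared = r2, n = length(a), n_log = sum(pos))
}
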