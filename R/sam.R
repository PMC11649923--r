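# Minimal SAM handling. Rsamtools only reads BAM, and RiboMeth-seq end
# counting needs nothing beyond flag, reference, position and the reference
# span implied by the CIGAR, so a small text parser keeps the input path
# plain-text end to end.

FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

# Reference bases consumed by a CIGAR string (M/D/N/=/X); soft clips, insertions
# and hard clips consume none.
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (sum(nchar(ops)) != nchar(cg)) stop_invalid("malformed CIGAR: ", cg)
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignment records from a SAM file
#'
#' Parses the mandatory SAM columns and derives, per record, the leftmost and
#' rightmost aligned reference positions (soft-clipped bases ignored, as they
#' consume no reference) plus flag-based status columns.
#'
#' @param path SAM file path.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `start`, `end`, `reverse`, `usable` (mapped, primary,
#'   non-supplementary).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), start = integer(), end = integer(),
                      reverse = logical(), usable = logical()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0) {
    stop_invalid("SAM record with fewer than 11 fields at data line ", short[1])
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  aln <- data.frame(
    qname = getf(1), flag = as.integer(getf(2)), rname = getf(3),
    pos = as.integer(getf(4)), mapq = as.integer(getf(5)), cigar = getf(6),
    stringsAsFactors = FALSE
  )
  span <- cigar_ref_span(aln$cigar)
  aln$start <- aln$pos
  aln$end <- aln$pos + span - 1L
  aln$reverse <- bitwAnd(aln$flag, FLAG_REVERSE) != 0L
  aln$usable <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(aln$flag, FLAG_SECONDARY) == 0L &
    bitwAnd(aln$flag, FLAG_SUPPLEMENTARY) == 0L &
    aln$rname != "*"
  aln
}

#' Count read ends per reference position
#'
#' Tallies, for every position of the reference, the number of usable
#' alignments (mapped, primary, non-supplementary) whose chosen end falls
#' there. By default reads are assumed sense-stranded to the rRNA, so the
#' 5' end is the leftmost aligned base and the 3' end the rightmost; with
#' `strand_aware = TRUE` reverse-strand alignments have the two swapped.
#'
#' @param alignments data.frame as returned by [read_sam()].
#' @param reference an [rrna_reference()].
#' @param end `"5p"` or `"3p"`.
#' @param strand_aware honour the reverse-strand flag (default `FALSE`:
#'   reads assumed sense-stranded).
#' @param condition,replicate labels stored on the resulting profile.
#' @return an `end_count_profile`.
#' @examples
#' ref <- rrna_reference("toy", strrep("ACGU", 10))
#' aln <- data.frame(qname = c("r1", "r2", "r3"), flag = 0L,
#'                   rname = "toy", pos = c(5L, 5L, 7L), mapq = 60L,
#'                   cigar = c("16M", "14M", "14M"))
#' aln <- within(aln, {
#'   start <- pos; end <- pos + c(16L, 14L, 14L) - 1L
#'   reverse <- FALSE; usable <- TRUE
#' })
#' count_read_ends(aln, ref, end = "5p")$counts[5]  # 2
#' @export
count_read_ends <- function(alignments, reference, end = c("5p", "3p"),
                            strand_aware = FALSE,
                            condition = "NA", replicate = "NA") {
  end <- match.arg(end)
  stopifnot(inherits(reference, "rrna_reference"))
  usable <- alignments[alignments$usable, , drop = FALSE]
  bad <- which(usable$rname != reference$name)
  if (length(bad) > 0) {
    stop_invalid("alignment of read '", usable$qname[bad[1]],
                 "' maps to unknown reference '", usable$rname[bad[1]],
                 "' (expected '", reference$name, "')")
  }
  if (nrow(usable) > 0) {
    left <- usable$start
    right <- usable$end
    flip <- if (strand_aware) usable$reverse else rep(FALSE, nrow(usable))
    p <- if (end == "5p") ifelse(flip, right, left) else ifelse(flip, left, right)
    if (any(p < 1L | p > reference$length)) {
      stop_invalid("alignment extends outside the reference (length ",
                   reference$length, ")")
    }
    counts <- tabulate(p, nbins = reference$length)
  } else {
    counts <- integer(reference$length)
  }
  prof <- new_end_count_profile(reference$name, end, counts, condition, replicate)
  attr(prof, "n_used") <- nrow(usable)
  prof
}
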