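# Cross-species rRNA site conservation: global alignment, coordinate
# projection, and conserved/unique labelling of called Nm sites.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch / Gotoh global alignment. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`. `U` and `T` are treated as identical
#' for scoring. Traceback tie-breaking is fixed (diagonal, then up, then
#' left) so alignments are reproducible.
#'
#' Default scores (match +2, mismatch -1, gap open -5, gap extend -1) are a
#' reasonable heuristic for closely structured rRNA sequences.
#'
#' @param a,b nucleotide sequences (character strings) over `A/C/G/U/T`.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return a `pairwise_alignment`: equal-length gapped strings `aligned_a`,
#'   `aligned_b`, the optimal `score`, and `params`.
#' @examples
#' aln <- global_align("ACGU", "ACGU")
#' aln$score  # 8 with default scoring
#' @export
global_align <- function(a, b, match = 2, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop_invalid("sequences must be non-empty")
  validate_nt(a, "sequence a"); validate_nt(b, "sequence b")
  au <- chartr("u", "U", a); bu <- chartr("u", "U", b)
  norm <- function(s) chartr("U", "T", toupper(s))  # U === T for scoring
  res <- .nw_align_cpp(norm(a), norm(b), match, mismatch, gap_open, gap_extend)
  # restore the original residue spelling in the gapped strings
  restore <- function(gapped, original) {
    g <- strsplit(gapped, "", fixed = TRUE)[[1]]
    o <- strsplit(toupper(original), "", fixed = TRUE)[[1]]
    g[g != "-"] <- o
    paste(g, collapse = "")
  }
  structure(list(aligned_a = restore(res$aligned_a, au),
                 aligned_b = restore(res$aligned_b, bu),
                 score = res$score,
                 params = c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> length %d, score %g\n",
              nchar(x$aligned_a), x$score))
  invisible(x)
}

#' Rescore a gapped alignment under the affine gap model
#'
#' Recomputes the score of an existing alignment directly from its gapped
#' strings; used to verify the invariant that a `pairwise_alignment`'s score
#' equals its own recomputation.
#'
#' @param aln a `pairwise_alignment`.
#' @return numeric score.
#' @export
score_alignment <- function(aln) {
  p <- aln$params
  ca <- strsplit(chartr("U", "T", toupper(aln$aligned_a)), "")[[1]]
  cb <- strsplit(chartr("U", "T", toupper(aln$aligned_b)), "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0; last <- "none"
  for (k in seq_along(ca)) {
    if (ca[k] == "-" && cb[k] == "-") stop_invalid("double-gap column")
    if (ca[k] == "-" || cb[k] == "-") {
      cur <- if (ca[k] == "-") "ga" else "gb"
      s <- s + if (identical(last, cur)) p[["gap_extend"]] else p[["gap_open"]]
      last <- cur
    } else {
      s <- s + if (ca[k] == cb[k]) p[["match"]] else p[["mismatch"]]
      last <- "none"
    }
  }
  s
}

#' Matched-coordinate projection of an alignment
#'
#' One entry per aligned column where neither sequence has a gap, giving the
#' 1-based coordinates in each sequence and whether the residues are
#' identical (`U` and `T` count as identical).
#'
#' @param aln a `pairwise_alignment`.
#' @return data.frame with columns `i`, `j`, `identical`; `i` and `j` are
#'   strictly increasing.
#' @export
map_positions <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  i <- cumsum(ca != "-")
  j <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  na <- chartr("U", "T", toupper(ca)); nb <- chartr("U", "T", toupper(cb))
  data.frame(i = i[keep], j = j[keep], identical = (na == nb)[keep])
}

#' Read a known-site annotation table
#'
#' Comma-separated annotation of known Nm sites in other species, with
#' columns `species`, `molecule`, `position`, `base`, `source` (extra
#' columns tolerated, `label` recognised).
#'
#' @param path CSV path.
#' @return data.frame of known sites.
#' @export
read_known_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("molecule", "position")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_invalid("known-site table lacks column(s): ",
                 paste(missing, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df
}

#' Label called sites as conserved, unique or unmapped
#'
#' Two modes share one contract: every site receives exactly one status in
#' `conserved` / `unique` / `unmapped`.
#'
#' Map mode (`map` supplied): a site is `unmapped` when its position falls
#' in a gap column of the alignment; otherwise it is `conserved` when its
#' projected counterpart position appears in `known` (positions in the other
#' species' coordinates; optionally also requiring identical bases), else
#' `unique`.
#'
#' List mode (`map = NULL`): `known` is a pre-resolved list of conserved
#' site labels (or positions) in the *same* coordinates as the calls; a site
#' is `conserved` iff it appears in the list, else `unique`. This supports
#' working directly from published per-species site lists.
#'
#' @param sites data.frame of site calls (needs `position`; `label` and
#'   `molecule` used when present).
#' @param known integer positions (map mode) or character labels / integer
#'   positions (list mode).
#' @param map optional [map_positions()] data.frame for map mode.
#' @param require_identical_base in map mode, additionally require the
#'   aligned column to be identical.
#' @return the `sites` data.frame with `status` and `counterpart` columns.
#' @export
classify_conservation <- function(sites, known, map = NULL,
                                  require_identical_base = FALSE) {
  out <- sites
  if (is.null(map)) {
    key <- if (is.character(known) && !is.null(sites$label)) sites$label
           else sites$position
    out$status <- ifelse(key %in% known, "conserved", "unique")
    out$counterpart <- NA_integer_
  } else {
    idx <- match(sites$position, map$i)
    counterpart <- map$j[idx]
    ident <- map$identical[idx]
    status <- rep("unique", nrow(sites))
    status[is.na(idx)] <- "unmapped"
    hit <- !is.na(counterpart) & counterpart %in% as.integer(known)
    if (require_identical_base) hit <- hit & !is.na(ident) & ident
    status[hit] <- "conserved"
    out$status <- status
    out$counterpart <- counterpart
  }
  out
}
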