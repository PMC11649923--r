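# Methscore computation and site classification.
#
# The Methscore at a position compares its read-end count with the mean of
# the six preceding and six succeeding positions: M = max(0, 1 - c / mean).
# A 2'-O-methyl on residue j blocks cleavage of the bond 3' of j, so the
# count deficit appears at read-5'-end position j+1 and read-3'-end position
# j; tracks are shifted onto site coordinates accordingly before the two
# ends are intersected into a consensus call set.

#' Compute the Methscore track for one end-count profile
#'
#' For a deficit position q with count `c_q`, the raw score is
#' `1 - c_q / mean(c over q-w..q-1, q+1..q+w)`; negative values are clamped
#' to 0 for reporting (the score estimates a methylated fraction) and the
#' unclamped value is retained in `raw` for differential testing. Scores are
#' undefined (`NA`) within `w` positions of either terminus and wherever the
#' flanking mean falls below `min_neighbor_mean`.
#'
#' With `shift = TRUE` (default) the track is moved onto site coordinates:
#' for a 5p profile, site j takes the score at deficit position q = j + 1;
#' for a 3p profile, q = j.
#'
#' @param profile an `end_count_profile`.
#' @param w flank half-width in positions (default 6).
#' @param min_neighbor_mean minimum flanking mean count for a defined score
#'   (default 10; guards division by near-zero coverage).
#' @param shift shift from deficit coordinates onto site coordinates.
#' @return a `methscore_track`: molecule/end/condition/replicate labels plus
#'   numeric vectors `score` (clamped) and `raw`, indexed 1..L.
#' @export
compute_methscore <- function(profile, w = 6L, min_neighbor_mean = 10,
                              shift = TRUE) {
  stopifnot(inherits(profile, "end_count_profile"))
  w <- as.integer(w)
  L <- length(profile$counts)
  if (L <= 2L * w) stop_invalid("profile length ", L, " must exceed 2*w = ", 2 * w)
  cnt <- as.numeric(profile$counts)
  cs <- cumsum(c(0, cnt))
  q <- seq_len(L)
  lo <- q - w; hi <- q + w
  valid <- lo >= 1L & hi <= L
  nb_sum <- rep(NA_real_, L)
  nb_sum[valid] <- cs[hi[valid] + 1L] - cs[lo[valid]] - cnt[valid]
  nb_mean <- nb_sum / (2 * w)
  raw <- 1 - cnt / nb_mean
  raw[!valid | nb_mean < min_neighbor_mean] <- NA_real_
  score <- pmax(raw, 0)
  if (shift) {
    if (profile$end == "5p") {
      # site j <- deficit position j + 1
      raw <- c(raw[-1L], NA_real_)
      score <- c(score[-1L], NA_real_)
    }
    # 3p: deficit position equals the site position already
  }
  structure(list(molecule = profile$molecule, end = profile$end,
                 condition = profile$condition, replicate = profile$replicate,
                 w = w, min_neighbor_mean = min_neighbor_mean,
                 shifted = shift, score = score, raw = raw),
            class = "methscore_track")
}

#' @export
print.methscore_track <- function(x, ...) {
  cat(sprintf("<methscore_track> %s %s %s/%s: L=%d, defined=%d, w=%d\n",
              x$molecule, x$end, x$condition, x$replicate,
              length(x$score), sum(!is.na(x$score)), x$w))
  invisible(x)
}

#' Average Methscore tracks across replicates
#'
#' Per-condition site discovery uses the mean Methscore across replicates of
#' one end; the per-replicate tracks are kept separately for differential
#' testing.
#'
#' @param tracks list of `methscore_track` objects for one molecule and end.
#' @return a `methscore_track` with `replicate = "mean"`; both `score` and
#'   `raw` are position-wise means over replicates with defined values.
#' @export
mean_methscore_track <- function(tracks) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "methscore_track")))
  mol <- unique(vapply(tracks, `[[`, character(1), "molecule"))
  end <- unique(vapply(tracks, `[[`, character(1), "end"))
  if (length(mol) != 1L || length(end) != 1L) {
    stop_invalid("tracks to average must share molecule and end")
  }
  sc <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "score")), na.rm = TRUE)
  rw <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "raw")), na.rm = TRUE)
  sc[is.nan(sc)] <- NA_real_; rw[is.nan(rw)] <- NA_real_
  out <- tracks[[1]]
  out$score <- sc; out$raw <- rw
  out$replicate <- "mean"
  out$condition <- unique(vapply(tracks, `[[`, character(1), "condition"))[1]
  out
}

#' Classify methylation sites from a Methscore track
#'
#' Thresholds follow the strict convention of the calling scheme:
#' fully methylated for `theta_full < M < 1`, partially methylated for
#' `theta_part <= M <= theta_full`, and `flagged` for `M == 1` exactly --
#' a score of exactly 1 means a zero observed count, which warrants manual
#' review rather than a silent full call.
#'
#' @param track a `methscore_track` in site coordinates.
#' @param reference the matching [rrna_reference()] (for site labels).
#' @param theta_full,theta_part classification thresholds (defaults 0.85
#'   and 0.65).
#' @param keep_none also return positions classified `none` (default drops
#'   them, leaving only called sites).
#' @return data.frame of site calls: `molecule`, `position`, `base`, `label`,
#'   `methscore`, `class`.
#' @export
classify_sites <- function(track, reference, theta_full = 0.85,
                           theta_part = 0.65, keep_none = FALSE) {
  stopifnot(inherits(track, "methscore_track"),
            inherits(reference, "rrna_reference"))
  if (!isTRUE(track$shifted)) {
    stop_invalid("track must be in site coordinates (computed with shift = TRUE)")
  }
  if (track$molecule != reference$name) {
    stop_invalid("track molecule '", track$molecule,
                 "' does not match reference '", reference$name, "'")
  }
  if (theta_part >= theta_full) stop_invalid("theta_part must be < theta_full")
  m <- track$score
  pos <- which(!is.na(m))
  cls <- rep("none", length(pos))
  v <- m[pos]
  cls[v >= theta_part & v <= theta_full] <- "partial"
  cls[v > theta_full & v < 1] <- "full"
  cls[v == 1] <- "flagged"
  calls <- data.frame(
    molecule = track$molecule,
    position = pos,
    base = sub("m.*$", "", name_site(pos, reference)),
    label = name_site(pos, reference),
    methscore = v,
    class = cls,
    stringsAsFactors = FALSE
  )
  if (!keep_none) calls <- calls[calls$class != "none", , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Two-end consensus of site calls
#'
#' The consensus set consists of positions called full or partial in both
#' the 5p-derived and 3p-derived call sets; the consensus class is the
#' weaker of the two (partial if either end says partial) and the consensus
#' Methscore is the mean of the two ends. `flagged` calls (M = 1) are not
#' eligible for consensus.
#'
#' @param calls_5p,calls_3p call data.frames from [classify_sites()] for the
#'   same molecule and condition.
#' @return data.frame of consensus calls with per-end scores retained in
#'   `methscore_5p` / `methscore_3p`.
#' @export
intersect_end_calls <- function(calls_5p, calls_3p) {
  mols <- unique(c(calls_5p$molecule, calls_3p$molecule))
  if (length(mols) > 1L) {
    stop_invalid("call sets come from different molecules: ",
                 paste(mols, collapse = ", "))
  }
  a <- calls_5p[calls_5p$class %in% c("full", "partial"), , drop = FALSE]
  b <- calls_3p[calls_3p$class %in% c("full", "partial"), , drop = FALSE]
  common <- intersect(a$position, b$position)
  a <- a[match(common, a$position), , drop = FALSE]
  b <- b[match(common, b$position), , drop = FALSE]
  cls <- ifelse(a$class == "partial" | b$class == "partial", "partial", "full")
  out <- data.frame(
    molecule = a$molecule, position = common, base = a$base, label = a$label,
    methscore = (a$methscore + b$methscore) / 2,
    class = cls,
    methscore_5p = a$methscore, methscore_3p = b$methscore,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end consensus site calling for one condition
#'
#' Convenience wrapper: computes per-replicate Methscore tracks from
#' end-count profiles, averages them per end, classifies each end's mean
#' track and intersects the two ends.
#'
#' @param profiles list of `end_count_profile`s (both ends, all replicates of
#'   one condition).
#' @param reference matching [rrna_reference()].
#' @inheritParams compute_methscore
#' @inheritParams classify_sites
#' @return list with `calls` (consensus data.frame), `calls_5p`, `calls_3p`,
#'   and `tracks` (per-replicate `methscore_track`s, keyed `end.replicate`).
#' @export
call_consensus_sites <- function(profiles, reference, w = 6L,
                                 min_neighbor_mean = 10, theta_full = 0.85,
                                 theta_part = 0.65) {
  stopifnot(length(profiles) > 0)
  tracks <- lapply(profiles, compute_methscore, w = w,
                   min_neighbor_mean = min_neighbor_mean)
  names(tracks) <- vapply(tracks, function(t) paste(t$end, t$replicate, sep = "."),
                          character(1))
  ends <- vapply(tracks, `[[`, character(1), "end")
  if (!all(c("5p", "3p") %in% ends)) {
    stop_invalid("consensus calling needs both 5p and 3p profiles")
  }
  calls_by_end <- lapply(c("5p", "3p"), function(e) {
    classify_sites(mean_methscore_track(tracks[ends == e]), reference,
                   theta_full = theta_full, theta_part = theta_part)
  })
  list(calls = intersect_end_calls(calls_by_end[[1]], calls_by_end[[2]]),
       calls_5p = calls_by_end[[1]], calls_3p = calls_by_end[[2]],
       tracks = tracks)
}
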