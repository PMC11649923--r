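# Readers and writers. Dialects are pinned: tab-separated for matrices and
# tracks, comma-separated for annotation tables, UTF-8, Unix newlines,
# mandatory header row. bedGraph is 0-based half-open (the standard);
# internal coordinates are 1-based inclusive, converted in one place.

#' Read rRNA references from a FASTA file
#'
#' Sequences are uppercased; `U` vs `T` is preserved as read. A light
#' pre-validation pass reports malformed headers or empty records with line
#' numbers; the actual parse is delegated to Biostrings.
#'
#' @param path FASTA path.
#' @return named list of [rrna_reference()] objects.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop_invalid("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    stop_invalid("malformed FASTA: expected '>' header at line ", first)
  }
  headers <- which(startsWith(lines, ">"))
  ends <- c(headers[-1] - 1L, length(lines))
  for (k in seq_along(headers)) {
    body <- lines[setdiff(seq(headers[k] + 1L, ends[k]), headers)]
    if (headers[k] == ends[k] || !any(nzchar(trimws(body)))) {
      stop_invalid("empty sequence for header at line ", headers[k])
    }
  }
  set <- Biostrings::readBStringSet(path)
  refs <- lapply(seq_along(set), function(i) {
    nm <- strsplit(names(set)[i], "\\s+")[[1]][1]
    rrna_reference(nm, toupper(as.character(set[[i]])))
  })
  names(refs) <- vapply(refs, `[[`, character(1), "name")
  refs
}

#' Write references to FASTA
#'
#' @param references list of [rrna_reference()] (or a single one).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(references, path, width = 70L) {
  if (inherits(references, "rrna_reference")) references <- list(references)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (ref in references) {
    starts <- seq(1L, ref$length, by = width)
    chunk <- substring(ref$sequence, starts, pmin(starts + width - 1L, ref$length))
    writeLines(c(paste0(">", ref$name), chunk), con, sep = "\n")
  }
  invisible(path)
}

#' Write end-count profiles to TSV
#'
#' Four required columns (`molecule`, `position`, `end`, `count`) plus the
#' `condition` and `replicate` labels. Zero-count positions are omitted
#' (the reader restores them).
#'
#' @param profiles list of `end_count_profile`s.
#' @param path output TSV path.
#' @param keep_zeros also write zero-count rows.
#' @export
write_end_counts <- function(profiles, path, keep_zeros = FALSE) {
  if (inherits(profiles, "end_count_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    idx <- if (keep_zeros) seq_along(p$counts) else which(p$counts > 0L)
    data.frame(molecule = p$molecule, position = idx, end = p$end,
               count = p$counts[idx], condition = p$condition,
               replicate = p$replicate, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read end-count profiles from TSV
#'
#' Expects the dialect of [write_end_counts()]; missing positions are filled
#' with zeros, positions are validated against the reference length, and
#' duplicated `(molecule, end, condition, replicate, position)` rows are
#' summed with a warning.
#'
#' @param path TSV path.
#' @param references named list of [rrna_reference()]s (from [read_fasta()]).
#' @return list of `end_count_profile`s.
#' @export
read_end_counts <- function(path, references) {
  if (inherits(references, "rrna_reference")) {
    references <- stats::setNames(list(references), references$name)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("molecule", "position", "end", "count")
  if (!all(needed %in% names(df))) {
    stop_invalid("end-count TSV needs columns: ", paste(needed, collapse = ", "))
  }
  if (!"condition" %in% names(df)) df$condition <- "NA"
  if (!"replicate" %in% names(df)) df$replicate <- "NA"
  bad_end <- setdiff(unique(df$end), c("5p", "3p"))
  if (length(bad_end) > 0) {
    stop_invalid("unknown end token(s): ", paste(bad_end, collapse = ", "))
  }
  bad_mol <- setdiff(unique(df$molecule), names(references))
  if (length(bad_mol) > 0) {
    stop_invalid("unknown molecule(s): ", paste(bad_mol, collapse = ", "))
  }
  keys <- unique(df[, c("molecule", "end", "condition", "replicate")])
  profiles <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sel <- df$molecule == keys$molecule[k] & df$end == keys$end[k] &
      df$condition == keys$condition[k] & df$replicate == keys$replicate[k]
    sub <- df[sel, , drop = FALSE]
    L <- references[[keys$molecule[k]]]$length
    if (any(sub$position < 1L | sub$position > L)) {
      stop_invalid("position outside [1, ", L, "] for molecule ",
                   keys$molecule[k])
    }
    if (anyDuplicated(sub$position)) {
      warning("duplicate rows for ", keys$molecule[k], " ", keys$end[k],
              ": counts summed")
    }
    counts <- integer(L)
    agg <- tapply(sub$count, sub$position, sum)
    counts[as.integer(names(agg))] <- as.integer(agg)
    profiles[[k]] <- new_end_count_profile(keys$molecule[k], keys$end[k],
                                           counts, keys$condition[k],
                                           keys$replicate[k])
  }
  profiles
}

#' Write one end-count track as bedGraph
#'
#' Emits standard 0-based half-open intervals (internal 1-based position p
#' becomes `[p-1, p)`), one merged line per run of equal counts; zero-count
#' runs are skipped.
#'
#' @param profile an `end_count_profile`.
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  cnt <- profile$counts
  r <- rle(cnt)
  stop_pos <- cumsum(r$lengths)
  start_pos <- stop_pos - r$lengths + 1L
  keep <- r$values > 0L
  lines <- sprintf("%s\t%d\t%d\t%d", profile$molecule,
                   start_pos[keep] - 1L, stop_pos[keep], r$values[keep])
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a bedGraph coverage track into an end-count profile
#'
#' @param path bedGraph path (0-based half-open intervals).
#' @param reference the [rrna_reference()] the track belongs to.
#' @param end `"5p"` or `"3p"`.
#' @param condition,replicate labels for the resulting profile.
#' @export
read_bedgraph <- function(path, reference, end, condition = "NA",
                          replicate = "NA") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  counts <- integer(reference$length)
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      start0 <- as.integer(p[2]); end0 <- as.integer(p[3])
      val <- as.numeric(p[4])
      if (end0 > reference$length) {
        stop_invalid("bedGraph interval ends at ", end0,
                     " beyond reference length ", reference$length)
      }
      counts[(start0 + 1L):end0] <- counts[(start0 + 1L):end0] + as.integer(val)
    }
  }
  new_end_count_profile(reference$name, end, counts, condition, replicate)
}

#' Write Methscore tracks to TSV
#'
#' Columns: molecule, position, end, score, raw, condition, replicate.
#' Undefined positions are written with empty score fields.
#'
#' @param tracks list of `methscore_track`s (or one).
#' @param path output path.
#' @export
write_methscore_tracks <- function(tracks, path) {
  if (inherits(tracks, "methscore_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(t) {
    data.frame(molecule = t$molecule, position = seq_along(t$score),
               end = t$end, score = t$score, raw = t$raw,
               condition = t$condition, replicate = t$replicate,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read Methscore tracks written by [write_methscore_tracks()]
#'
#' @param path TSV path.
#' @param w,min_neighbor_mean parameter values recorded on the rebuilt
#'   tracks (the file does not carry them).
#' @return list of `methscore_track`s.
#' @export
read_methscore_tracks <- function(path, w = 6L, min_neighbor_mean = 10) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("molecule", "end", "condition", "replicate")])
  lapply(seq_len(nrow(keys)), function(k) {
    sel <- df$molecule == keys$molecule[k] & df$end == keys$end[k] &
      df$condition == keys$condition[k] & df$replicate == keys$replicate[k]
    sub <- df[sel, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    structure(list(molecule = keys$molecule[k], end = keys$end[k],
                   condition = keys$condition[k],
                   replicate = keys$replicate[k], w = as.integer(w),
                   min_neighbor_mean = min_neighbor_mean, shifted = TRUE,
                   score = sub$score, raw = sub$raw),
              class = "methscore_track")
  })
}

#' Write site calls to CSV
#' @param calls data.frame from [classify_sites()] or [intersect_end_calls()].
#' @param path output CSV path.
#' @export
write_site_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site calls written by [write_site_calls()]
#' @param path CSV path.
#' @export
read_site_calls <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write simulator ground truth to CSV
#' @param truth a `meth_truth`.
#' @param path output CSV path.
#' @export
write_truth <- function(truth, path) {
  df <- truth$sites
  df <- cbind(molecule = truth$molecule, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV plus a sample-metadata sidecar CSV
#'
#' The TSV carries `gene`, `length`, then one column per sample; the CSV
#' carries `sample`, `condition`, `replicate`, `assay`.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,meta_path output paths.
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  df <- data.frame(gene = rownames(cm$counts),
                   length = as.integer(cm$lengths), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  utils::write.csv(cm$samples, meta_path, row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param counts_path,meta_path paths to the TSV and sidecar CSV.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, meta$sample, drop = FALSE])
  rownames(counts) <- df$gene
  storage.mode(counts) <- "integer"
  count_matrix(counts, lengths = stats::setNames(df$length, df$gene),
               samples = meta)
}
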