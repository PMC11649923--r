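#' rRNA reference sequence
#'
#' Container for a mature rRNA molecule (e.g., 18S or 28S) used as the
#' coordinate system for end counting and Methscore calling. Coordinates are
#' 1-based and inclusive throughout the package; the 28S molecule is treated
#' as one contiguous reference (the planarian hidden break is not modelled).
#'
#' @param name molecule identifier, e.g. `"18S"`.
#' @param sequence nucleotide string over `A`, `C`, `G`, `U`/`T`
#'   (case-insensitive; stored uppercased as supplied).
#' @return An object of class `rrna_reference` with fields `name`,
#'   `sequence` and `length`.
#' @examples
#' ref <- rrna_reference("toy", "ACGUACGUAC")
#' ref$length
#' @export
rrna_reference <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop_invalid("empty sequence for reference '", name, "'")
  validate_nt(sequence, what = paste0("reference '", name, "'"))
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "rrna_reference"
  )
}

#' @export
print.rrna_reference <- function(x, ...) {
  cat(sprintf("<rrna_reference> %s (%d nt)\n", x$name, x$length))
  invisible(x)
}

ref_bases <- function(reference) {
  strsplit(reference$sequence, "", fixed = TRUE)[[1]]
}

#' Name an Nm site by base and position
#'
#' Builds the conventional 2'-O-methylation site label: the nucleotide letter
#' (with `T` reported as `U`, since sites live on RNA), `"m"`, then the
#' 1-based position -- e.g. `Am28` for a methylated adenosine at position 28.
#'
#' @param position 1-based position(s) on the reference.
#' @param reference an [rrna_reference()].
#' @return character vector of site labels.
#' @examples
#' ref <- rrna_reference("18S", strrep("A", 30))
#' name_site(28, ref)  # "Am28"
#' @export
name_site <- function(position, reference) {
  stopifnot(inherits(reference, "rrna_reference"))
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > reference$length)) {
    stop_invalid("position out of range [1, ", reference$length, "]")
  }
  base <- ref_bases(reference)[position]
  base[base == "T"] <- "U"
  paste0(base, "m", position)
}
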