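# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Benjamini-Hochberg adjustment tolerant of NA entries.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

validate_nt <- function(sequence, what = "sequence") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "U"))
  if (length(bad) > 0) {
    stop_invalid(sprintf("invalid nucleotide symbol(s) in %s: %s",
                         what, paste(bad, collapse = ", ")))
  }
  invisible(chars)
}
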