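# Independent oracles and in-code fixtures shared across test files.

# Brute-force Methscore recomputation straight from the definition:
# explicit loops, no cumulative sums, deficit coordinates (unshifted).
oracle_methscore <- function(counts, w = 6L, min_neighbor_mean = 10) {
  L <- length(counts)
  out <- rep(NA_real_, L)
  for (q in seq_len(L)) {
    if (q - w < 1L || q + w > L) next
    nb <- counts[c((q - w):(q - 1L), (q + 1L):(q + w))]
    m <- mean(nb)
    if (m < min_neighbor_mean) next
    out[q] <- max(0, 1 - counts[q] / m)
  }
  out
}

# Exhaustive enumeration of global alignments in pure R (used both directly
# on tiny cases and to validate the compiled enumeration oracle once).
# Affine gap: a run of k gapped columns costs gap_open + (k-1)*gap_extend.
r_enum_align <- function(a, b, match, mismatch, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(ca)) {
      g <- if (last == 1L) gap_extend else gap_open
      best <- max(best, g + rec(i + 1L, j, 1L))
    }
    if (j <= length(cb)) {
      g <- if (last == 2L) gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, -1L)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Minimal SAM text builder: reads is a data.frame with qname, flag, pos, cigar.
write_sam_fixture <- function(reads, rname, rlen, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  reads$qname, reads$flag, rname, reads$pos, reads$cigar)
  writeLines(c(header, body), path, sep = "\n")
  path
}

# A small methylated world used by several tests.
make_world <- function(L = 400L, n_full = 4L, n_partial = 3L, depth = 200,
                       noise_cv = 0.2, replicates = 6L, seed = 7L,
                       f_full = c(0.95, 0.95), f_partial = c(0.75, 0.75)) {
  ref <- simulate_rrna_reference(L, 0.5, seed = seed)
  truth <- simulate_truth_sites(ref, n_full, n_partial, seed = seed + 1L,
                                f_full = f_full, f_partial = f_partial)
  profiles <- simulate_end_counts(
    ref, truth, rms_sim_config(depth, noise_cv, replicates, seed = seed + 2L))
  list(ref = ref, truth = truth, profiles = profiles)
}
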