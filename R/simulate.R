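# Synthetic-data generators with known ground truth.
#
# The RiboMeth-seq simulator follows the fragmentation chemistry only as far
# as the Methscore statistic can see it: alkaline hydrolysis cleaves each
# phosphodiester bond independently, a 2'-O-methyl on residue j protects the
# bond 3' of j, and sequencing recovers read 5'/3' ends at the two residues
# flanking each cleaved bond. Counts per bond are therefore independent
# Poisson draws whose rate is depth x noise x (1 - f), with f the methylated
# fraction of the protecting residue.

#' Simulate an rRNA reference sequence
#'
#' @param length sequence length in nt (>= 50).
#' @param gc target G+C fraction, strictly between 0 and 1.
#' @param seed integer RNG seed; the same seed reproduces the same sequence.
#' @param name molecule name for the resulting reference.
#' @return an [rrna_reference()] over the RNA alphabet `A/C/G/U`.
#' @examples
#' ref <- simulate_rrna_reference(100, gc = 0.5, seed = 1)
#' @export
simulate_rrna_reference <- function(length, gc = 0.5, seed = 1L, name = "rRNA_sim") {
  if (length < 50) stop_invalid("reference length must be >= 50 nt")
  if (gc <= 0 || gc >= 1) stop_invalid("gc must be strictly between 0 and 1")
  bases <- with_seed(seed, {
    sample(c("A", "U", "G", "C"), size = length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  })
  rrna_reference(name, paste(bases, collapse = ""))
}

#' Plant ground-truth methylation sites on a reference
#'
#' Places `n_full` fully and `n_partial` partially methylated sites, keeping
#' every site at least `2w + 1` nt away from the molecule ends (so its
#' Methscore neighbourhood is always defined) and at least 2 nt away from any
#' other site. Methylated fractions are drawn uniformly from `f_full` for
#' full sites and `f_partial` for partial sites.
#'
#' @param reference an [rrna_reference()].
#' @param n_full,n_partial numbers of fully / partially methylated sites.
#' @param seed integer RNG seed.
#' @param w Methscore flank width the placement margin is derived from.
#' @param f_full,f_partial length-2 ranges for the methylated fraction of
#'   full and partial sites.
#' @return a `meth_truth` object: `molecule` plus a data.frame `sites` with
#'   columns `position`, `f`, `class_label`.
#' @export
simulate_truth_sites <- function(reference, n_full, n_partial, seed = 1L,
                                 w = 6L, f_full = c(0.9, 1.0),
                                 f_partial = c(0.65, 0.85)) {
  stopifnot(inherits(reference, "rrna_reference"))
  n_full <- as.integer(n_full); n_partial <- as.integer(n_partial)
  stopifnot(n_full >= 0L, n_partial >= 0L)
  L <- reference$length
  n <- n_full + n_partial
  margin <- 2L * w + 1L
  candidates <- seq.int(margin + 1L, L - margin)
  if (n > L - 2L * w || length(candidates) < n) {
    stop_invalid(sprintf(
      "cannot place %d sites on a %d-nt molecule (margin %d nt): at most %d feasible",
      n, L, margin, max(0L, length(candidates))))
  }
  sites <- with_seed(seed, {
    pool <- sample(candidates)
    chosen <- integer(0)
    for (p in pool) {
      if (length(chosen) == n) break
      if (all(abs(chosen - p) >= 2L)) chosen <- c(chosen, p)
    }
    if (length(chosen) < n) {
      stop_invalid(sprintf(
        "requested %d sites but only %d placements satisfy the 2-nt spacing on L=%d",
        n, length(chosen), L))
    }
    f <- c(stats::runif(n_full, f_full[1], f_full[2]),
           stats::runif(n_partial, f_partial[1], f_partial[2]))
    data.frame(
      position = chosen,
      f = f,
      class_label = rep(c("full", "partial"), c(n_full, n_partial)),
      stringsAsFactors = FALSE
    )
  })
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(molecule = reference$name, sites = sites), class = "meth_truth")
}

#' @export
print.meth_truth <- function(x, ...) {
  cat(sprintf("<meth_truth> %s: %d sites (%d full, %d partial)\n",
              x$molecule, nrow(x$sites),
              sum(x$sites$class_label == "full"),
              sum(x$sites$class_label == "partial")))
  invisible(x)
}

#' RiboMeth-seq simulator configuration
#'
#' @param depth expected mean end count per cleavable bond (sequencing depth
#'   on the rRNA; free parameter of the simulator).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   per-position cleavage-bias factor (shared between the 5p and 3p tracks
#'   of a replicate). Default 0.2.
#' @param replicates biological replicates for the condition being simulated;
#'   the default design is 6 control vs 3 knockdown.
#' @param seed integer RNG seed.
#' @return an `rms_sim_config` list.
#' @export
rms_sim_config <- function(depth = 200, noise_cv = 0.2, replicates = 6L,
                           seed = 1L) {
  if (depth <= 0) stop_invalid("depth must be > 0")
  if (noise_cv < 0) stop_invalid("noise_cv must be >= 0")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop_invalid("replicates must be >= 1")
  structure(list(depth = depth, noise_cv = noise_cv,
                 replicates = replicates, seed = as.integer(seed)),
            class = "rms_sim_config")
}

new_end_count_profile <- function(molecule, end, counts, condition, replicate) {
  structure(list(molecule = molecule, end = end,
                 counts = as.integer(counts),
                 condition = condition, replicate = replicate),
            class = "end_count_profile")
}

#' @export
print.end_count_profile <- function(x, ...) {
  cat(sprintf("<end_count_profile> %s %s %s/%s: L=%d, total=%d\n",
              x$molecule, x$end, x$condition, x$replicate,
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Simulate RiboMeth-seq read-end count profiles
#'
#' For each replicate, each bond k (between residues k and k+1) is cleaved
#' with rate `depth * noise_rk * (1 - f_k)` where `f_k` is the methylated
#' fraction of residue k (0 if unmethylated, optionally shifted by
#' `condition_effects`). Counts are independent Poisson draws per end type;
#' a cleavage leaves a 5'-end at position k+1 and a 3'-end at position k.
#' The lognormal noise factor is drawn per replicate and position and shared
#' between the two end tracks, mimicking sequence-dependent cleavage bias.
#'
#' @param reference an [rrna_reference()].
#' @param truth a `meth_truth` from [simulate_truth_sites()].
#' @param cfg an [rms_sim_config()].
#' @param condition_effects optional named numeric vector of per-site changes
#'   in methylated fraction (names = positions); `f + delta` must stay in
#'   `[0, 1]`. Used to simulate knockdown conditions.
#' @param condition condition label stored on the profiles.
#' @return list of `end_count_profile` objects, two per replicate
#'   (ends `"5p"` and `"3p"`).
#' @export
simulate_end_counts <- function(reference, truth, cfg,
                                condition_effects = NULL,
                                condition = "control") {
  stopifnot(inherits(reference, "rrna_reference"),
            inherits(truth, "meth_truth"),
            inherits(cfg, "rms_sim_config"))
  if (truth$molecule != reference$name) {
    stop_invalid("truth molecule '", truth$molecule,
                 "' does not match reference '", reference$name, "'")
  }
  L <- reference$length
  f <- numeric(L)
  f[truth$sites$position] <- truth$sites$f
  if (!is.null(condition_effects)) {
    pos <- as.integer(names(condition_effects))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L)) {
      stop_invalid("condition_effects names must be positions in [1, L]")
    }
    f[pos] <- f[pos] + as.numeric(condition_effects)
    if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
      stop_invalid("condition_effects push a methylated fraction outside [0, 1]")
    }
    f <- pmin(pmax(f, 0), 1)
  }
  bonds <- seq_len(L - 1L)          # bond k sits 3' of residue k
  rate0 <- cfg$depth * (1 - f[bonds])
  with_seed(cfg$seed, {
    out <- vector("list", 2L * cfg$replicates)
    for (r in seq_len(cfg$replicates)) {
      noise <- rlnorm_cv(L - 1L, cfg$noise_cv)
      rate <- rate0 * noise
      c5 <- integer(L); c3 <- integer(L)
      c5[bonds + 1L] <- stats::rpois(L - 1L, rate)
      c3[bonds] <- stats::rpois(L - 1L, rate)
      rep_id <- paste0("rep", r)
      out[[2L * r - 1L]] <- new_end_count_profile(reference$name, "5p", c5,
                                                  condition, rep_id)
      out[[2L * r]] <- new_end_count_profile(reference$name, "3p", c3,
                                             condition, rep_id)
    }
    out
  })
}

#' Ground truth for the translation-efficiency simulator
#'
#' @param gene gene identifiers.
#' @param length transcript length in nt (>= 1).
#' @param baseline_mean expected count in the reference condition (> 0).
#' @param dispersion negative-binomial dispersion per gene (> 0; variance is
#'   `mu + dispersion * mu^2`).
#' @param log2fc_rna,log2fc_te planted condition effects on mRNA abundance
#'   and on translation efficiency (log2 scale).
#' @return a `te_sim_truth` object wrapping a per-gene data.frame.
#' @export
te_sim_truth <- function(gene, length, baseline_mean, dispersion,
                         log2fc_rna = 0, log2fc_te = 0) {
  n <- length(gene)
  genes <- data.frame(
    gene = as.character(gene),
    length = as.integer(rep_len(length, n)),
    baseline_mean = rep_len(baseline_mean, n),
    dispersion = rep_len(dispersion, n),
    log2fc_rna = rep_len(log2fc_rna, n),
    log2fc_te = rep_len(log2fc_te, n),
    stringsAsFactors = FALSE
  )
  if (any(genes$length < 1L)) stop_invalid("gene lengths must be >= 1")
  if (any(genes$baseline_mean <= 0)) stop_invalid("baseline means must be > 0")
  if (any(genes$dispersion <= 0)) stop_invalid("dispersions must be > 0")
  if (anyDuplicated(genes$gene)) stop_invalid("gene identifiers must be unique")
  structure(list(genes = genes), class = "te_sim_truth")
}

#' Convenience constructor: a gene universe with planted TE-down genes
#'
#' Builds a [te_sim_truth()] of `n_genes` genes, the first `n_te_down` of
#' which carry a translation-efficiency effect (`log2fc_te`, default -1.5)
#' with no mRNA change; the remainder are null genes.
#'
#' @param n_genes total genes; @param n_te_down planted TE-down genes.
#' @param log2fc_te planted TE effect for the affected genes.
#' @param baseline_mean,dispersion shared negative-binomial parameters.
#' @param length_range transcript-length range sampled uniformly.
#' @param seed RNG seed for the lengths.
#' @export
simulate_te_truth <- function(n_genes = 2000L, n_te_down = 100L,
                              log2fc_te = -1.5, baseline_mean = 500,
                              dispersion = 0.05,
                              length_range = c(500L, 5000L), seed = 1L) {
  stopifnot(n_te_down <= n_genes)
  lens <- with_seed(seed, sample(length_range[1]:length_range[2], n_genes,
                                 replace = TRUE))
  te_sim_truth(
    gene = sprintf("g%04d", seq_len(n_genes)),
    length = lens,
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    log2fc_rna = 0,
    log2fc_te = rep(c(log2fc_te, 0), c(n_te_down, n_genes - n_te_down))
  )
}

#' Simulate paired RPF and RNA count matrices
#'
#' Emulates the paired aliquot design: for each biological replicate one
#' RNA-seq and one Ribo-seq (RPF) library. RNA counts are negative binomial
#' with mean `baseline * 2^(log2fc_rna * cond)`; RPF counts with mean
#' `baseline * 2^((log2fc_rna + log2fc_te) * cond)`, where `cond` is 0 for
#' control and 1 for the treatment condition.
#'
#' @param truth a [te_sim_truth()].
#' @param replicates replicates per condition (>= 2; differential testing is
#'   impossible below that).
#' @param seed integer RNG seed.
#' @param conditions length-2 character vector: reference condition first.
#' @return list with `rpf` and `rna`, both [count_matrix()] objects.
#' @export
simulate_ribo_rna_counts <- function(truth, replicates = 3L, seed = 1L,
                                     conditions = c("control", "kd")) {
  stopifnot(inherits(truth, "te_sim_truth"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L) {
    stop_invalid("replicates must be >= 2 per condition")
  }
  g <- truth$genes
  n <- nrow(g)
  samples <- expand.grid(replicate = paste0("rep", seq_len(replicates)),
                         condition = conditions,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  size <- 1 / g$dispersion
  draw <- function(mu_matrix) {
    m <- matrix(stats::rnbinom(length(mu_matrix), size = size, mu = mu_matrix),
                nrow = n)
    storage.mode(m) <- "integer"
    m
  }
  with_seed(seed, {
    is_trt <- as.numeric(samples$condition == conditions[2])
    mu_rna <- outer(g$baseline_mean, rep(1, nrow(samples))) *
      2^(outer(g$log2fc_rna, is_trt))
    mu_rpf <- outer(g$baseline_mean, rep(1, nrow(samples))) *
      2^(outer(g$log2fc_rna + g$log2fc_te, is_trt))
    rna <- draw(mu_rna)
    rpf <- draw(mu_rpf)
    mk <- function(counts, assay) {
      smp <- samples
      smp$assay <- assay
      smp$sample <- sprintf("%s_%s_%s", assay, smp$condition, smp$replicate)
      colnames(counts) <- smp$sample
      rownames(counts) <- g$gene
      count_matrix(counts, lengths = stats::setNames(g$length, g$gene),
                   samples = smp[, c("sample", "condition", "replicate", "assay")])
    }
    list(rpf = mk(rpf, "RPF"), rna = mk(rna, "RNA"))
  })
}

#' Simulate ribosome-protected-fragment reads on a CDS
#'
#' Read 5'-ends start at codon boundaries with probability `frame0_weight`
#' (frames 1 and 2 split the remainder equally); lengths are uniform over
#' `length_range`. Used to exercise the 3-nt periodicity QC.
#'
#' @param cds_length CDS length in nt (>= 3).
#' @param n_reads number of reads.
#' @param frame0_weight probability that a read starts in frame 0; default
#'   0.75, a typical in-frame fraction for a good Ribo-seq library.
#' @param length_range inclusive read-length range; the RPF selection window
#'   is 30-40 nt.
#' @param seed integer RNG seed.
#' @param cds_start 1-based CDS start on the transcript.
#' @return data.frame of read records (`length`, `pos5`) with the CDS start
#'   stored in attribute `"cds_start"`.
#' @export
simulate_rpf_reads <- function(cds_length, n_reads, frame0_weight = 0.75,
                               length_range = c(30L, 40L), seed = 1L,
                               cds_start = 1L) {
  if (cds_length < 3) stop_invalid("cds_length must be >= 3 nt (empty CDS)")
  if (frame0_weight < 0 || frame0_weight > 1) {
    stop_invalid("frame0_weight must lie in [0, 1]")
  }
  n_codons <- cds_length %/% 3L
  with_seed(seed, {
    frame <- sample(0:2, n_reads, replace = TRUE,
                    prob = c(frame0_weight, (1 - frame0_weight) / 2,
                             (1 - frame0_weight) / 2))
    codon <- sample.int(n_codons, n_reads, replace = TRUE) - 1L
    reads <- data.frame(
      length = sample(length_range[1]:length_range[2], n_reads, replace = TRUE),
      pos5 = cds_start + 3L * codon + frame
    )
    attr(reads, "cds_start") <- as.integer(cds_start)
    reads
  })
}
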