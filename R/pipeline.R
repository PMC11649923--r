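# Pipeline configuration and the umbrella runner binding the stages into a
# reproducible end-to-end analysis on synthetic or user-supplied data.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage with validation. A config
#' plus a seed fully determines the pipeline outputs.
#'
#' @param seed integer master seed.
#' @param w,theta_full,theta_part,min_neighbor_mean Methscore parameters.
#' @param fc_cut,fdr_tiers,pseudocount translation-efficiency parameters.
#' @param sim simulator settings: a list with `length`, `gc`, `n_full`,
#'   `n_partial`, `depth`, `noise_cv`, `replicates_control`,
#'   `replicates_kd`, `kd_delta_f`, `n_genes`, `n_te_down`, `log2fc_te`,
#'   `baseline_mean`, `dispersion`, `te_replicates`, `rpf_reads`,
#'   `frame0_weight` (missing entries take defaults).
#' @param inputs optional named list of input paths (e.g. `fasta`,
#'   `end_counts`, `query_fasta`, `subject_fasta`, `known_sites`,
#'   `cell_types`); when absent the corresponding stage runs on simulated
#'   data (or is skipped).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, w = 6L, theta_full = 0.85,
                            theta_part = 0.65, min_neighbor_mean = 10,
                            fc_cut = 0.8, fdr_tiers = c(0.05, 0.25),
                            pseudocount = 0.1, sim = list(),
                            inputs = list()) {
  if (theta_full <= 0 || theta_full >= 1 || theta_part <= 0 || theta_part >= 1) {
    stop_invalid("thresholds must lie in (0, 1)")
  }
  if (theta_part >= theta_full) stop_invalid("theta_part must be < theta_full")
  if (fc_cut <= 0) stop_invalid("fc_cut must be > 0")
  defaults <- list(length = 1800L, gc = 0.52, n_full = 20L, n_partial = 14L,
                   depth = 200, noise_cv = 0.2, replicates_control = 6L,
                   replicates_kd = 3L, kd_delta_f = -0.4, n_genes = 500L,
                   n_te_down = 25L, log2fc_te = -1.5, baseline_mean = 500,
                   dispersion = 0.05, te_replicates = 3L, rpf_reads = 5000L,
                   frame0_weight = 0.75)
  sim <- utils::modifyList(defaults, sim)
  structure(list(seed = as.integer(seed), w = as.integer(w),
                 theta_full = theta_full, theta_part = theta_part,
                 min_neighbor_mean = min_neighbor_mean, fc_cut = fc_cut,
                 fdr_tiers = fdr_tiers, pseudocount = pseudocount,
                 sim = sim, inputs = inputs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Run the full pipeline
#'
#' Executes simulate (when no input profiles are given), Methscore calling,
#' consensus site calling, differential methylation, conservation (when a
#' subject sequence and known-site table are supplied), translation
#' efficiency and ribosome-profiling QC, writing each stage's outputs plus a
#' machine-readable `manifest.json` (package version, seed, parameters,
#' per-stage output paths). Rerunning with an identical config and seed
#' reproduces byte-identical outputs; the manifest deliberately records no
#' timestamps.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress logging.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop_invalid("pre-flight: input path missing: ", p)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) log_msg("info", ...)
  outputs <- list()
  sim <- config$sim
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # --- RiboMeth-seq arm -----------------------------------------------------
  say("stage simulate: rRNA reference, truth sites, end counts")
  rms <- run_stage("simulate", {
    ref <- simulate_rrna_reference(sim$length, sim$gc, seed = config$seed)
    truth <- simulate_truth_sites(ref, sim$n_full, sim$n_partial,
                                  seed = config$seed + 1L, w = config$w)
    ctl <- simulate_end_counts(ref, truth,
                               rms_sim_config(sim$depth, sim$noise_cv,
                                              sim$replicates_control,
                                              seed = config$seed + 2L),
                               condition = "control")
    full_pos <- truth$sites$position[truth$sites$class_label == "full"]
    eff <- stats::setNames(rep(sim$kd_delta_f, length(full_pos)), full_pos)
    eff <- pmax(eff, -truth$sites$f[truth$sites$class_label == "full"])
    kd <- simulate_end_counts(ref, truth,
                              rms_sim_config(sim$depth, sim$noise_cv,
                                             sim$replicates_kd,
                                             seed = config$seed + 3L),
                              condition_effects = eff, condition = "kd")
    list(ref = ref, truth = truth, ctl = ctl, kd = kd)
  })
  outputs$reference <- file.path(outdir, "reference.fa")
  write_fasta(rms$ref, outputs$reference)
  outputs$truth <- file.path(outdir, "truth_sites.csv")
  write_truth(rms$truth, outputs$truth)
  outputs$end_counts <- file.path(outdir, "end_counts.tsv")
  write_end_counts(c(rms$ctl, rms$kd), outputs$end_counts)

  say("stage methscore + callsites")
  calls <- run_stage("callsites", {
    call_consensus_sites(rms$ctl, rms$ref, w = config$w,
                         min_neighbor_mean = config$min_neighbor_mean,
                         theta_full = config$theta_full,
                         theta_part = config$theta_part)
  })
  outputs$methscore_tracks <- file.path(outdir, "methscore_control.tsv")
  write_methscore_tracks(calls$tracks, outputs$methscore_tracks)
  outputs$site_calls <- file.path(outdir, "site_calls.csv")
  write_site_calls(calls$calls, outputs$site_calls)

  say("stage diffmeth")
  diffmeth <- run_stage("diffmeth", {
    kd_tracks <- lapply(rms$kd, compute_methscore, w = config$w,
                        min_neighbor_mean = config$min_neighbor_mean)
    summarize_diffmeth(calls$tracks, kd_tracks, sites = calls$calls,
                       reference = rms$ref)
  })
  outputs$diffmeth <- file.path(outdir, "diffmeth.csv")
  utils::write.csv(diffmeth, outputs$diffmeth, row.names = FALSE, quote = FALSE)

  # --- conservation (optional) ---------------------------------------------
  if (!is.null(config$inputs$subject_fasta) &&
      !is.null(config$inputs$known_sites)) {
    say("stage conserve")
    cons <- run_stage("conserve", {
      query <- if (!is.null(config$inputs$query_fasta)) {
        read_fasta(config$inputs$query_fasta)[[1]]
      } else rms$ref
      subject <- read_fasta(config$inputs$subject_fasta)[[1]]
      known <- read_known_sites(config$inputs$known_sites)
      aln <- global_align(query$sequence, subject$sequence)
      classify_conservation(calls$calls, known$position, map_positions(aln))
    })
    outputs$conservation <- file.path(outdir, "conservation.csv")
    utils::write.csv(cons, outputs$conservation, row.names = FALSE,
                     quote = FALSE)
  }

  # --- translatome arm ------------------------------------------------------
  say("stage te: simulate counts, deltaTE contrast, categories")
  te <- run_stage("te", {
    truth <- simulate_te_truth(sim$n_genes, sim$n_te_down, sim$log2fc_te,
                               sim$baseline_mean, sim$dispersion,
                               seed = config$seed + 4L)
    mats <- simulate_ribo_rna_counts(truth, replicates = sim$te_replicates,
                                     seed = config$seed + 5L)
    res <- differential_te(mats$rpf, mats$rna, ref_level = "control")
    cat_res <- categorize_genes(res, fc_cut = config$fc_cut,
                                fdr_tiers = config$fdr_tiers)
    fit <- te_scatter_fit(res$log2FC_RNA, res$log2FC_TE)
    list(truth = truth, mats = mats, res = cat_res, fit = fit)
  })
  outputs$rpf_counts <- file.path(outdir, "rpf_counts.tsv")
  outputs$sample_meta <- file.path(outdir, "samples.csv")
  write_count_matrix(te$mats$rpf, outputs$rpf_counts, outputs$sample_meta)
  outputs$rna_counts <- file.path(outdir, "rna_counts.tsv")
  write_count_matrix(te$mats$rna, outputs$rna_counts,
                     file.path(outdir, "samples_rna.csv"))
  outputs$te_results <- file.path(outdir, "te_results.csv")
  utils::write.csv(te$res$results, outputs$te_results, row.names = FALSE,
                   quote = FALSE)
  outputs$te_categories <- file.path(outdir, "te_categories.json")
  jsonlite::write_json(list(counts = as.list(te$res$counts),
                            scatter_fit = te$fit),
                       outputs$te_categories, auto_unbox = TRUE, digits = NA)

  if (!is.null(config$inputs$cell_types)) {
    say("stage celltypes")
    map <- read_cell_type_map(config$inputs$cell_types)
    ann <- annotate_cell_types(te$res, map)
    outputs$cell_types <- file.path(outdir, "cell_type_counts.csv")
    utils::write.csv(as.data.frame(ann$counts), outputs$cell_types,
                     row.names = FALSE, quote = FALSE)
  }

  # --- QC -------------------------------------------------------------------
  say("stage qc")
  qc <- run_stage("qc", {
    reads <- simulate_rpf_reads(3000L, sim$rpf_reads, sim$frame0_weight,
                                seed = config$seed + 6L)
    reads <- select_rpf(filter_reads_by_length(reads))
    per <- compute_periodicity(reads)
    rna_tpm <- compute_tpm(te$mats$rna)
    rpf_tpm <- compute_tpm(te$mats$rpf)
    corr <- sample_correlation(rna_tpm[, 1], rpf_tpm[, 1])
    list(periodicity = per, correlation = corr)
  })
  outputs$qc <- file.path(outdir, "qc.json")
  jsonlite::write_json(
    list(frame_fractions = as.list(qc$periodicity$frame_fractions),
         n_reads = qc$periodicity$n_reads,
         spearman_rho = qc$correlation$spearman_rho,
         r_squared = qc$correlation$r_squared),
    outputs$qc, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "ribomethr",
    version = as.character(utils::packageVersion("ribomethr")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "inputs")],
    inputs = config$inputs,
    # paths relative to outdir, so a rerun elsewhere is byte-identical
    outputs = lapply(outputs, basename)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(outputs), " outputs in ", outdir)
  invisible(manifest)
}

#' A small demo configuration
#'
#' Scaled-down simulator settings so the end-to-end pipeline runs in well
#' under a minute.
#'
#' @param seed master seed.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(seed = seed,
                  sim = list(length = 600L, n_full = 6L, n_partial = 4L,
                             n_genes = 300L, n_te_down = 15L,
                             rpf_reads = 2000L))
}
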