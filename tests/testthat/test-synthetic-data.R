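# synthetic_data module: references, truth sites, end counts, count
# matrices, RPF reads.

test_that("simulate_rrna_reference honors its contract", {
  ref <- simulate_rrna_reference(100, gc = 0.5, seed = 1)
  expect_s3_class(ref, "rrna_reference")
  expect_equal(ref$length, 100)
  expect_equal(nchar(ref$sequence), 100)
  expect_true(all(strsplit(ref$sequence, "")[[1]] %in% c("A", "C", "G", "U")))

  # determinism
  expect_identical(simulate_rrna_reference(100, 0.5, seed = 1)$sequence,
                   ref$sequence)
  expect_false(identical(simulate_rrna_reference(100, 0.5, seed = 2)$sequence,
                         ref$sequence))

  # gc target within 3 sigma of binomial sampling
  n <- 3000
  ref9 <- simulate_rrna_reference(n, gc = 0.9, seed = 3)
  gc_obs <- mean(strsplit(ref9$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.9), 3 * sqrt(0.9 * 0.1 / n))

  expect_error(simulate_rrna_reference(49), "50")
  expect_error(simulate_rrna_reference(100, gc = 1), "between 0 and 1")
})

test_that("simulate_truth_sites places sites within bands and margins", {
  ref <- simulate_rrna_reference(1800, 0.52, seed = 4)
  empty <- simulate_truth_sites(ref, 0, 0, seed = 1)
  expect_equal(nrow(empty$sites), 0)

  truth <- simulate_truth_sites(ref, 10, 14, seed = 5)
  s <- truth$sites
  expect_equal(nrow(s), 24)
  expect_false(anyDuplicated(s$position) > 0)
  expect_true(all(diff(sort(s$position)) >= 2))
  expect_true(all(s$position > 13 & s$position <= 1800 - 13))
  full <- s[s$class_label == "full", ]
  part <- s[s$class_label == "partial", ]
  expect_equal(nrow(full), 10)
  expect_true(all(full$f >= 0.9 & full$f <= 1.0))
  expect_true(all(part$f >= 0.65 & part$f <= 0.85))

  # infeasible placement reports requested vs feasible
  tiny <- simulate_rrna_reference(50, 0.5, seed = 6)
  expect_error(simulate_truth_sites(tiny, 30, 30, seed = 1), "feasible")
})

test_that("simulate_end_counts models protection and is deterministic", {
  ref <- simulate_rrna_reference(80, 0.5, seed = 8)
  truth <- simulate_truth_sites(ref, 1, 0, seed = 9, f_full = c(1, 1))
  j <- truth$sites$position
  cfg <- rms_sim_config(depth = 100, noise_cv = 0.2, replicates = 4, seed = 10)
  prof <- simulate_end_counts(ref, truth, cfg)
  expect_length(prof, 8)

  # f = 1 fully protects the bond: zero 5p ends at j+1 and 3p ends at j
  p5 <- Filter(function(p) p$end == "5p", prof)
  p3 <- Filter(function(p) p$end == "3p", prof)
  expect_true(all(vapply(p5, function(p) p$counts[j + 1L], integer(1)) == 0L))
  expect_true(all(vapply(p3, function(p) p$counts[j], integer(1)) == 0L))

  # determinism: bit-identical profiles for a fixed seed
  prof2 <- simulate_end_counts(ref, truth, cfg)
  expect_identical(lapply(prof, `[[`, "counts"), lapply(prof2, `[[`, "counts"))

  # unmethylated molecule: grand mean of per-bond counts ~ depth (3 sigma)
  ref2 <- simulate_rrna_reference(500, 0.5, seed = 11)
  truth0 <- simulate_truth_sites(ref2, 0, 0, seed = 1)
  prof0 <- simulate_end_counts(ref2, truth0,
                               rms_sim_config(100, 0, 10, seed = 12))
  counts5 <- unlist(lapply(Filter(function(p) p$end == "5p", prof0),
                           function(p) p$counts[2:500]))
  expect_lt(abs(mean(counts5) - 100), 3 * sqrt(100 / length(counts5)))

  # delta f cannot push f outside [0, 1]
  expect_error(
    simulate_end_counts(ref, truth, cfg,
                        condition_effects = setNames(0.5, j)),
    "outside")
})

test_that("simulate_ribo_rna_counts plants NB effects where stated", {
  # null world: condition-wise mean ratios ~ 1
  truth0 <- te_sim_truth(gene = sprintf("g%d", 1:200), length = 1000,
                         baseline_mean = 400, dispersion = 0.05)
  mats <- simulate_ribo_rna_counts(truth0, replicates = 6, seed = 13)
  for (m in mats) {
    ctl <- m$counts[, m$samples$condition == "control"]
    kd <- m$counts[, m$samples$condition == "kd"]
    ratio <- mean(kd) / mean(ctl)
    # relative SE of a mean over 1200 NB draws is ~ sqrt(0.052/1200) ~ 0.0066
    expect_lt(abs(log2(ratio)), 3 * 0.0066 / log(2) * sqrt(2))
  }

  # planted TE effect shifts the RPF/RNA ratio by ~ 2^log2fc_te in kd only
  truth1 <- te_sim_truth(gene = sprintf("g%d", 1:300), length = 1000,
                         baseline_mean = 500, dispersion = 0.05,
                         log2fc_rna = 0, log2fc_te = -1.5)
  mats1 <- simulate_ribo_rna_counts(truth1, replicates = 4, seed = 14)
  kd_ratio <- mean(mats1$rpf$counts[, mats1$rpf$samples$condition == "kd"]) /
    mean(mats1$rna$counts[, mats1$rna$samples$condition == "kd"])
  ctl_ratio <- mean(mats1$rpf$counts[, mats1$rpf$samples$condition == "control"]) /
    mean(mats1$rna$counts[, mats1$rna$samples$condition == "control"])
  expect_equal(log2(kd_ratio / ctl_ratio), -1.5, tolerance = 0.05)

  # determinism and the replicate precondition
  mats2 <- simulate_ribo_rna_counts(truth0, replicates = 6, seed = 13)
  expect_identical(mats$rpf$counts, mats2$rpf$counts)
  expect_error(simulate_ribo_rna_counts(truth0, replicates = 1), ">= 2")

  # sample metadata carries the design
  expect_setequal(unique(mats$rpf$samples$assay), "RPF")
  expect_equal(sum(mats$rna$samples$condition == "control"), 6)
})

test_that("simulate_rpf_reads controls frame and length", {
  reads <- simulate_rpf_reads(900, 2000, frame0_weight = 1, seed = 15)
  expect_true(all((reads$pos5 - 1L) %% 3L == 0L))
  expect_true(all(reads$length >= 30 & reads$length <= 40))

  r3 <- simulate_rpf_reads(900, 6000, frame0_weight = 1 / 3, seed = 16)
  fr <- tabulate((r3$pos5 - 1L) %% 3L + 1L, 3) / 6000
  expect_true(all(abs(fr - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 6000)))

  expect_error(simulate_rpf_reads(2, 10), "CDS")
  expect_error(simulate_rpf_reads(900, 10, frame0_weight = 1.2), "0, 1")
})
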