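# translatome: TPM, per-replicate TE, the deltaTE interaction contrast,
# quadrant categories, scatter fit, cell-type attribution.

make_cm <- function(counts, lengths, condition, replicate, assay) {
  samples <- data.frame(
    sample = sprintf("%s_%s_%s", assay, condition, replicate),
    condition = condition, replicate = replicate, assay = assay)
  count_matrix(counts, lengths, samples)
}

test_that("compute_tpm normalizes by length and library", {
  counts <- matrix(c(100L, 100L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  cm <- make_cm(counts, c(g1 = 1000, g2 = 2000), "control", "rep1", "RNA")
  tpm <- compute_tpm(cm)
  expect_equal(unname(tpm["g1", 1] / tpm["g2", 1]), 2)
  expect_equal(unname(colSums(tpm)), 1e6)

  # single gene gets the whole million
  cm1 <- make_cm(matrix(7L, 1, 1, dimnames = list("g1", "s1")),
                 c(g1 = 500), "control", "rep1", "RNA")
  expect_equal(unname(compute_tpm(cm1)[1, 1]), 1e6)

  # random matrices: every nonzero column sums to 1e6
  set.seed(61)
  counts <- matrix(rpois(50, 30), 10, 5,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  cm <- count_matrix(counts, setNames(sample(500:2000, 10), paste0("g", 1:10)),
                     data.frame(sample = paste0("s", 1:5), condition = "c",
                                replicate = paste0("r", 1:5), assay = "RNA"))
  expect_equal(unname(colSums(compute_tpm(cm))), rep(1e6, 5))

  # zero library flagged
  counts0 <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "s0"))
  cm0 <- make_cm(counts0, c(g1 = 1000, g2 = 1000), "c", "r1", "RNA")
  expect_warning(tpm0 <- compute_tpm(cm0), "zero-library")
  expect_true(all(tpm0 == 0))
})

test_that("compute_te pairs replicates and applies the TPM floor", {
  g <- c(g1 = 1000, g2 = 1000)
  rpf <- make_cm(matrix(c(10L, 10L), 2, dimnames = list(names(g), "rpf1")),
                 g, "control", "rep1", "RPF")
  rna <- make_cm(matrix(c(5L, 15L), 2, dimnames = list(names(g), "rna1")),
                 g, "control", "rep1", "RNA")
  te <- compute_te(compute_tpm(rpf), compute_tpm(rna), pseudo = 0)
  # RPF TPM g1 = 5e5, RNA TPM g1 = 2.5e5 -> TE 2
  expect_equal(unname(te$te["g1", 1]), 2)
  expect_equal(unname(te$log2_te["g1", 1]), 1)

  # RPF == RNA -> log2 TE 0
  te_eq <- compute_te(compute_tpm(rna), compute_tpm(rna), pseudo = 0)
  expect_true(all(te_eq$log2_te == 0))

  # floor keeps TE finite when RNA is 0
  rna0 <- make_cm(matrix(c(0L, 15L), 2, dimnames = list(names(g), "rna1")),
                  g, "control", "rep1", "RNA")
  te0 <- compute_te(compute_tpm(rpf), compute_tpm(rna0), pseudo = 0.5)
  expect_true(all(is.finite(te0$te)))

  # unpaired replicate errors with the orphan named
  rna2 <- make_cm(matrix(c(5L, 15L), 2, dimnames = list(names(g), "rna2")),
                  g, "control", "rep2", "RNA")
  expect_error(compute_te(compute_tpm(rpf), compute_tpm(rna2)), "rep")
})

test_that("differential_te is null-calibrated and orthogonal (OLS route)", {
  # null world
  truth0 <- te_sim_truth(sprintf("g%03d", 1:300), 1000, 400, 0.05)
  mats <- simulate_ribo_rna_counts(truth0, replicates = 3, seed = 62)
  res <- differential_te(mats$rpf, mats$rna, method = "ols")
  expect_equal(nrow(res), 300)
  expect_gte(mean(res$fdr_TE >= 0.05, na.rm = TRUE), 0.99)
  expect_lt(abs(mean(res$log2FC_TE)), 0.05)

  # RNA-only shift on a gene subset leaves the interaction at ~0 there
  # (a shift on *all* genes would be absorbed by size-factor normalization)
  truth1 <- te_sim_truth(sprintf("g%03d", 1:300), 1000, 400, 0.05,
                         log2fc_rna = rep(c(2, 0), c(30, 270)), log2fc_te = 0)
  mats1 <- simulate_ribo_rna_counts(truth1, replicates = 3, seed = 63)
  res1 <- differential_te(mats1$rpf, mats1$rna, method = "ols")
  shifted <- seq_len(30)
  expect_lt(abs(mean(res1$log2FC_TE[shifted])), 0.15)
  expect_equal(mean(res1$log2FC_RNA[shifted]), 2, tolerance = 0.1)

  expect_error(differential_te(mats$rpf, mats$rna, ref_level = "control",
                               method = "nope"))
})

test_that("deltaTE (DESeq2) recovers a planted TE effect", {
  truth <- simulate_te_truth(n_genes = 400, n_te_down = 20, log2fc_te = -1.5,
                             baseline_mean = 500, dispersion = 0.05, seed = 64)
  mats <- simulate_ribo_rna_counts(truth, replicates = 3, seed = 65)
  res <- differential_te(mats$rpf, mats$rna, ref_level = "control")
  planted <- truth$genes$gene[truth$genes$log2fc_te != 0]
  est <- res$log2FC_TE[match(planted, res$gene)]
  expect_equal(mean(est), -1.5, tolerance = 0.15)  # parameter recovery
  ann <- categorize_genes(res)$results
  hit <- ann$gene[ann$category == "TE_down" & ann$fdr_tier == "0.05"]
  expect_gte(sum(planted %in% hit) / length(planted), 0.6)
})

test_that("categorize_genes applies the quadrant rules and partitions", {
  res <- data.frame(
    gene = paste0("g", 1:8),
    log2FC_RNA = c(0, 0, 1.2, -1.5, 1.0, 0.3, NA, 0.79),
    log2FC_TE = c(-1, 1.3, 0.2, -0.1, -2.0, -0.5, 0.1, -0.81),
    p_TE = c(0.001, 0.2, 0.5, 0.6, 0.01, 0.9, NA, 0.03),
    fdr_TE = c(0.01, 0.3, 0.6, 0.7, 0.04, 0.95, NA, 0.2))
  out <- categorize_genes(res)
  cat <- setNames(out$results$category, out$results$gene)
  expect_equal(unname(cat["g1"]), "TE_down")     # (-1, 0, fdr 0.01)
  expect_equal(unname(cat["g2"]), "TE_up")
  expect_equal(unname(cat["g3"]), "RNA_up")
  expect_equal(unname(cat["g4"]), "RNA_down")
  expect_equal(unname(cat["g5"]), "concordant")
  expect_equal(unname(cat["g6"]), "unchanged")   # (-0.5, 0.3)
  expect_equal(unname(cat["g7"]), "not_tested")
  expect_equal(unname(cat["g8"]), "TE_down")     # boundary |RNA| < 0.8
  expect_equal(out$results$fdr_tier[1], "0.05")
  expect_equal(out$results$fdr_tier[8], "0.25")
  expect_equal(out$results$fdr_tier[3], "ns")
  # categories partition the gene set
  expect_equal(sum(out$counts), nrow(res))
})

test_that("te_scatter_fit matches closed-form least squares", {
  # y = x exactly
  f <- te_scatter_fit(1:10, 1:10)
  expect_equal(f$slope, 1)
  expect_equal(f$r2, 1)

  # hand-computable 4-point set via the normal equations
  x <- c(0, 1, 2, 4); y <- c(1, 2, 2, 5)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  inter <- mean(y) - slope * mean(x)
  f4 <- te_scatter_fit(x, y)
  expect_equal(f4$slope, slope)
  expect_equal(f4$intercept, inter)
  expect_equal(f4$r2, cor(x, y)^2)

  # independent y -> R2 near 0
  set.seed(66)
  f0 <- te_scatter_fit(rnorm(2000), rnorm(2000))
  expect_lt(f0$r2, 0.01)

  expect_warning(fc <- te_scatter_fit(rep(1, 5), 1:5), "constant")
  expect_true(is.na(fc$slope))
  expect_error(te_scatter_fit(1:2, 1:2), ">= 3")
})

test_that("annotate_cell_types buckets genes and normalizes fractions", {
  res <- data.frame(gene = paste0("g", 1:6),
                    category = c(rep("TE_down", 4), "unchanged", "unchanged"))
  map <- setNames(rep("neoblast", 4), paste0("g", 1:4))
  ann <- annotate_cell_types(res, map)
  expect_equal(unname(ann$fractions["TE_down", "neoblast"]), 1)
  expect_equal(unname(ann$fractions["unchanged", "unassigned"]), 1)
  expect_equal(unname(rowSums(ann$counts)), c(4, 2))

  # empty map -> all unassigned
  ann0 <- annotate_cell_types(res, setNames(character(0), character(0)))
  expect_true(all(colnames(ann0$counts) == "unassigned"))

  # random labels track label frequencies within multinomial error
  set.seed(67)
  n <- 3000
  res_big <- data.frame(gene = paste0("g", 1:n), category = "TE_down")
  labs <- sample(c("neoblast", "epidermal", "neural"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  ann_big <- annotate_cell_types(res_big, setNames(labs, res_big$gene))
  fr <- ann_big$fractions["TE_down", c("neoblast", "epidermal", "neural")]
  expect_true(all(abs(fr - c(0.5, 0.3, 0.2)) <
                    3 * sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / n)))
})
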