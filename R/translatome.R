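# Translation-efficiency analysis of paired Ribo-seq / RNA-seq matrices:
# TPM, per-replicate TE, deltaTE-style differential statistics (a
# condition-by-assay interaction contrast), quadrant categories and
# cell-type attribution.

#' Gene-by-sample count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes in rows (rownames set),
#'   samples in columns.
#' @param lengths named numeric vector of transcript lengths in nt (>= 1),
#'   one per gene.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`, `assay` (`"RNA"` or `"RPF"`), one row per column of
#'   `counts`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop_invalid("counts must have gene rownames")
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths < 1)) {
    stop_invalid("every gene needs a length >= 1 nt")
  }
  needed <- c("sample", "condition", "replicate", "assay")
  if (!all(needed %in% names(samples))) {
    stop_invalid("samples needs columns: ", paste(needed, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, needed]
  if (nrow(samples) != ncol(counts)) {
    stop_invalid("samples rows (", nrow(samples),
                 ") must match count columns (", ncol(counts), ")")
  }
  colnames(counts) <- samples$sample
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = "/")))
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' `TPM_gs = (count_gs / length_g) / sum_g'(count_g's / length_g') * 1e6`;
#' each sample column sums to one million whenever it has any nonzero count.
#' Zero-library columns are returned as zeros with a warning.
#'
#' @param cm a [count_matrix()].
#' @return numeric TPM matrix with the sample metadata attached as
#'   attribute `"samples"`.
#' @export
compute_tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rate <- cm$counts / cm$lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("zero-library column(s): ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  attr(tpm, "samples") <- cm$samples
  tpm
}

#' Per-replicate translation efficiency
#'
#' Pairs RPF and RNA samples by `(condition, replicate)` -- the paired
#' aliquot design -- and computes `TE = (rpf_tpm + pseudo) / (rna_tpm +
#' pseudo)` per gene and replicate, with the TPM floor `pseudo` keeping TE
#' finite for unexpressed genes.
#'
#' @param rpf_tpm,rna_tpm TPM matrices from [compute_tpm()] (carrying
#'   `"samples"` attributes).
#' @param pseudo TPM floor added to both assays (default 0.1).
#' @return list with matrices `te` and `log2_te` (columns named
#'   `condition.replicate`), the pairing table `pairs`, and `low_expression`
#'   (logical matrix marking entries where both assays sat below `pseudo`).
#' @export
compute_te <- function(rpf_tpm, rna_tpm, pseudo = 0.1) {
  sp <- attr(rpf_tpm, "samples"); sr <- attr(rna_tpm, "samples")
  if (is.null(sp) || is.null(sr)) {
    stop_invalid("TPM matrices must carry a 'samples' attribute (see compute_tpm)")
  }
  key <- function(s) paste(s$condition, s$replicate, sep = ".")
  kp <- key(sp); kr <- key(sr)
  orphans <- c(setdiff(kp, kr), setdiff(kr, kp))
  if (length(orphans) > 0) {
    stop_invalid("unpaired replicate(s): ", paste(unique(orphans), collapse = ", "))
  }
  ord <- match(kp, kr)
  te <- (rpf_tpm + pseudo) / (rna_tpm[, ord, drop = FALSE] + pseudo)
  colnames(te) <- kp
  low <- (rpf_tpm < pseudo) & (rna_tpm[, ord, drop = FALSE] < pseudo)
  colnames(low) <- kp
  list(te = te, log2_te = log2(te),
       pairs = data.frame(pair = kp, rpf_sample = sp$sample,
                          rna_sample = sr$sample[ord]),
       low_expression = low)
}

# Median-of-ratios size factors (computed per assay; RNA and RPF libraries
# differ in composition). Genes with any zero count are excluded from the
# reference geometric mean.
size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0
  if (sum(keep) < 1) stop_invalid("no gene has all-positive counts; cannot normalize")
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  apply(counts[keep, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
}

#' deltaTE-style differential translation efficiency
#'
#' Estimates, per gene, the RNA-level condition effect (`log2FC_RNA`) and
#' the translation-efficiency condition effect (`log2FC_TE`) as the
#' condition-by-assay interaction of a model over the combined RNA and RPF
#' libraries, following the deltaTE formulation.
#'
#' `method = "deseq2"` (default) fits the negative-binomial GLM
#' `~ condition + assay + condition:assay` with DESeq2 and takes the Wald
#' test of the interaction coefficient; this is the deltaTE estimator.
#' `method = "ols"` is a lightweight approximation: per-assay
#' median-of-ratios size factors, then ordinary least squares on
#' `log2(normalized count + 0.5)` with the same design and a t-test of the
#' interaction on the residual degrees of freedom. The OLS route estimates
#' the same contrast but, lacking any variance sharing across genes, has
#' considerably less power at small replicate numbers.
#'
#' FDR is Benjamini-Hochberg across genes on the raw interaction p-values.
#'
#' @param rpf,rna [count_matrix()] objects with identical genes and a shared
#'   `(condition, replicate)` design, >= 2 replicates per condition.
#' @param ref_level reference (control) condition; default the first level
#'   encountered in the RNA metadata.
#' @param method `"deseq2"` or `"ols"`.
#' @return data.frame, one row per gene: `gene`, `base_mean`, `log2FC_RNA`,
#'   `log2FC_TE`, `p_TE`, `fdr_TE`.
#' @export
differential_te <- function(rpf, rna, ref_level = NULL,
                            method = c("deseq2", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(rpf, "count_matrix"), inherits(rna, "count_matrix"))
  if (!identical(rownames(rpf$counts), rownames(rna$counts))) {
    stop_invalid("RPF and RNA matrices must share the same genes in order")
  }
  meta <- rbind(rna$samples, rpf$samples)
  counts <- cbind(rna$counts, rpf$counts)
  conds <- unique(meta$condition)
  if (length(conds) != 2L) stop_invalid("exactly two conditions are required")
  ref_level <- ref_level %||% conds[1]
  trt_level <- setdiff(conds, ref_level)
  tab <- table(meta$condition, meta$assay)
  if (any(tab < 2L)) {
    stop_invalid("need >= 2 replicates per condition per assay")
  }
  condition <- factor(meta$condition, levels = c(ref_level, trt_level))
  assay <- factor(meta$assay, levels = c("RNA", "RPF"))
  genes <- rownames(counts)

  if (method == "deseq2") {
    coldata <- data.frame(condition = condition, assay = assay)
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = counts, colData = coldata,
      design = ~ condition + assay + condition:assay)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    rn <- DESeq2::resultsNames(dds)
    int_name <- grep("^condition.*\\.assay", rn, value = TRUE)[1]
    cond_name <- grep("^condition_.*_vs_", rn, value = TRUE)[1]
    res_te <- DESeq2::results(dds, name = int_name,
                              independentFiltering = FALSE, cooksCutoff = FALSE)
    res_rna <- DESeq2::results(dds, name = cond_name,
                               independentFiltering = FALSE, cooksCutoff = FALSE)
    out <- data.frame(
      gene = genes,
      base_mean = res_te$baseMean,
      log2FC_RNA = res_rna$log2FoldChange,
      log2FC_TE = res_te$log2FoldChange,
      p_TE = res_te$pvalue,
      stringsAsFactors = FALSE
    )
  } else {
    sf <- numeric(ncol(counts))
    for (a in levels(assay)) {
      idx <- which(assay == a)
      sf[idx] <- size_factors(counts[, idx, drop = FALSE])
    }
    norm <- sweep(counts, 2, sf, "/")
    y <- log2(norm + 0.5)
    X <- stats::model.matrix(~ condition * assay)
    XtXi <- solve(crossprod(X))
    H <- XtXi %*% t(X)
    B <- y %*% t(H)                      # genes x coefficients
    fitted <- B %*% t(X)
    resid <- y - fitted
    df <- ncol(y) - ncol(X)
    s2 <- rowSums(resid^2) / df
    i_int <- ncol(X)                      # interaction is the last column
    i_cond <- 2L                          # condition main effect
    se_int <- sqrt(s2 * XtXi[i_int, i_int])
    tstat <- B[, i_int] / se_int
    out <- data.frame(
      gene = genes,
      base_mean = rowMeans(norm),
      log2FC_RNA = B[, i_cond],
      log2FC_TE = B[, i_int],
      p_TE = 2 * stats::pt(-abs(tstat), df),
      stringsAsFactors = FALSE
    )
  }
  out$fdr_TE <- bh_adjust(out$p_TE)
  rownames(out) <- NULL
  out
}

#' Quadrant categories for TE results
#'
#' Genes are partitioned by their RNA-level and TE-level log2 fold changes
#' at a symmetric cutoff (default +/- 0.8):
#' * `TE_down` / `TE_up`: `log2FC_TE` beyond the cutoff with
#'   `|log2FC_RNA|` inside it (translation changes, mRNA does not);
#' * `RNA_down` / `RNA_up`: `|log2FC_RNA| >=` cutoff with `|log2FC_TE|`
#'   inside it;
#' * `concordant`: both beyond the cutoff;
#' * `unchanged`: neither.
#' Genes with missing statistics are reported as `not_tested`. An FDR tier
#' (`"0.05"`, `"0.25"`, `"ns"`) is recorded per gene from `fdr_TE`,
#' mirroring the strict and relaxed significance cut-offs.
#'
#' @param results data.frame from [differential_te()].
#' @param fc_cut absolute log2 fold-change cutoff (default 0.8).
#' @param fdr_tiers two significance tiers for the TE FDR (default
#'   `c(0.05, 0.25)`).
#' @return list with `results` (annotated with `category` and `fdr_tier`),
#'   `counts` (named vector over categories, summing to the gene count) and
#'   `counts_by_tier` (category x tier table).
#' @export
categorize_genes <- function(results, fc_cut = 0.8, fdr_tiers = c(0.05, 0.25)) {
  if (fc_cut <= 0) stop_invalid("fc_cut must be > 0")
  fdr_tiers <- sort(fdr_tiers)
  te <- results$log2FC_TE; rna <- results$log2FC_RNA
  te_hit <- abs(te) > fc_cut
  rna_hit <- abs(rna) >= fc_cut
  category <- rep("unchanged", nrow(results))
  category[te_hit & !rna_hit & te < 0] <- "TE_down"
  category[te_hit & !rna_hit & te > 0] <- "TE_up"
  category[rna_hit & !te_hit & rna < 0] <- "RNA_down"
  category[rna_hit & !te_hit & rna > 0] <- "RNA_up"
  category[te_hit & rna_hit] <- "concordant"
  category[is.na(te) | is.na(rna)] <- "not_tested"
  tier <- rep("ns", nrow(results))
  tier[!is.na(results$fdr_TE) & results$fdr_TE < fdr_tiers[2]] <-
    format(fdr_tiers[2])
  tier[!is.na(results$fdr_TE) & results$fdr_TE < fdr_tiers[1]] <-
    format(fdr_tiers[1])
  res <- results
  res$category <- category
  res$fdr_tier <- tier
  lev <- c("TE_down", "TE_up", "RNA_down", "RNA_up", "concordant",
           "unchanged", "not_tested")
  counts <- table(factor(category, levels = lev))
  list(results = res,
       counts = stats::setNames(as.integer(counts), lev),
       counts_by_tier = table(category = factor(category, levels = lev),
                              fdr_tier = tier))
}

#' Least-squares fit of TE change against RNA change
#'
#' Ordinary least-squares line and coefficient of determination for the
#' scatter of per-gene `log2FC_TE` (y) against `log2FC_RNA` (x).
#'
#' @param x,y equal-length numeric vectors (non-finite pairs dropped);
#'   needs >= 3 finite pairs.
#' @return list with `slope`, `intercept`, `r2`, `n`. A constant `x` yields
#'   an `NA` slope with a warning.
#' @export
te_scatter_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_invalid("need >= 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) {
    warning("constant x: slope undefined")
    return(list(slope = NA_real_, intercept = mean(y), r2 = NA_real_,
                n = length(x)))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(x))
}

#' Read a gene-to-cell-type mapping
#'
#' @param path CSV with columns `gene`, `cell_type`.
#' @return named character vector (gene -> cell type).
#' @export
read_cell_type_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "cell_type") %in% names(df))) {
    stop_invalid("cell-type map needs columns gene, cell_type")
  }
  if (anyDuplicated(df$gene)) stop_invalid("one cell-type label per gene, please")
  stats::setNames(df$cell_type, df$gene)
}

#' Cell-type attribution of categorized genes
#'
#' Tabulates, per quadrant category, how its genes distribute over cell-type
#' labels; genes absent from the mapping are bucketed as `"unassigned"`.
#'
#' @param categorized output of [categorize_genes()] (or its `results`
#'   data.frame).
#' @param map named character vector from [read_cell_type_map()] (may be
#'   empty).
#' @return list with `counts` (category x cell-type table) and `fractions`
#'   (rows summing to 1 for non-empty categories).
#' @export
annotate_cell_types <- function(categorized, map) {
  res <- if (is.list(categorized) && !is.data.frame(categorized)) {
    categorized$results
  } else categorized
  ct <- unname(map[res$gene])
  ct[is.na(ct)] <- "unassigned"
  counts <- table(category = res$category, cell_type = ct)
  fractions <- prop.table(counts, margin = 1)
  list(counts = counts, fractions = fractions)
}
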