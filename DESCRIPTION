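Package: ribomethr
Title: RiboMeth-Seq Methscore Calling and Ribosome-Profiling Translation
    Efficiency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calling 2'-O-methylation (Nm) sites on rRNA from
    RiboMeth-seq read-end count profiles using the Methscore statistic,
    classifying fully and partially methylated sites, forming two-end
    consensus call sets, and testing differential methylation between
    conditions. Also provides cross-species rRNA site conservation mapping
    via global pairwise alignment, translation-efficiency analysis of
    paired Ribo-seq/RNA-seq count matrices with a deltaTE-style
    condition-by-assay interaction contrast, ribosome-profiling quality
    control (read-length filters, 3-nt periodicity, sample correlation),
    and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    Rcpp,
    Biostrings,
    DESeq2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
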