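---
title: "Methods: Methscore calling, differential methylation, and deltaTE analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Methscore calling, differential methylation, and deltaTE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomethr)
```

## The measurement model

RiboMeth-seq quantifies ribose 2'-O-methylation (Nm) through a chemical
negative: a 2'-O-methyl on residue $j$ protects the phosphodiester bond 3'
of $j$ from alkaline hydrolysis. After random alkaline fragmentation and
end sequencing, read ends pile up at cleaved bonds, so a methylated
position shows a *deficit* of read ends at the blocked cleavage point. With
$c_q$ the read-end count at deficit position $q$ and a flank half-width of
$w = 6$ positions, the Methscore is

$$ M_q = \max\!\left(0,\; 1 - \frac{c_q}{\tfrac{1}{2w}\sum_{k \in
   \{q-w..q-1,\,q+1..q+w\}} c_k}\right), $$

an estimate of the methylated fraction at the protecting residue. The
neighbour average is the plain (unweighted) mean of the six preceding and
six succeeding loci; weighted variants exist in the RiboMeth-seq
literature but are deliberately not used here, matching the plain-average
definition this implementation follows.

Coordinate convention (fixed throughout): methylation of residue $j$
protects the bond 3' of $j$, so the 5'-read-end deficit appears at $j+1$
and the 3'-read-end deficit at $j$. `compute_methscore()` shifts each end's
track onto **site coordinates** before classification, and a site is only
reported when *both* end tracks call it (the two-end consensus), which
suppresses coverage artefacts that affect a single end.

### Classification thresholds

Per-condition calling averages the per-replicate Methscore tracks per end,
classifies each end, then intersects:

* **full**: $0.85 < M < 1$;
* **partial**: $0.65 \le M \le 0.85$;
* **flagged**: $M = 1$ exactly. A score of exactly 1 means a zero observed
  count, which can equally be a mapping dropout; honouring the strict
  "$<1$" upper bound, such positions are routed to manual review instead of
  being silently called full;
* **none** otherwise.

`min_neighbor_mean` (default 10 counts) suppresses scores where flanking
coverage is too thin for the ratio to be meaningful; positions within $w$
of a terminus are undefined. Classification is invariant to uniform
scaling of the counts, so no between-replicate normalization is needed
before averaging scores.

## Differential methylation

Per site, each replicate contributes one score: the mean of its 5p- and
3p-derived track values. Conditions are compared with a two-tailed
Student (pooled-variance) $t$-test on $n_1 + n_2 - 2$ df — matching the
mean ± SEM replicate summaries reported alongside — with Welch's form
behind `var_equal = FALSE`. Raw p-values are the primary output;
Benjamini–Hochberg FDR across tested sites is reported as a supplementary
column, never replacing raw p.

One deliberate numerical choice: the $t$-test consumes the **raw
(unclamped)** score $s_q = 1 - c_q/\bar c$, not the reported
$M = \max(s, 0)$. Clamping truncates the null sampling distribution at 0;
in the package's own null simulations the clamped scores produce tied
zeros and visibly distorted calibration, while raw scores give a
type-I rate and p-value uniformity the test suite checks directly
(`test-diffmeth.R`, acceptance criterion on calibration). `use = "score"`
restores the clamped behaviour if wanted.

By default only the consensus sites discovered in the control condition
are tested (`all_positions = TRUE` is the escape hatch), which mirrors
discovering sites in the control and asking how the knockdown moved them.

## Conservation mapping

Cross-species projection uses global Needleman–Wunsch alignment with
affine gaps (Gotoh), scoring match $+2$, mismatch $-1$, gap open $-5$, gap
extend $-1$ — a reasonable heuristic for rRNA; no published tool or
parameter set was available to copy, so the defaults are the package's own
choice and every score is verifiable against an exhaustive enumeration
oracle in the tests. A gap of length $k$ costs
$\mathrm{open} + (k-1)\,\mathrm{extend}$. `U` and `T` are identical for
scoring, and traceback ties are broken deterministically
(diagonal > up > left) so alignments are reproducible. Each called site is
then exactly one of:

* **conserved** — its column maps and the counterpart position is an
  annotated known site (optionally also requiring identical bases);
* **unmapped** — its column is a gap;
* **unique** — otherwise.

A *list mode* consumes pre-resolved conserved-site label lists directly,
which is how the package reproduces published per-species set
intersections and differences without the full cross-species annotation.

## Translation efficiency (deltaTE-style)

Paired Ribo-seq (RPF) and RNA-seq libraries from the same lysate are
modelled jointly. The estimand is the condition effect on translation
efficiency, i.e. the **condition × assay interaction**: the RNA condition
coefficient is `log2FC_RNA` and the interaction is `log2FC_TE`.

Two routes estimate the same contrast:

* `method = "deseq2"` (default): the negative-binomial GLM
  `~ condition + assay + condition:assay` fitted with DESeq2, Wald test on
  the interaction — this *is* the deltaTE estimator. FDR is plain
  Benjamini–Hochberg on the raw interaction p-values (no independent
  filtering), since downstream category counts should partition the full
  gene set.
* `method = "ols"`: per-assay median-of-ratios size factors, ordinary least
  squares on $\log_2(\text{normalized count} + 0.5)$ with the same design,
  $t$-test on the residual df. This dependency-light route was the
  originally sketched design, but with three replicates per arm its
  per-gene variance estimate (8 residual df) is far too noisy: in the
  package's own simulations it recovers only a minority of planted effects
  where the NB GLM with cross-gene dispersion sharing recovers the large
  majority (see `test-translatome.R` and the acceptance suite). It is kept
  as a cross-check and for degenerate inputs, not as the default.

Per-replicate display TE is $(\mathrm{TPM}_{RPF} + p)/(\mathrm{TPM}_{RNA} + p)$
with a TPM floor $p = 0.1$ guarding unexpressed genes. Quadrant categories
use a symmetric $\pm 0.8$ log2 cutoff: `TE_down` is
$\log_2\mathrm{FC}_{TE} < -0.8$ with $|\log_2\mathrm{FC}_{RNA}| < 0.8$,
`TE_up` symmetric, `RNA_down`/`RNA_up` the transpose, `concordant` both,
`unchanged` neither; two FDR tiers (0.05 strict, 0.25 relaxed) are
recorded per gene rather than gating the category itself. Cell-type
attribution is a straight contingency of categories against a
gene → cell-type mapping, with `unassigned` for unmapped genes.

## Ribosome-profiling QC

Read-length filters are closed intervals — $[20, 50]$ nt after trimming,
$[30, 40]$ nt for RPF selection. The reading frame of a read is
$(\text{5' end} - \text{CDS start}) \bmod 3$ from raw 5' ends, with no
P-site offsetting (raw periodicity only). Sample concordance reports
Spearman's $\rho$ (average ranks on ties) plus an OLS $R^2$ on log2 values
of positive pairs.

## What the simulator emulates — and what it does not

The generator states a world and stays there:

* **Fragmentation** is independent Poisson counts per bond with rate
  $\text{depth} \times \text{noise}_{rk} \times (1 - f_k)$, not full
  fragment sampling: the Methscore only sees per-position end counts, and
  the independent-Poisson form keeps every expectation analysable.
  Each end track draws its own Poisson count (not every fragment end is
  recovered), but the two tracks of a replicate share the lognormal
  per-position noise factor (cv default 0.2), mimicking sequence-dependent
  cleavage bias.
* **Design defaults** mirror a typical knockdown experiment of this kind:
  6 control vs 3 knockdown replicates for RiboMeth-seq; sequencing depth
  on the rRNA is a free parameter with default 200 mean end counts per
  bond, a mid-range value for rRNA-saturated libraries. Planted fractions are $f \in [0.9, 1]$ for full and
  $[0.65, 0.85]$ for partial sites, i.e. the fractions the thresholds are
  meant to recover.
* **Counts for the TE arm** are negative binomial per gene with
  RNA mean $\mu 2^{\beta_{RNA}}$ and RPF mean
  $\mu 2^{\beta_{RNA}+\beta_{TE}}$ in the treated condition
  (default $\mu = 500$, dispersion 0.05, 3 + 3 replicates, 2000 genes with
  100 planted TE-down at $\beta_{TE} = -1.5$).
* **RPF reads** start on codons with a frame-0 weight (default 0.75, a
  typical in-frame fraction for a good library) and uniform lengths in
  $[30, 40]$.

Not modelled, deliberately: read-level FASTQ output, alignment error,
snoRNA guide structure, the planarian 28S hidden break (28S is one
contiguous reference), library-composition artefacts, and any correlation
between RNA and RPF counts of the same biological replicate. A green test
on this world therefore establishes that the *estimators* behave as
specified under their own assumptions — not that real libraries satisfy
those assumptions.

## Reproducibility and plumbing

Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state. `run_pipeline()` writes a manifest (package
version, seed, parameters, per-stage outputs) with paths relative to the
output directory and no timestamps, so identical config + seed reproduce
byte-identical output trees. Configuration files are JSON (no YAML parser
is available in the supported dependency set); TSV is used for matrices
and tracks, CSV for annotation tables, bedGraph is read and written as
standard 0-based half-open and converted to the internal 1-based inclusive
coordinates in a single function. SAM input is handled by a minimal
purpose-built parser (flags, CIGAR reference span, soft clips ignored)
because the supported binary-free toolchain has no plain-text SAM reader;
reads are assumed sense-stranded to the rRNA by default, with
`strand_aware = TRUE` honouring the reverse flag.

## Known limitations

* The Methscore flank mean assumes locally flat cleavage propensity;
  closely spaced sites (within $w$) depress each other's neighbourhoods
  and bias both scores downward. The simulator's 2-nt minimum spacing does
  not protect against this; real clustered sites (e.g. adjacent Gm/Am
  pairs) deserve joint review.
* `flagged` ($M = 1$) sites are excluded from consensus rather than
  adjudicated; at very high depth a genuinely fully protected bond can
  legitimately yield zero counts.
* The OLS TE route underestimates significance at small $n$ by
  construction (see above); its estimates agree closely with the GLM, its
  p-values do not.
* Spearman/R² concordance is reported per sample pair; no batch model.
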