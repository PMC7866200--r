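---
title: "Rank-aggregation meta-analysis with promoter TFBS enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-aggregation meta-analysis with promoter TFBS enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the methods account of `tfbsmeta`: the statistical model
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the problem left them open.

# The meta-analysis model

## Per-study inclusion filter

A gene enters the meta-analysis from one study if it satisfies, with
strict inequalities,

* |fold change| > 1.25, interpreted symmetrically on the log scale
  (up: FC > 1.25; down: FC < 1/1.25), so the up and down arms are
  mirror images;
* adjusted p below the platform cutoff: 0.05 for RNA-seq, 0.1 for DNA
  microarray. CAGE takes the RNA-seq cutoff, since both are count-based
  sequencing assays;
* a translated biotype (protein-coding, polymorphic pseudogene, or a
  translated pseudogene class) — regulatory inference downstream is only
  meaningful for genes with promoters driving translated products.

The filter is monotone: strengthening a gene's evidence can never remove
it. Retained genes are ordered per direction by ascending adjusted p,
ties broken by descending |log2 FC| then gene id, so that ranking is
fully deterministic. The ranking key is a design choice — a DE table
carries two orderings (significance and effect size) and the
significance ordering is the one the per-study tests were powered for.

## Normalized ranks

The normalized rank of a retained gene is its position divided by the
number of *measured, biotype-eligible* genes in that study — not by the
length of the retained list. Genes measured but not retained implicitly
occupy rank 1. Two considerations force this:

1. Under the null, the rank of a random gene in a full ranking of the
   candidate universe is uniform on (0, 1], which is exactly the
   assumption the binomial order-statistic score needs. Position within
   the short retained list is uniform for *every* gene, signal or not,
   and carries no information.
2. Studies on different platforms measure different universes. Dividing
   by each study's own eligible-universe size keeps ranks comparable
   across platforms, and distinguishing "measured but not differentially
   expressed" (rank 1) from "not measured" (no rank; the study drops out
   of the gene's n) keeps absence of evidence separate from evidence of
   absence.

## The rho score and DEG call

For a gene with ascending ranks $r_{(1)} \le \dots \le r_{(m)}$ across
the $n$ studies measuring it,

$$\rho = \min_{k \le m} \; P\!\left(X \ge k\right), \qquad
  X \sim \mathrm{Binomial}(n, r_{(k)}),$$

the probability that at least $k$ of $n$ uniform ranks fall at or below
the $k$-th observed rank. Ranks equal to 1 contribute a tail of 1 and
can never attain the minimum, so only retained ranks need evaluating.
The tail is computed through the regularized-incomplete-beta identity
(`pbinom`), which is stable for the minute probabilities that consistent
genes reach; the single-study case returns the rank itself exactly.

Because $\rho$ is a minimum over $n$ dependent tails, `min(1, rho * n)`
is a conservative (Bonferroni) p-value. Benjamini–Hochberg across all
eligible genes gives `padj`; the DEG call is `padj < 0.01`, strict. Both
adjustments are available (`adjust = "BH"` or `"bonferroni"`); BH across
genes is the default because the per-gene Bonferroni bound already pays
for the minimum over k, and the genome-wide multiplicity is the one the
0.01 threshold is meant to control. A gene must be measured in at least
two studies (`min_studies = 2`) — a "meta-analytic" call from one study
would be just that study's rank.

On null data (random permutation lists) the observed fraction of genes
with `p_bonf < 0.05` is ~0.03, confirming the bound is conservative; on
the synthetic study conditions (5000 genes, 10 studies, 100 planted
up-regulated genes, penetrance 0.7) sensitivity is ~0.97 with zero false
positives at `padj < 0.01`.

# Promoters and motif scanning

## Windows and coordinates

Promoters span −1500..+500 around the TSS, 0-based half-open: 1500
upstream bases, the TSS base at offset 1500, and 499 further downstream
bases — 2000 bp exactly. Whether "+500" includes base +500 is not
decidable from the printed window; the half-open reading makes the
arithmetic exact and testable and is applied on both strands (minus-
strand windows are `[pos − 499, pos + 1501)`, reverse-complemented so
offset 0 is always the −1500 position in transcription coordinates).
The TSS is the most abundant transcript's start; ties break to the
5′-most position on the gene's strand, then transcript id. Condition-
specific TSS choice (e.g. promoter shifts after an acute stimulus) is
supported by re-running `select_tss()` on a condition-specific abundance
table; no isoform-switch detection is attempted.

## Scoring and threshold calibration

Matrices are scored in bits: `log2` odds of the pseudocount-smoothed
column probability over the background, with the pseudocount (default 1)
distributed according to the background so zero counts stay finite.
Unknown bases score 0 bits (= background). Both strands are scanned;
minus-strand hits are reported in forward coordinates, and all
above-threshold windows are reported without merging — the overlap
statistic downstream defines its own geometry.

Thresholds are not p-values but empirical site frequencies: the least
stringent score whose both-strand hit rate on a background corpus does
not exceed the target (1/2000 bp for enrichment, 1/50 kb for the overlap
analysis), with the number of scannable forward-strand positions as the
denominator. Empirical calibration on the reference promoters themselves
(or any user background) matches "site frequency" as an observed rate
and needs no independence model of the background.

One numerical caveat, visible in the tests: the empirical score
distribution of a near-consensus matrix is effectively discrete (scores
cluster by mismatch count), so around a coarse tie the achievable rate
can jump from far below the target to far above it. The calibrated
threshold then honours the "at or below target" contract but may sit
well below the target rate. For matrices of ordinary information content
the distribution is fine-grained and an independently drawn background
of equal length reproduces the target within sampling error (±20% is
comfortable at 1 Mb).

# Enrichment statistics

Occurrence is binary at promoter level (≥ 1 hit). At a calibrated rate
of ≤ 1 site per 2000 bp, the expected number of sites per 2000-bp
promoter is at most 1, so binary occurrence loses little relative to
site counts while making the 2×2 table exact. The one-sided Fisher exact
test targets enrichment only (depletion is never interpreted). The
adjusted fold enrichment is operationalized as the lower bound of the
Woolf 99% CI of the odds ratio,
$\exp(\ln \mathrm{OR} - z_{0.995}\sqrt{1/a + 1/b + 1/c + 1/d})$, with
the Haldane–Anscombe +0.5 applied to all cells iff any cell is zero —
the central stand-in decision of this module, since the commercial
platform's exact "statistically corrected odds ratio" is unpublished. It
has the right qualitative behaviour: always below the OR for enriched
tables, increasing toward it as samples grow at fixed proportions, and
penalising estimates built on near-empty cells.

FDR (BH) is computed across the matrices of one analysis — one
(intervention, direction, time point) column — matching how per-column
heat maps are reported. A TF owning several matrices takes the maximal
FE\_adj, with the minimal FDR recorded alongside; `significant` means
FE\_adj > 1.25 and FDR < 0.05 (strict, as printed), `highly_enriched`
additionally FE\_adj > 1.5.

# Overlap statistic and clustering

A motif of TF X is "overlapped" iff a motif of a *different* TF on the
same promoter covers strictly more than half of X's own length.
"Half the length" is resolved to the focal motif's length because
matrices differ in length; the asymmetric per-motif reading is the one
that yields a well-defined per-TF percentage. Same-TF overlaps are
excluded by default — a TF's own matrix variants co-locating is no
evidence of heterodimers. Hit intervals are the full matrix length; no
separate core annotation exists in the flat-file dialects parsed here.
The statistic is meaningful at the sparse 1/50 kb calibration, where
chance overlap is rare.

MCL clustering adds self-loops (weight 1) to the weighted adjacency,
column-normalizes, and alternates expansion (matrix square) with
inflation (elementwise power 2, renormalize), pruning entries below
1e-10 each iteration, until the maximal entry change falls below 1e-6 or
200 iterations. Clusters are connected components of the converged
matrix's support; nodes with no edges become singletons. The
implementation is dense-matrix and intended for the dozens-of-TFs graphs
this analysis produces, not for genome-scale networks. Inflation 2 is
the conventional default; larger values fragment clusters faster.

# Synthetic data: what it emulates, and what not

`simulate_meta_tables()` emulates *post-adjustment* DE tables: null
genes draw adjusted p uniformly and log2 fold changes from
N(0, 0.25); a planted true DEG passes any one study's filter with
probability `penetrance` (default 0.7), in which case its adjusted p is
the platform cutoff times a Beta(0.1, 1) draw — guaranteed below the
cutoff and concentrated near zero, which makes the per-study pass count
exactly Binomial(penetrance) and lets truth-based tests count passes
directly — and its |log2 FC| is log2(1.25) plus an Exponential(mean 0.5)
excess with the planted sign. Ten percent of gene × study cells are
unmeasured; half the studies are labelled microarray. These are
calibration choices for a realistic mid-sized meta-analysis — published
effect-size distributions per study are not available to estimate them
from — chosen once and not tuned. The generator does **not** simulate
raw reads or intensities, between-gene correlation, platform-specific
probe effects, or study-level confounding; passing tests demonstrate the
machinery recovers planted structure under honest noise, not that real
studies meet these assumptions.

`simulate_promoter_corpus()` plants column-wise PWM draws on random
strands at non-overlapping offsets in i.i.d. background at 41% GC (the
human genome-wide value); prevalence defaults to 0.4 among 300 "DEG"
promoters against 5000 clean reference promoters. Real promoters are
CpG-structured and repeat-laden; the i.i.d. background is deliberately
the cleanest case for calibration.

`simulate_ppi_edges()` is a standard planted-partition model with
weights uniform on [0.4, 1); `simulate_pwm_library()` always includes a
near-consensus and a degenerate matrix so tests cover both entropy
extremes. One global seed fans out to per-generator seeds through a
fixed hash (`derive_seed`), so modules are independently reproducible
and byte-identical under a fixed seed.

# Pipeline, sizes, and limitations

`run_pipeline()` chains the synthetic stages end to end, logs one
structured count line per stage, and writes an md5-hashed manifest
embedding the resolved configuration; reruns under the same
configuration are byte-identical. Real-data analyses compose the same
exported functions on their own files (study TSVs, genome FASTA,
transcript tables, TRANSFAC- or JASPAR-dialect matrix files, STRING-like
edge lists); time-point analyses are just separately named intervention
blocks — no temporal model is imposed.

The shipped tests run the rank-aggregation stages at the full study
conditions (5000 genes × 10 studies; 5000-gene null calibration) and the
sequence stages at 300 + 5000 × 2000-bp promoters with 1-Mb calibration
backgrounds; the end-to-end determinism check uses a reduced
configuration (600 genes × 6 studies, 290 promoters of 1200 bp, three
matrices) chosen as the smallest size at which every stage still has
signal to find.

Known limitations: the FE_adj formula is a documented surrogate for an
unpublished statistic; bit-score log-odds stand in for the platform's
proprietary score normalization; empirical calibration inherits the
granularity of the background score distribution (see above); the MCL
implementation is dense; and promoter extraction assumes gene-keyed,
pre-collapsed input tables — probe-to-gene mapping and annotation
reconciliation must happen upstream.
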