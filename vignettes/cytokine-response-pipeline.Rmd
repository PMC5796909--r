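---
title: "Methods: cytokine-response transcriptomics with cytoresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytokine-response transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices
behind its defaults, and what validation on synthetic data does and does
not establish. Code chunks are illustrative and not evaluated at build
time; the test suite and `scripts/acceptance.R` run every computation the
vignette refers to.

## 1. The experimental structure being modelled

The pipeline targets multi-cytokine stimulation experiments in cultured
epithelial cells: several IL-1-family cytokines and an unstimulated
control, measured by bulk RNA-seq at an early (8 h) and a late (24 h)
time point, with replicate cultures drawn from a small number of donor
cell lines. Cell line is a blocking factor — donor-to-donor expression
differences are large relative to treatment effects — so every
differential-expression model carries it as a covariate, and the paired
t-test utilities pair samples by line.

## 2. Differential expression

**Detection filter.** A gene is detectably expressed in a sample when its
counts-per-million exceeds 0.25 (strictly), and is retained when detected
in at least `ceiling(0.25 * n_samples)` samples. The filter uses raw
library sizes because it precedes normalization in the pipeline's order of
operations. Some workflows additionally gate detection on an
abundance-confidence bound computed from transcript-length models; such a
mask depends on information outside a count matrix, so
`detect_expressed()` accepts it as an optional user-supplied logical
vector (`extra_mask`) rather than computing it.

**TMM normalization.** `tmm_factors()` implements the weighted trimmed
mean of M-values: reference column = the sample whose upper-quartile cpm
is closest to the mean upper-quartile; per sample, M and A values over
genes non-zero in both columns; double trimming (30% two-sided on M, 5%
on A, rank-based); inverse-asymptotic-variance weights; factors
re-centered to geometric mean 1. Depth is carried by library sizes — a
pure depth change leaves factors at 1.

**Dispersion.** The NB dispersion is estimated by Cox–Reid adjusted
profile likelihood. Per gene, the adjusted profile likelihood at a
candidate `phi` is the NB log-likelihood at the IRLS fit minus half the
log-determinant of `X'WX` (the Fisher information of the mean
parameters), which corrects the downward bias of plug-in ML dispersion
estimates at small n. Genes are grouped into up to 20 equal-occupancy
abundance bins (never fewer than 20 genes per bin); a shared `phi` per
bin maximizes the summed adjusted likelihood by golden-section search
over `log10(phi)` in `[-6, 1]`; bins with likelihood flat toward zero
dispersion collapse to the lower boundary. Binned estimates are smoothed
by local linear regression (loess, span 0.5, degree 1) on abundance, and
each gene takes the trend value at its own average log2-cpm (linear
interpolation, flat extrapolation). Bins larger than `bin_cap` (100) are
evaluated on a systematic subsample: the objective is a sum over
exchangeable genes, so a subsample estimates the shared bin dispersion
without bias and keeps the search inside practical runtimes. On
simulations the trend recovers a constant true dispersion of 0.1 within
a few percent and collapses to ~1e-6 on Poisson data; the test suite
asserts both.

**The LRT.** Per gene, full and reduced NB GLMs (log link, log effective
library size offset) are fitted by IRLS — normal equations solved
directly (the designs have a handful of columns), convergence on the
relative deviance change at 1e-8 within 100 iterations, linear predictor
clamped to ±30 to prevent overflow. The statistic is
`max(0, 2 * (ll_full - ll_reduced))` with chi-square degrees of freedom
equal to the design-rank difference; non-estimable designs error out
rather than silently aliasing, and genes that fail to converge are
flagged with missing p (reported via a message) and excluded from BH.
The reported log2 FC is the tested GLM coefficient divided by `log(2)` —
defined even with zero counts, shrinkage-free; display-scale abundances
instead use `log2(cpm + 0.25)`. All p-values are two-sided and all
calling thresholds are strict inequalities (FDR < 0.10 with FC > 2.00 or
FC < 0.50; the looser heatmap preset uses raw P < 0.05 with FC > 1.50 or
FC < 0.67).

**Interaction test.** Time dependence of a cytokine response is the LRT
of `~ treatment * time + cell_line` against the additive model (df = 1).
Significant genes are classified by the signs of the two per-time log2 FC
estimates read off the interaction parametrization (up-then-down,
down-then-up, same-sign).

## 3. Response-pattern analytics

Profiles are gene × condition log2 FC matrices. Spearman correlations use
average ranks for ties; constant columns yield missing correlations with
a warning rather than an arbitrary number. Condition clustering is
average-linkage on 1 − rho; gene clustering is average-linkage Euclidean.

The SOM is trained online on a rectangular grid: codebooks initialized on
the first two principal components (a deterministic, data-aligned start),
learning rate decaying linearly 0.05 → 0.01, Gaussian neighborhood with
radius shrinking linearly from half the larger grid dimension to 0.5,
presentation order seeded. Final assignments are recomputed as exact
nearest codebooks, and the tests verify this exhaustively. Grid size and
epochs are config arguments, not inferences: nothing in the underlying
methodology pins them down, so they are exposed and recorded.

Cluster representatives are exact medoids (lowest average Euclidean
distance to the other members), ties broken to the lexicographically
smallest gene id for reproducibility. Chernoff-face parameters clip log2
FCs to ±3 before the affine map to [0, 1]; the clip keeps a single
extreme gene from flattening every other feature, and ±3 (8-fold) spans
the response range the calling thresholds consider meaningful.
Mahalanobis coverage ellipses use the empirical quantile of squared
distances, so exactly `floor(coverage * n)` points fall inside or on the
boundary when distances are distinct; for large bivariate normal samples
the squared radius approaches the chi-square(2) quantile (2.77 at 75%),
which the tests check.

## 4. Set and rank statistics

The universe for every enrichment test is the detected-gene universe, not
an annotation's full gene list: DEGs are compared against the other
expressed genes, and annotation genes outside the universe are dropped
before testing. Over-representation uses the one-sided upper
hypergeometric tail (equivalently one-sided Fisher); rank-overlap curves
report per-k one-sided Fisher p-values plus a null band (mean `k^2/N`,
95th hypergeometric percentile — the band construction is a
package choice, recorded in the curve output). Cumulative-overlap
enrichment tests set-member ranks against non-member ranks with the
Wilcoxon rank-sum: exact by enumeration when the smaller group has at
most 10 members, normal approximation with tie and continuity corrections
otherwise; two-sided and both one-sided p-values are reported because
enrichment direction conventions vary across uses.

## 5. SNP proximity

Coordinates are 0-based half-open. Gene–SNP distance is 0 inside
`[start, end)` and the gap to the nearer edge otherwise; a TSS mode is
available, and the output metadata records which convention produced a
table. The edge convention is the default because "within d of a locus"
reads most naturally as a gap from the gene body; strand never affects
edge distances (asserted as an invariant). Genes on chromosomes without a
trait SNP receive an infinite sentinel and never count as proximal.
Percent-overlap curves are non-decreasing step functions of the distance
cutoff; each cutoff gets a one-sided Fisher test of DEG over-representation
among proximal genes. The default grid (10, 25, 50, 100, 200, 500 kb)
includes the 200 kb point at which such analyses are conventionally read.
One caveat the tests make explicit: the Fisher null assumes the DEG set is
exchangeable with the background; a DEG set of *adjacent* genes shares
SNPs and inflates the per-cutoff type-I error, so calibration claims are
made for scattered sets.

## 6. Motif scanning and enrichment

PWMs are position-probability matrices (rows sum to 1); MEME-minimal and
JASPAR count formats are parsed by small readers (count matrices are
row-normalized on read). Scoring is log2 odds against the background
composition with a pseudocount of 1e-3 added to probabilities first —
otherwise a zero-probability cell forbids any mismatch at that position.
A window is a hit at relative score `min + 0.8 * (max - min)` by default;
overlapping hits count individually, both strands are scanned via the
reverse complement (a palindromic site therefore counts once per strand —
a documented convention, not a bug), and windows containing N never fire.
The scanner is validated against a naive per-window rescoring oracle on
random sequence/motif pairs.

Enrichment fits, per motif, `logit P(DEG) = a + b * count + s(GC)` with
`s` a natural cubic spline basis of 4 degrees of freedom, and tests
`b = 0` by likelihood-ratio chi-square; BH runs across converged motifs.
The GC smooth is there because promoter GC content confounds motif
content and DEG status; the tests construct a GC-confounded null in which
the unadjusted model grossly inflates type-I error while the
spline-adjusted model stays at nominal. Degenerate predictors
(constant counts) and non-converged or separated fits are flagged and
excluded from BH with a warning. Enrichment direction is the sign of `b`,
retaining depletion information without a second one-sided test. Promoter
length is constant (5 kb) in this pipeline, so length is not a covariate;
spline df and the scan threshold are config-exposed and recorded in scan
metadata.

## 7. The synthetic generator: what it emulates, what it does not

Defaults were chosen once, as the study conditions:

* **Design**: 4 cytokines + control; n = 2 at 8 h (lines A, B), n = 3 at
  24 h (lines A, B, C) — the replication of the emulated experiment.
* **Baseline abundance**: mean counts log-uniform in [50, 800]. The
  generator emulates the *detected* (expressed-gene) stratum on which
  every downstream analysis operates, not the full transcriptome with its
  mass of near-zero genes.
* **Dispersion**: `phi(mu) = 0.04 + 1/mu`. A biological CV of ~20% is
  typical for technically clean primary cultures once line effects are
  blocked; the `1/mu` term gives the falling trend seen in real data.
* **Cell-line offsets**: gene × line Gaussian, sd 0.3 (log scale) —
  enough to make line the dominant variance factor, as observed, while
  remaining absorbable by the covariate.
* **Effects**: planted |log2 FC| = 2, i.e. fold change 4. This matches
  the calling threshold's intent (FC > 2 with estimation noise on top)
  rather than an inferred effect-size distribution, which the emulated
  study does not report.
* **Class proportions**: 4% shared-up, 1% shared-down, 2%
  cytokine-specific, 1% time-flip — a shared-dominant mixture mirroring
  the reported preponderance of shared over specific responses.
* **Depth**: per-sample depth factors log-uniform over a 2-fold range —
  enough to exercise TMM without extreme composition artifacts.
* **Genome**: one chromosome per 1000 genes, 100 kb start spacing, 10 kb
  gene bodies — closed-form proximity expectations.

The generator does **not** emulate: read-level error (counts are drawn,
not aligned), transcript isoforms, correlated gene modules beyond the
planted classes, LD structure among SNPs, or dinucleotide/repeat
structure in promoters (bases are i.i.d. given GC). Passing recovery
tests therefore demonstrates that the statistical machinery is correct
and calibrated under its stated model — not that the model captures every
property of real libraries.

Ranked-signature simulation mixes normal scores of the truth ordering
with Gaussian noise and solves the mixing weight by root finding on the
realized Spearman statistic. When most genes are null the truth has heavy
ties, which cap the attainable rank correlation (average-rank ties shrink
the statistic); the function errors when the target exceeds that ceiling
rather than silently under-delivering. The workflow's lesional-signature
stand-in uses a target of 0.3, of the magnitude seen between in vitro
response rankings and diseased-tissue signatures.

## 8. Numerical and reproducibility choices

Every stochastic function takes a seed and restores the caller's RNG
state; the pipeline derives per-stage sub-seeds from one global seed so
that toggling a stage never shifts another stage's randomness, and output
provenance headers hash only the scientific parameters (not output paths
or stage toggles). Ties everywhere break lexicographically or to the
first index, deterministically. Exact-test paths switch to enumeration
only below documented size cutoffs (Wilcoxon: smaller group ≤ 10), and
the test suite pins both paths to brute-force oracles.

Problem sizes in the validation suite — 2000-gene simulations for
calibration and end-to-end recovery, 500-motif calibration panels, 50-seed
detection studies — were chosen as the smallest sizes at which the binomial
noise of the measured rates is well inside the asserted bands.

## 9. Known limitations

* Dispersion is a trend value per gene; no empirical-Bayes moderation or
  gene-wise shrinkage, and no quasi-likelihood variant. Numerics will not
  exactly match any specific external package, by design.
* The GAM-logistic motif model uses a fixed spline basis rather than
  penalized smoothness selection; with a constant promoter length this is
  the model's only smooth term.
* The FPKM-confidence detection mask is consumed, never computed.
* SOM training is the classical online algorithm; batch training and
  toroidal grids are out of scope.
* Conditional (parent–child eliminating) ontology testing is out of
  scope; enrichment is plain hypergeometric against the detected-gene
  universe.
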