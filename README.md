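# cytoresponse

Transcriptomic analysis of multi-cytokine stimulation experiments in
epithelial cells, built as a tested, reusable R pipeline with a synthetic
data generator for validation.

The motivating setting is bulk RNA-seq of primary keratinocytes stimulated
with IL-1-family cytokines (IL-1B, IL-36A, IL-36B, IL-36G) versus
unstimulated control at two time points (8 h and 24 h), with replicate
cultures from distinct donor cell lines. The scientific questions the
pipeline answers: which genes respond to each cytokine, which respond to
*all* of them in the same direction at both times (the shared signature),
which responses flip sign between early and late time points, and whether
the shared signature is enriched near disease-associated GWAS loci and for
transcription-factor binding motifs in upstream regions.

## The statistical core

**Differential expression.** Counts are filtered for detectable expression
(cpm strictly greater than 0.25 in at least 25% of samples), normalized by
the weighted trimmed mean of M-values (TMM), and tested gene by gene with a
negative binomial generalized linear model:

    y_gs ~ NB(mu_gs, phi_g),   log mu_gs = o_s + x_s' beta_g

with offset `o_s` the log effective library size and dispersion `phi_g`
taken from a trend fitted by Cox–Reid adjusted profile likelihood (the
adjustment subtracts half the log-determinant of the Fisher information of
the estimated mean parameters). The per-gene test is a likelihood-ratio
chi-square comparing the full model (treatment + cell line) against the
reduced model (cell line only); p-values get Benjamini–Hochberg FDR
adjustment, and DEGs are called at FDR < 0.10 with FC > 2.00 or FC < 0.50
(strict inequalities). A treatment-by-time interaction LRT finds
time-dependent responses and classifies their sign patterns.

**Downstream analytics.** Gene-by-condition log2 FC profiles feed Spearman
condition correlations, average-linkage clustering (distance 1 − rho),
principal-component response vectors (arrows from the control group's
PC mean to each cytokine's), a self-organizing map of response profiles,
exact medoid representatives per gene cluster, and Chernoff-face parameter
mapping. Set statistics include top-k rank-overlap curves with one-sided
Fisher tails and a hypergeometric null band, cumulative-overlap gene-set
enrichment with Wilcoxon rank-sum p-values (exact by enumeration for small
sets), hypergeometric over-representation with BH adjustment,
SNP-proximity enrichment over a grid of distances, and PWM promoter
scanning with GC-spline-adjusted logistic enrichment of motif counts.

**Synthetic generator.** `simulate_counts()` reproduces the study's
structure — 4 cytokines × 2 times versus control, n = 2 (8 h) or 3 (24 h)
replicates from 3 cell lines, NB counts with trend
phi(mu) = phi0 + a/mu, gene-by-line offsets — and plants shared up/down,
cytokine-specific and time-flip gene classes recorded in a ground-truth
table. Companion generators produce ranked signatures with a calibrated
rank correlation, promoters with planted motif consensus instances, and
SNP catalogs with SNPs planted near target genes.

## Worked example

```r
library(cytoresponse)
cfg <- sim_config(n_genes = 1000, seed = 1)
s   <- simulate_counts(cfg)
de  <- run_de(s$counts, s$design, "IL1B", "24h")
head(de[order(de$p), c("gene_id","log2fc","avg_log_cpm","lr_stat","q")], 3)
#>        gene_id log2fc avg_log_cpm lr_stat        q
#> g00299  g00299   2.53       12.30    97.3 3.64e-20
#> g00642  g00642   2.51       12.14    96.9 3.64e-20
#> g00485  g00485   2.81        9.54    90.4 6.35e-19
calls <- call_degs(de)                  # FDR < 0.10, FC > 2 or < 0.5
table(calls$direction)
#> down   up
#>   20   60
```

The three strongest genes have estimated log2 fold changes near the
planted value of 2 (FC ≈ 4) at high abundance; of the 80 calls, all 40
planted shared-up genes are recovered as up-DEGs, with the remaining calls
covering the other planted classes and a small number of false positives
controlled by the FDR threshold.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate counts, design, truth table, gene loci |
| `02_differential_expression.R` | 8 contrasts + interaction tests, DEG calls |
| `03_response_patterns.R` | correlations, clustering, PC arrows, SOM, medoids, faces |
| `04_shared_signature_enrichment.R` | 8-way shared signature, rank/set enrichment |
| `05_gwas_proximity.R` | SNP catalog, proximity enrichment, nearest-SNP table |
| `06_motif_enrichment.R` | promoter scan, GC-adjusted motif enrichment |

Each stage reads the previous stage's TSVs, so they run in order:
`for f in analysis/0*.R; do Rscript "$f"; done`. A single-call
orchestration with provenance headers and a checksummed manifest is also
available as `run_pipeline(pipeline_config(...))`.

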