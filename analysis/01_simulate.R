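#!/usr/bin/env Rscript

## Stage 1: generate the synthetic stimulation study.
##
## Emulates the design of the keratinocyte experiment: 4 cytokines plus
## control at 8 h (n = 2, lines A/B) and 24 h (n = 3, lines A/B/C), NB
## counts with a trended dispersion, gene-by-line offsets, and planted
## response classes (shared up/down, cytokine-specific, time-flip).

suppressMessages(library(cytoresponse))

seed <- 20240101L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000, seed = seed)
s <- simulate_counts(cfg)
loci <- make_gene_loci(s$truth$gene_id)

meta <- c(paste("cytoresponse", packageVersion("cytoresponse")),
          paste("seed", seed))
wt <- function(x, f) cytoresponse:::write_tsv_meta(x, file.path(outdir, f),
                                                  meta)
wt(data.frame(gene_id = rownames(s$counts), s$counts, check.names = FALSE),
   "counts.tsv")
wt(s$design, "design.tsv")
wt(s$truth, "truth.tsv")
wt(loci, "gene_loci.tsv")

cat("Simulated", nrow(s$counts), "genes x", ncol(s$counts), "samples\n")
print(table(s$truth$class))
cat("Library sizes:", paste(range(colSums(s$counts)), collapse = " - "),
    "\nOutputs in", outdir, "\n")
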