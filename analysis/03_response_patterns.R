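#!/usr/bin/env Rscript

## Stage 3: global response-pattern analytics.
##
## Builds the gene x condition log2 FC matrix from the per-condition DE
## tables, then: Spearman correlations among conditions, average-linkage
## condition dendrogram (distance 1 - rho), gene clustering, PC response
## vectors, a self-organizing map of response profiles, per-cluster medoid
## representatives, and Chernoff-face parameters for each condition.

suppressMessages(library(cytoresponse))

ind <- "results/de"
outdir <- "results/patterns"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

files <- list.files(ind, pattern = "^de_.*\\.tsv$", full.names = TRUE)
de_list <- lapply(files, cytoresponse:::read_tsv_meta)
names(de_list) <- sub("^de_(.*)\\.tsv$", "\\1", basename(files))

common <- Reduce(intersect, lapply(de_list, `[[`, "gene_id"))
de_list <- lapply(de_list, function(d) d[match(common, d$gene_id), ])
profile <- build_response_profile(de_list)
cat("Response profile:", nrow(profile), "genes x", ncol(profile),
    "conditions\n")

rc <- response_correlation(profile)
write.table(data.frame(condition = rownames(rc), rc, check.names = FALSE),
            file.path(outdir, "condition_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
hc <- cluster_conditions(rc)
cat("Condition dendrogram merge heights:",
    paste(round(hc$height, 3), collapse = ", "), "\n")

## samples in PC space, arrows from CTL to each cytokine at 24 h
cts_df <- cytoresponse:::read_tsv_meta("results/synthetic/counts.tsv")
counts <- as.matrix(cts_df[, -1]); rownames(counts) <- cts_df$gene_id
design <- cytoresponse:::read_tsv_meta("results/synthetic/design.tsv")
expr <- log2(cpm(counts)[detect_expressed(counts), ] + 1)
arrows <- pc_response_vectors(expr, design, time = "24h")
write.table(arrows, file.path(outdir, "pc_response_vectors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

som <- fit_som(profile, grid = c(4, 4), epochs = 50, seed = 11)
node_means <- sapply(colnames(profile), function(cn)
  summarize_som(som, profile, cn))
write.table(data.frame(node = seq_len(nrow(som$codebook)), node_means,
                       check.names = FALSE),
            file.path(outdir, "som_node_means.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cl <- cluster_genes(profile, k = 15)
reps <- select_representatives(profile, cl)
write.table(data.frame(cluster = names(reps), gene_id = reps,
                       size = as.vector(table(cl)[names(reps)])),
            file.path(outdir, "cluster_representatives.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Cluster medoid representatives:", paste(head(reps, 5), collapse = ", "),
    "...\n")

faces <- do.call(rbind, lapply(colnames(profile), function(cn) {
  fs <- chernoff_mapping(profile, unname(reps)[1:15], cn)
  data.frame(condition = cn, feature = names(fs$features),
             value = unname(fs$features))
}))
write.table(faces, file.path(outdir, "face_parameters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote patterns outputs to", outdir, "\n")
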