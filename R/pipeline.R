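#' Default pipeline configuration
#'
#' One config drives the full synthetic workflow: simulate -> differential
#' expression -> response patterns -> signatures -> SNP proximity ->
#' motifs. All statistical thresholds live here; a single global seed
#' deterministically derives per-stage substreams, so toggling one stage
#' never shifts another stage's randomness.
#'
#' @param seed global integer seed.
#' @param outdir output directory.
#' @param n_genes genes to simulate.
#' @param stages named logical vector of stage toggles.
#' @param sim list of overrides passed to [sim_config()].
#' @param fdr_max,fc_min,fc_max DEG thresholds.
#' @param k_max rank-overlap depth.
#' @param d_grid proximity distance grid (bp).
#' @param scan_threshold PWM relative score threshold.
#' @param som_grid SOM grid dimensions.
#' @param n_promoter_genes promoters are simulated/scanned for this many
#'   genes (capped for runtime; planted and background genes are retained
#'   proportionally).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "results",
                            n_genes = 2000,
                            stages = c(simulate = TRUE, de = TRUE,
                                       patterns = TRUE, signatures = TRUE,
                                       gwas = TRUE, motifs = TRUE),
                            sim = list(),
                            fdr_max = 0.10, fc_min = 2.00, fc_max = 0.50,
                            k_max = 500,
                            d_grid = c(10, 25, 50, 100, 200, 500) * 1000,
                            scan_threshold = 0.8,
                            som_grid = c(4, 4),
                            n_promoter_genes = 600) {
  cfg <- list(seed = seed, outdir = outdir, n_genes = n_genes,
              stages = stages, sim = sim, fdr_max = fdr_max,
              fc_min = fc_min, fc_max = fc_max, k_max = k_max,
              d_grid = d_grid, scan_threshold = scan_threshold,
              som_grid = som_grid, n_promoter_genes = n_promoter_genes)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Fields in the file override the [pipeline_config()] defaults; unknown
#' fields are rejected so typos surface immediately.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  if (!is.null(vals$stages)) {
    ## partial stage lists override the defaults stage by stage
    user <- unlist(vals$stages)
    st <- eval(formals(pipeline_config)$stages)
    st[names(user)] <- user
    vals$stages <- st
  }
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Collects every problem rather than failing fast.
#'
#' @param config a `pipeline_config` (or plain list).
#' @return list with `errors` (character vector, empty when valid).
#' @export
validate_config <- function(config) {
  errors <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        config$seed == round(config$seed), "seed must be a single integer")
  chk(is.numeric(config$fdr_max) && config$fdr_max > 0 &&
        config$fdr_max <= 1, "fdr_max must lie in (0, 1]")
  chk(is.numeric(config$fc_min) && config$fc_min > 0, "fc_min must be > 0")
  chk(is.numeric(config$fc_max) && config$fc_max > 0, "fc_max must be > 0")
  chk(is.numeric(config$k_max) && config$k_max >= 1, "k_max must be >= 1")
  chk(all(config$d_grid > 0), "d_grid must be positive")
  chk(config$scan_threshold > 0 && config$scan_threshold <= 1,
      "scan_threshold must lie in (0, 1]")
  for (path_field in c("counts_path", "design_path"))
    if (!is.null(config[[path_field]]) && !file.exists(config[[path_field]]))
      errors <- c(errors, paste0(path_field, " does not exist: ",
                                 config[[path_field]]))
  if (length(config$sim) > 0) {
    ok <- tryCatch({
      do.call(sim_config, c(list(n_genes = config$n_genes,
                                 seed = config$seed), config$sim))
      TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) errors <- c(errors, paste("sim:", ok))
  }
  list(errors = errors)
}

pkg_version <- function() {
  as.character(utils::packageVersion("cytoresponse"))
}

## hash of the scientific parameters only: where outputs go and which
## stages are toggled must not alter the provenance of stages that do run
config_hash <- function(config) {
  keep <- setdiff(sort(names(config)), c("outdir", "stages"))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[keep]), tf)
  unname(tools::md5sum(tf))
}

demo_motif_set <- function() {
  ## small built-in dictionary: an NF-kB-like, an ETS-like (GGAA core),
  ## an AP-1-like (TGACTCA) and two GC-skewed decoys
  strong <- function(id, cons, p = 0.94) {
    b <- c(A = 1, C = 2, G = 3, T = 4)
    m <- matrix((1 - p) / 3, nchar(cons), 4)
    for (i in seq_len(nchar(cons)))
      m[i, b[substr(cons, i, i)]] <- p
    pwm(id, m)
  }
  list(NFKB_like = strong("NFKB_like", "GGGAATTTCC"),
       ETS_like = strong("ETS_like", "ACAGGAAGTG"),
       AP1_like = strong("AP1_like", "TGACTCA"),
       GC_decoy = strong("GC_decoy", "GCGGCGGC"),
       AT_decoy = strong("AT_decoy", "ATTTAAAT"))
}

#' Run the full synthetic pipeline
#'
#' Executes enabled stages in dependency order, writes every output as a
#' TSV with '#'-prefixed provenance header lines, and returns (and writes)
#' a manifest listing outputs with md5 checksums. Identical config + seed
#' give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (length(v$errors) > 0)
    stop("invalid config:\n  ", paste(v$errors, collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(paste("cytoresponse", pkg_version()),
            paste("seed", config$seed),
            paste("config_hash", config_hash(config)))
  outputs <- character()
  emit <- function(x, name) {
    path <- file.path(config$outdir, name)
    write_tsv_meta(x, path, meta)
    outputs <<- c(outputs, path)
    path
  }
  stage_on <- function(s) isTRUE(config$stages[[s]])
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- NULL; de_tables <- NULL; calls <- NULL; shared <- NULL
  if (stage_on("simulate")) run_stage("simulate", {
    scfg <- do.call(sim_config, c(list(n_genes = config$n_genes,
                                       seed = derive_seed(config$seed, 1)),
                                  config$sim))
    sim <- simulate_counts(scfg)
    emit(data.frame(gene_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE), "counts.tsv")
    emit(sim$design, "design.tsv")
    emit(sim$truth, "truth.tsv")
  })

  if (stage_on("de")) run_stage("de", {
    if (is.null(sim)) stop("de requires the simulate stage")
    trts <- setdiff(unique(sim$design$treatment), "CTL")
    times <- unique(sim$design$time)
    de_tables <- list(); calls <- list()
    for (tr in trts) for (ti in times) {
      key <- paste(tr, ti, sep = "_")
      d <- run_de(sim$counts, sim$design, tr, ti)
      de_tables[[key]] <- d
      calls[[key]] <- call_degs(d, config$fdr_max, config$fc_min,
                                config$fc_max)
      emit(d[, c("gene_id", "log2fc", "avg_log_cpm", "lr_stat", "p", "q")],
           paste0("de_", key, ".tsv"))
    }
    it <- interaction_test(sim$counts, sim$design, trts[1],
                           fdr_max = config$fdr_max)
    emit(it, paste0("interaction_", trts[1], ".tsv"))
  })

  profile <- NULL
  if (stage_on("patterns")) run_stage("patterns", {
    if (is.null(de_tables)) stop("patterns requires the de stage")
    common <- Reduce(intersect, lapply(de_tables, `[[`, "gene_id"))
    trimmed <- lapply(de_tables, function(d)
      d[match(common, d$gene_id), , drop = FALSE])
    profile <- build_response_profile(trimmed)
    rc <- response_correlation(profile)
    emit(data.frame(condition = rownames(rc), rc, check.names = FALSE),
         "condition_correlation.tsv")
    som <- fit_som(profile, grid = config$som_grid, epochs = 20,
                   seed = derive_seed(config$seed, 3))
    node_means <- sapply(colnames(profile), function(cn)
      summarize_som(som, profile, cn))
    emit(data.frame(node = seq_len(nrow(som$codebook)), node_means,
                    check.names = FALSE), "som_node_means.tsv")
    cl <- cluster_genes(profile, k = 15)
    reps <- select_representatives(profile, cl)
    emit(data.frame(cluster = names(reps), gene_id = reps),
         "representatives.tsv")
    face <- chernoff_mapping(profile, unname(reps)[1:15],
                             colnames(profile)[1])
    emit(data.frame(feature = names(face$features),
                    value = face$features,
                    gene_id = face$genes), "face_spec.tsv")
  })

  if (stage_on("signatures")) run_stage("signatures", {
    if (is.null(calls)) stop("signatures requires the de stage")
    shared <- shared_signature(calls)
    emit(data.frame(gene_id = c(shared$up, shared$down),
                    direction = rep(c("up", "down"),
                                    c(length(shared$up),
                                      length(shared$down)))),
         "shared_signature.tsv")
    ## lesional-signature stand-in; modest rank correlation of the kind
    ## observed between in vitro responses and diseased-tissue signatures
    sig <- simulate_signature(sim$truth, 0.3,
                              seed = derive_seed(config$seed, 4))
    if (length(shared$up) > 0 &&
        length(shared$up) < nrow(sig)) {
      gs <- cumulative_overlap_gsea(sig, shared$up)
      emit(data.frame(r = gs$curve$r, overlap = gs$curve$overlap),
           "gsea_curve.tsv")
      emit(data.frame(p_two = gs$p_two, p_toward_top = gs$p_toward_top,
                      p_toward_bottom = gs$p_toward_bottom),
           "gsea_p.tsv")
    }
    class_sets <- split(sim$truth$gene_id, sim$truth$class)
    enr <- hypergeometric_enrichment(shared$up, class_sets,
                                     universe = sim$truth$gene_id)
    emit(enr, "class_enrichment.tsv")
  })

  if (stage_on("gwas")) run_stage("gwas", {
    if (is.null(shared)) stop("gwas requires the signatures stage")
    loci <- make_gene_loci(sim$truth$gene_id)
    planted_near <- sim$truth$gene_id[sim$truth$class == "shared_up"]
    snp <- simulate_snp_catalog(loci, planted_near,
                                n_background_snps = 50, n_planted = 20,
                                max_planted_distance = 2e5,
                                seed = derive_seed(config$seed, 5))
    deg <- if (length(shared$up) > 0) shared$up else planted_near
    pr <- proximity_enrichment(deg, loci, snp$catalog, "IBD",
                               d_grid = config$d_grid)
    emit(pr$table, "proximity_enrichment.tsv")
    emit(pr$nearest, "nearest_snp.tsv")
  })

  if (stage_on("motifs")) run_stage("motifs", {
    if (is.null(shared)) stop("motifs requires the signatures stage")
    motifs <- demo_motif_set()
    keep_deg <- sim$truth$class %in% c("shared_up", "shared_down")
    n_bg <- max(0, config$n_promoter_genes - sum(keep_deg))
    bg_ids <- sample_stable(sim$truth$gene_id[!keep_deg], n_bg,
                            derive_seed(config$seed, 6))
    sub <- sim$truth[keep_deg | sim$truth$gene_id %in% bg_ids, ,
                     drop = FALSE]
    pro <- simulate_promoters(sub, motifs[c("NFKB_like", "ETS_like")],
                              enrichment_rate_deg = 2, base_rate = 0.5,
                              seed = derive_seed(config$seed, 7))
    hits <- scan_motifs(pro$sequences, motifs,
                        threshold_fraction = config$scan_threshold)
    enr <- motif_logistic_enrichment(hits,
                                     deg = sub$class %in% c("shared_up",
                                                            "shared_down"),
                                     gc = pro$truth$gc_fraction,
                                     fdr_max = config$fdr_max)
    emit(enr, "motif_enrichment.tsv")
    emit(data.frame(gene_id = rownames(hits), hits, check.names = FALSE),
         "motif_hits.tsv")
  })

  manifest <- list(version = pkg_version(), seed = config$seed,
                   config_hash = config_hash(config),
                   outputs = lapply(setNames(outputs, basename(outputs)),
                                    function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

sample_stable <- function(x, n, seed) {
  with_seed(seed, sample(x, min(n, length(x))))
}
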