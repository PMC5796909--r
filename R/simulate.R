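#' Simulate a multi-cytokine stimulation count experiment
#'
#' Draws negative binomial counts for the design held in `config`: each
#' (treatment, time) group is measured in replicate cultures from distinct
#' cell lines, with gene-by-line offsets on the log scale, log-uniform
#' per-sample depth factors, and a trended dispersion
#' phi(mu) = phi0 + a / mu. Planted response classes (shared up/down across
#' all cytokines, cytokine-specific, time-flip) are recorded in a ground
#' truth table for recovery testing.
#'
#' The expected count is
#' mu_gs = depth_s * exp(b0_g + line_gl + log(2) * lfc_g(treatment, time)).
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts` (integer matrix, genes x samples),
#'   `design` (data.frame: sample_id, treatment, time, cell_line) and
#'   `truth` (data.frame: gene_id, class, baseline_log_mean,
#'   true_dispersion, and one `lfc_<treatment>_<time>` column per
#'   non-control condition).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    ng <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(ng))
    lines <- LETTERS[seq_len(config$n_cell_lines)]

    ## design: at each time point, replicates come from the first r lines
    des <- do.call(rbind, lapply(seq_along(config$times), function(it) {
      r <- config$replicates_per_group[it]
      expand.grid(cell_line = lines[seq_len(r)],
                  treatment = config$treatments,
                  time = config$times[it],
                  stringsAsFactors = FALSE)[, c("treatment", "time",
                                                "cell_line")]
    }))
    des$sample_id <- paste(des$treatment, des$time, des$cell_line, sep = "_")
    des <- des[, c("sample_id", "treatment", "time", "cell_line")]

    ## planted classes, assigned to random gene positions
    n_up <- round(config$pi_shared_up * ng)
    n_dn <- round(config$pi_shared_down * ng)
    n_sp <- round(config$pi_specific * ng)
    n_tf <- round(config$pi_timeflip * ng)
    cls <- rep("null", ng)
    idx <- sample.int(ng, n_up + n_dn + n_sp + n_tf)
    cls[idx[seq_len(n_up)]] <- "shared_up"
    cls[idx[n_up + seq_len(n_dn)]] <- "shared_down"
    cls[idx[n_up + n_dn + seq_len(n_sp)]] <- "il1b_specific"
    cls[idx[n_up + n_dn + n_sp + seq_len(n_tf)]] <- "timeflip"

    trts <- config$treatments[-1]       # non-control
    conds <- as.vector(outer(trts, config$times, paste, sep = "_"))
    eff <- config$effect_log2fc
    lfc <- matrix(0, ng, length(conds), dimnames = list(gene_ids, conds))
    for (tr in trts) {
      for (ti in seq_along(config$times)) {
        cn <- paste(tr, config$times[ti], sep = "_")
        lfc[cls == "shared_up", cn] <- eff
        lfc[cls == "shared_down", cn] <- -eff
        lfc[cls == "timeflip", cn] <- if (ti == 1L) eff else -eff
      }
    }
    ## cytokine-specific class responds to the first cytokine only
    for (ti in config$times)
      lfc[cls == "il1b_specific", paste(trts[1], ti, sep = "_")] <- eff

    b0 <- runif(ng, config$baseline_logmean_range[1],
                config$baseline_logmean_range[2])
    cl_off <- matrix(rnorm(ng * length(lines), 0, config$cellline_sd),
                     ng, length(lines), dimnames = list(gene_ids, lines))
    depth <- exp(runif(nrow(des), -log(config$depth_fold_range) / 2,
                       log(config$depth_fold_range) / 2))

    counts <- matrix(0L, ng, nrow(des),
                     dimnames = list(gene_ids, des$sample_id))
    for (s in seq_len(nrow(des))) {
      tr <- des$treatment[s]
      cn <- paste(tr, des$time[s], sep = "_")
      l2 <- if (tr == config$treatments[1]) 0 else lfc[, cn]
      mu <- depth[s] * exp(b0 + cl_off[, des$cell_line[s]] + log(2) * l2)
      phi <- config$phi0 + config$a / mu
      counts[, s] <- ifelse(phi < 1e-12,
                            rpois(ng, mu),
                            rnbinom(ng, mu = mu, size = 1 / phi))
    }

    mu0 <- exp(b0)
    truth <- data.frame(gene_id = gene_ids, class = cls,
                        baseline_log_mean = b0,
                        true_dispersion = config$phi0 + config$a / mu0,
                        stringsAsFactors = FALSE)
    lfc_df <- as.data.frame(lfc)
    names(lfc_df) <- paste0("lfc_", conds)
    truth <- cbind(truth, lfc_df)
    rownames(truth) <- NULL
    list(counts = counts, design = des, truth = truth)
  })
}

#' Mean planted log2 fold change across all conditions
#'
#' @param truth a truth table from [simulate_counts()].
#' @return named numeric vector, one value per gene.
#' @export
truth_mean_lfc <- function(truth) {
  cols <- grep("^lfc_", names(truth), value = TRUE)
  if (length(cols) == 0L) stop("truth table has no lfc_* columns")
  x <- rowMeans(as.matrix(truth[, cols, drop = FALSE]))
  names(x) <- truth$gene_id
  x
}

#' Simulate a ranked disease signature correlated with the planted response
#'
#' Produces a complete gene ordering whose Spearman correlation with the
#' truth table's mean planted log2 FC is calibrated to `target_rank_corr`
#' (within +/- 0.05, checked empirically during construction). Scores are
#' built by mixing normal scores of the truth ordering with independent
#' Gaussian noise; the mixing weight is solved by root finding on the
#' realized Spearman statistic, so heavy ties in the truth (many null
#' genes) are accounted for up to the attainable maximum.
#'
#' @param truth truth table from [simulate_counts()].
#' @param target_rank_corr desired Spearman correlation in [0, 1].
#' @param seed integer seed.
#' @return data.frame (gene_id, score), ordered by decreasing score.
#' @export
simulate_signature <- function(truth, target_rank_corr, seed = 1L) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth table")
  if (target_rank_corr < 0 || target_rank_corr > 1)
    stop("target_rank_corr must be in [0, 1]")
  x <- truth_mean_lfc(truth)
  n <- length(x)
  with_seed(seed, {
    base <- qnorm((rank(x, ties.method = "first") - 0.5) / n)
    if (target_rank_corr == 1) {
      sc <- base
    } else {
      eps <- rnorm(n)
      rho_of <- function(w)
        suppressWarnings(cor(w * base + sqrt(1 - w^2) * eps, x,
                             method = "spearman"))
      rho_max <- rho_of(1)
      if (rho_max < target_rank_corr - 0.05)
        stop(sprintf(paste0("target_rank_corr %.2f unattainable: ties in ",
                            "the truth cap Spearman at %.3f"),
                     target_rank_corr, rho_max))
      g0 <- rho_of(0) - target_rank_corr
      if (g0 >= 0) {
        w <- 0
      } else if (rho_of(1) <= target_rank_corr) {
        w <- 1
      } else {
        w <- uniroot(function(w) rho_of(w) - target_rank_corr,
                     c(0, 1), tol = 1e-4)$root
      }
      sc <- w * base + sqrt(1 - w^2) * eps
    }
    out <- data.frame(gene_id = names(x), score = sc,
                      stringsAsFactors = FALSE)
    out[order(-out$score, out$gene_id), , drop = FALSE]
  })
}

#' Simulate upstream promoter regions with planted motif instances
#'
#' Background bases are i.i.d. with a per-gene GC fraction drawn from a
#' Beta distribution. For each motif, consensus-sequence instances (argmax
#' base per PWM column, so a brute-force substring count is an exact
#' oracle) are planted at Poisson-distributed counts: rate
#' `enrichment_rate_deg` for shared-signature genes (classes shared_up and
#' shared_down) and `base_rate` otherwise, at uniform non-overlapping
#' positions.
#'
#' @param truth truth table from [simulate_counts()].
#' @param motifs list of [pwm] objects.
#' @param enrichment_rate_deg expected planted instances per promoter for
#'   shared-signature genes.
#' @param base_rate expected planted instances per promoter for all other
#'   genes.
#' @param length promoter length in bp (default 5000, the upstream window
#'   scanned downstream).
#' @param gc_beta shape parameters of the Beta distribution of per-gene GC.
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet] named by
#'   gene id) and `truth` (data.frame gene_id, gc_fraction; planted counts
#'   in `attr(, "planted_counts")`, a gene x motif matrix; planted start
#'   positions in `attr(, "planted_positions")`).
#' @export
simulate_promoters <- function(truth, motifs, enrichment_rate_deg = 2,
                               base_rate = 0.5, length = 5000,
                               gc_beta = c(50, 50), seed = 1L) {
  if (enrichment_rate_deg < 0 || base_rate < 0) stop("rates must be >= 0")
  if (is.null(names(motifs)))
    names(motifs) <- vapply(motifs, function(m) m$id, character(1))
  widths <- vapply(motifs, function(m) nrow(m$mat), integer(1))
  if (any(widths > length))
    stop("motif wider than promoter: ",
         paste(names(motifs)[widths > length], collapse = ", "))
  ng <- nrow(truth)
  deg <- truth$class %in% c("shared_up", "shared_down")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    gc <- rbeta(ng, gc_beta[1], gc_beta[2])
    counts <- matrix(0L, ng, length(motifs),
                     dimnames = list(truth$gene_id, names(motifs)))
    positions <- vector("list", ng)
    seqs <- character(ng)
    for (g in seq_len(ng)) {
      p <- c((1 - gc[g]) / 2, gc[g] / 2, gc[g] / 2, (1 - gc[g]) / 2)
      s <- sample(bases, length, replace = TRUE, prob = p)
      occupied <- integer(0)     # occupied positions (for non-overlap)
      pos_g <- list()
      for (mi in seq_along(motifs)) {
        w <- widths[mi]
        rate <- if (deg[g]) enrichment_rate_deg else base_rate
        k <- rpois(1, rate)
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < k && tries < 200L) {
          st <- sample.int(length - w + 1L, 1L)
          if (!any((st:(st + w - 1L)) %in% occupied)) {
            starts <- c(starts, st)
            occupied <- c(occupied, st:(st + w - 1L))
          }
          tries <- tries + 1L
        }
        if (length(starts) > 0) {
          cons <- strsplit(consensus(motifs[[mi]]), "")[[1]]
          for (st in starts) s[st:(st + w - 1L)] <- cons
        }
        counts[g, mi] <- length(starts)
        pos_g[[names(motifs)[mi]]] <- sort(starts)
      }
      positions[[g]] <- pos_g
      seqs[g] <- paste(s, collapse = "")
    }
    names(positions) <- truth$gene_id
    pt <- data.frame(gene_id = truth$gene_id, gc_fraction = gc,
                     stringsAsFactors = FALSE)
    attr(pt, "planted_counts") <- counts
    attr(pt, "planted_positions") <- positions
    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- truth$gene_id
    list(sequences = sset, truth = pt)
  })
}

#' Lay out gene loci on a synthetic genome
#'
#' One chromosome per `genes_per_chrom` genes with fixed start spacing, so
#' proximity expectations downstream have simple closed forms. Coordinates
#' are 0-based half-open; strands alternate.
#'
#' @param gene_ids character vector of gene ids.
#' @param genes_per_chrom genes per chromosome.
#' @param spacing distance between consecutive gene starts (bp).
#' @param gene_length gene span length (bp).
#' @return data.frame: gene_id, chrom, start, end, strand, tss.
#' @export
make_gene_loci <- function(gene_ids, genes_per_chrom = 1000,
                           spacing = 1e5, gene_length = 1e4) {
  i <- seq_along(gene_ids)
  j <- (i - 1L) %% genes_per_chrom
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  start <- j * spacing
  end <- start + gene_length
  data.frame(gene_id = gene_ids,
             chrom = paste0("chr", (i - 1L) %/% genes_per_chrom + 1L),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             stringsAsFactors = FALSE)
}

#' Simulate a trait SNP catalog with SNPs planted near target genes
#'
#' Plants `n_planted` SNPs uniformly within `max_planted_distance` of a
#' target gene (distance 0 meaning inside the gene span) and scatters
#' background SNPs uniformly over the synthetic genome.
#'
#' @param loci gene loci from [make_gene_loci()].
#' @param target_genes character vector of gene ids to plant SNPs near;
#'   must be a subset of `loci$gene_id`.
#' @param n_background_snps number of uniform background SNPs.
#' @param n_planted number of planted SNPs.
#' @param max_planted_distance maximum gene-edge distance of a planted SNP.
#' @param trait trait label attached to every SNP.
#' @param seed integer seed.
#' @return list with `catalog` (data.frame snp_id, chrom, pos, trait) and
#'   `truth` (catalog plus planted_near_gene, NA for background SNPs).
#' @export
simulate_snp_catalog <- function(loci, target_genes, n_background_snps = 1000,
                                 n_planted = 20, max_planted_distance = 2e5,
                                 trait = "IBD", seed = 1L) {
  if (is.null(loci) || nrow(loci) == 0L) stop("empty gene loci")
  if (!all(target_genes %in% loci$gene_id))
    stop("target genes absent from loci: ",
         paste(setdiff(target_genes, loci$gene_id), collapse = ", "))
  chrom_len <- tapply(loci$end, loci$chrom, max) + 1e5
  with_seed(seed, {
    planted <- NULL
    if (n_planted > 0) {
      tg <- sample(rep(target_genes, length.out = n_planted))
      rows <- loci[match(tg, loci$gene_id), ]
      lo <- pmax(0, rows$start - max_planted_distance)
      hi <- pmin(chrom_len[rows$chrom] - 1, rows$end - 1 + max_planted_distance)
      pos <- floor(runif(n_planted, lo, hi + 1))
      planted <- data.frame(chrom = rows$chrom, pos = as.numeric(pos),
                            planted_near_gene = tg, stringsAsFactors = FALSE)
    }
    bg <- NULL
    if (n_background_snps > 0) {
      ch <- sample(names(chrom_len), n_background_snps, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
      pos <- floor(runif(n_background_snps, 0, chrom_len[ch]))
      bg <- data.frame(chrom = ch, pos = as.numeric(pos),
                       planted_near_gene = NA_character_,
                       stringsAsFactors = FALSE)
    }
    all <- rbind(planted, bg)
    all$snp_id <- sprintf("snp%05d", seq_len(nrow(all)))
    all$trait <- trait
    catalog <- all[, c("snp_id", "chrom", "pos", "trait")]
    truth <- all[, c("snp_id", "chrom", "pos", "trait", "planted_near_gene")]
    rownames(catalog) <- rownames(truth) <- NULL
    list(catalog = catalog, truth = truth)
  })
}
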