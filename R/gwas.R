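#' Distance from each gene to its nearest trait SNP
#'
#' Coordinates are 0-based half-open. Distance is 0 when a trait SNP lies
#' inside the gene span [start, end); otherwise the base-pair gap to the
#' nearer gene edge (or, in TSS mode, the absolute distance to the
#' transcription start site). Genes on chromosomes with no trait SNP get
#' an infinite sentinel.
#'
#' @param loci gene loci data.frame (gene_id, chrom, start, end, strand;
#'   `tss` used in TSS mode, derived from strand if absent).
#' @param snps SNP catalog data.frame (snp_id, chrom, pos, trait).
#' @param trait trait label to restrict to.
#' @param mode `"edge"` (gene-body edge, default) or `"tss"`.
#' @return data.frame: gene_id, distance, nearest_snp.
#' @export
distance_to_nearest_snp <- function(loci, snps, trait,
                                    mode = c("edge", "tss")) {
  mode <- match.arg(mode)
  traits <- unique(snps$trait)
  if (!trait %in% traits)
    stop("unknown trait '", trait, "'; available: ",
         paste(traits, collapse = ", "))
  ss <- snps[snps$trait == trait, , drop = FALSE]
  ss <- ss[!duplicated(ss[, c("chrom", "pos")]), , drop = FALSE]
  if (mode == "tss" && is.null(loci$tss))
    loci$tss <- ifelse(loci$strand == "+", loci$start, loci$end - 1)
  dist <- rep(Inf, nrow(loci))
  nearest <- rep(NA_character_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    gi <- which(loci$chrom == ch)
    sp <- ss[ss$chrom == ch, , drop = FALSE]
    if (nrow(sp) == 0) next
    for (i in gi) {
      d <- if (mode == "tss") {
        abs(sp$pos - loci$tss[i])
      } else {
        ifelse(sp$pos < loci$start[i], loci$start[i] - sp$pos,
               ifelse(sp$pos >= loci$end[i], sp$pos - loci$end[i], 0))
      }
      j <- which.min(d)
      dist[i] <- d[j]
      nearest[i] <- sp$snp_id[j]
    }
  }
  data.frame(gene_id = loci$gene_id, distance = dist, nearest_snp = nearest,
             stringsAsFactors = FALSE)
}

#' SNP-proximity enrichment of a DEG set
#'
#' At each distance cutoff d, the percentage of DEGs and of non-DEG
#' universe genes lying within d of a trait SNP, with a one-sided Fisher
#' exact test (upper hypergeometric tail) for over-representation of DEGs
#' among proximal genes, plus the nearest-SNP table of the DEGs sorted by
#' ascending distance.
#'
#' @param deg character vector of DEG gene ids (subset of the universe).
#' @param loci gene loci for the universe genes.
#' @param snps SNP catalog.
#' @param trait trait label.
#' @param d_grid distance cutoffs in bp (default 10, 25, 50, 100, 200,
#'   500 kb).
#' @param mode distance convention, see [distance_to_nearest_snp()].
#' @return list of class `proximity_result`: `table` (d, pct_deg,
#'   pct_background, p), `nearest` (per-DEG nearest SNP, ascending),
#'   `meta` (trait, mode).
#' @export
proximity_enrichment <- function(deg, loci, snps, trait,
                                 d_grid = c(10, 25, 50, 100, 200, 500) * 1000,
                                 mode = "edge") {
  if (length(deg) == 0) stop("empty DEG set")
  if (!all(deg %in% loci$gene_id))
    stop("DEG genes absent from loci: ",
         paste(head(setdiff(deg, loci$gene_id), 5), collapse = ", "))
  dd <- distance_to_nearest_snp(loci, snps, trait, mode)
  is_deg <- dd$gene_id %in% deg
  n1 <- sum(is_deg); n0 <- sum(!is_deg)
  tab <- do.call(rbind, lapply(d_grid, function(d) {
    a <- sum(is_deg & dd$distance <= d)
    b <- sum(!is_deg & dd$distance <= d)
    p <- phyper(a - 1, a + b, (n1 + n0) - (a + b), n1, lower.tail = FALSE)
    data.frame(d = d, pct_deg = 100 * a / n1, pct_background = 100 * b / n0,
               n_deg_within = a, n_background_within = b, p = p)
  }))
  nearest <- dd[is_deg, , drop = FALSE]
  nearest <- nearest[order(nearest$distance, nearest$gene_id), , drop = FALSE]
  rownames(nearest) <- NULL
  structure(list(table = tab, nearest = nearest,
                 meta = list(trait = trait, mode = mode, d_grid = d_grid)),
            class = "proximity_result")
}
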