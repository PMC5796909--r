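#' Shared response signature across conditions
#'
#' Intersects directional DEG calls over conditions: a gene enters the up
#' signature when it is called up in at least `n_required` of the supplied
#' condition call sets (all of them by default — the 8-way intersection of
#' 4 cytokines at 2 time points), analogously for down. Genes qualifying
#' in both directions (possible only when `n_required` is less than half
#' the conditions) are excluded from both sets, keeping them disjoint.
#'
#' @param calls named list of DEG call data.frames (from [call_degs()]),
#'   one per condition.
#' @param n_required minimum number of conditions (default: all).
#' @return list with character vectors `up` and `down`.
#' @export
shared_signature <- function(calls, n_required = length(calls)) {
  if (length(calls) == 0) stop("no condition call sets supplied")
  if (any(vapply(calls, is.null, logical(1)))) stop("missing condition")
  count_dir <- function(dir) {
    tab <- table(unlist(lapply(calls, function(d)
      unique(d$gene_id[d$direction == dir]))))
    n <- as.vector(tab)
    names(n) <- names(tab)
    n
  }
  nup <- count_dir("up")
  ndn <- count_dir("down")
  genes <- union(names(nup), names(ndn))
  u <- ifelse(genes %in% names(nup), nup[genes], 0)
  d <- ifelse(genes %in% names(ndn), ndn[genes], 0)
  ## a gene's direction is its majority direction across conditions; exact
  ## ties are excluded, keeping the sets disjoint and monotone in
  ## n_required (at n_required = all conditions this is the plain
  ## directional intersection)
  list(up = sort(genes[u >= n_required & u > d]),
       down = sort(genes[d >= n_required & d > u]))
}

#' Top-k rank overlap curve between two ranked signatures
#'
#' For k = 1..k_max, the overlap of the two top-k sets, a one-sided Fisher
#' exact p-value for over-representation (2x2 table of top-k membership in
#' each list over the universe), and the hypergeometric null band
#' (expectation k^2/N and 95th percentile).
#'
#' @param list_a,list_b data.frames with `gene_id` ordered by decreasing
#'   score (as from [simulate_signature()]), or character vectors of
#'   ordered gene ids.
#' @param k_max deepest rank considered (default 500).
#' @param n_universe universe size N (default: length of the lists).
#' @return data.frame of class `overlap_curve`: k, overlap, p, expected,
#'   null95.
#' @export
rank_overlap_curve <- function(list_a, list_b, k_max = 500,
                               n_universe = NULL) {
  a <- if (is.data.frame(list_a)) list_a$gene_id else as.character(list_a)
  b <- if (is.data.frame(list_b)) list_b$gene_id else as.character(list_b)
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("duplicated gene in a ranked list")
  if (is.null(n_universe)) n_universe <- length(union(a, b))
  if (k_max > n_universe) stop("k_max exceeds the universe size")
  pos_b <- match(a, b)
  worst <- pmax(seq_along(a), pos_b)
  worst <- worst[!is.na(worst) & worst <= k_max]
  ov <- cumsum(tabulate(worst, nbins = k_max))
  k <- seq_len(k_max)
  p <- phyper(ov - 1, k, n_universe - k, k, lower.tail = FALSE)
  out <- data.frame(k = k, overlap = ov, p = p,
                    expected = k^2 / n_universe,
                    null95 = qhyper(0.95, k, n_universe - k, k))
  class(out) <- c("overlap_curve", "data.frame")
  out
}

#' Cumulative-overlap gene-set enrichment along a ranked signature
#'
#' The running count of set members among the top r genes, for r = 1..N,
#' with a Wilcoxon rank-sum test comparing the signature ranks of set
#' members against non-members (exact enumeration when the smaller group
#' has at most 10 members, normal approximation with continuity correction
#' otherwise). Two-sided and both one-sided p-values are reported.
#'
#' @param signature ranked signature (data.frame with `gene_id` ordered by
#'   decreasing score, or an ordered character vector).
#' @param set character vector of member gene ids; must be a proper
#'   non-empty subset of the signature universe.
#' @return list: `curve` (data.frame r, overlap), `p_two`, `p_toward_top`
#'   (one-sided: members rank higher than non-members), `p_toward_bottom`,
#'   `w` (rank-sum statistic of the member group).
#' @export
cumulative_overlap_gsea <- function(signature, set) {
  genes <- if (is.data.frame(signature)) signature$gene_id
           else as.character(signature)
  n <- length(genes)
  memb <- genes %in% set
  m <- sum(memb)
  if (m == 0) stop("set has no genes in the signature universe")
  if (m == n) stop("set equals the signature universe")
  curve <- data.frame(r = seq_len(n), overlap = cumsum(memb))
  rk <- seq_len(n)                       # rank 1 = top of the signature
  exact <- min(m, n - m) <= 10
  ## "toward top" = member ranks smaller than non-member ranks
  ht_less <- wilcox.test(rk[memb], rk[!memb], alternative = "less",
                         exact = exact, correct = TRUE)
  ht_greater <- wilcox.test(rk[memb], rk[!memb], alternative = "greater",
                            exact = exact, correct = TRUE)
  ht_two <- wilcox.test(rk[memb], rk[!memb], alternative = "two.sided",
                        exact = exact, correct = TRUE)
  list(curve = curve, p_two = ht_two$p.value,
       p_toward_top = ht_less$p.value,
       p_toward_bottom = ht_greater$p.value,
       w = sum(rk[memb]))
}

#' Hypergeometric over-representation of annotation sets in a DEG list
#'
#' One-sided upper-tail hypergeometric p-values for the overlap between a
#' DEG set and each annotation set, both intersected with the universe
#' first; odds ratios from the 2x2 table; BH adjustment across sets.
#'
#' @param deg character vector of DEG gene ids.
#' @param sets named list of annotation gene sets.
#' @param universe character vector of universe gene ids (e.g. all
#'   detected genes).
#' @return data.frame: set_id, overlap, set_size, deg_size, universe_size,
#'   odds_ratio, p, q.
#' @export
hypergeometric_enrichment <- function(deg, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  deg <- intersect(unique(deg), universe)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    ov <- length(intersect(deg, s))
    a <- ov
    b <- length(deg) - ov
    cc <- length(s) - ov
    d <- length(universe) - length(deg) - cc
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(deg), lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = length(s),
               deg_size = length(deg), universe_size = length(universe),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Mean fold change of a gene set under one condition
#'
#' @param profile response profile (genes x conditions log2 FC matrix).
#' @param set character vector of gene ids (>= 1 present in the profile).
#' @param condition condition column.
#' @return the arithmetic mean log2 FC of the present set genes; the
#'   number of absent genes is attached as `attr(, "n_missing")`.
#' @export
signature_score <- function(profile, set, condition) {
  present <- intersect(set, rownames(profile))
  if (length(present) == 0) stop("no set genes present in the profile")
  sc <- mean(unclass(as.matrix(profile))[present, condition])
  attr(sc, "n_missing") <- length(set) - length(present)
  sc
}

#' Fold-change comparison between binding-site strata
#'
#' Two-sided Wilcoxon rank-sum test of log2 FCs between genes with at
#' least `threshold` motif sites and genes with fewer, plus the middle-50%
#' fold-change interval per stratum.
#'
#' @param profile response profile.
#' @param site_counts named integer vector of per-gene site counts.
#' @param condition condition column.
#' @param threshold site-count split point (default 2, i.e. "2+ sites").
#' @return list: `p` (two-sided), `n_high`, `n_low`, `quartiles`
#'   (2 x 2 matrix of 25%/75% log2 FC per stratum).
#' @export
stratified_fc_test <- function(profile, site_counts, condition,
                               threshold = 2) {
  genes <- intersect(rownames(profile), names(site_counts))
  lfc <- unclass(as.matrix(profile))[genes, condition]
  high <- site_counts[genes] >= threshold
  if (!any(high) || all(high)) stop("a stratum is empty")
  exact <- min(sum(high), sum(!high)) <= 8
  ht <- suppressWarnings(wilcox.test(lfc[high], lfc[!high],
                                     alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  qs <- rbind(high = quantile(lfc[high], c(0.25, 0.75)),
              low = quantile(lfc[!high], c(0.25, 0.75)))
  list(p = ht$p.value, n_high = sum(high), n_low = sum(!high),
       quartiles = qs)
}
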