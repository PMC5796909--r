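#' Detection filter on counts per million
#'
#' A gene is considered detectably expressed in a sample when its cpm is
#' strictly greater than `min_cpm`; it is retained when detected in at
#' least `ceiling(min_sample_fraction * n_samples)` samples. Filtering
#' uses raw library sizes (it precedes normalization).
#'
#' @param counts genes x samples count matrix.
#' @param lib_sizes library sizes (default column sums).
#' @param min_cpm strict cpm threshold (default 0.25).
#' @param min_sample_fraction minimum fraction of samples (default 0.25).
#' @param extra_mask optional logical vector (e.g. an externally computed
#'   abundance-confidence mask) AND-combined with the cpm rule.
#' @return named logical vector over genes.
#' @export
detect_expressed <- function(counts, lib_sizes = colSums(counts),
                             min_cpm = 0.25, min_sample_fraction = 0.25,
                             extra_mask = NULL) {
  x <- cpm(counts, lib_sizes)
  need <- ceiling(min_sample_fraction * ncol(x))
  keep <- rowSums(x > min_cpm) >= need
  if (!is.null(extra_mask)) {
    stopifnot(length(extra_mask) == nrow(counts))
    keep <- keep & extra_mask
  }
  keep
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-robust between-sample scaling factors. The reference sample
#' is the column whose upper-quartile cpm is closest to the mean
#' upper-quartile. For every other sample, M (log2 cpm ratio) and A
#' (average log2 cpm) values are computed over genes non-zero in both
#' columns, doubly trimmed (by M and by A), and averaged with weights equal
#' to the inverse asymptotic variance of M; the factor is 2 to that mean.
#' Factors are re-centered to geometric mean 1, so sequencing depth is
#' carried by library sizes, not factors.
#'
#' @param counts genes x samples count matrix.
#' @param lib_sizes library sizes (default column sums).
#' @param logratio_trim two-sided trim fraction on M (default 0.30).
#' @param abs_expr_trim two-sided trim fraction on A (default 0.05).
#' @return numeric vector of positive factors, one per sample, product 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.30, abs_expr_trim = 0.05) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  if (ns < 2) stop("TMM needs at least 2 samples")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  x <- cpm(counts, lib_sizes)
  uq <- apply(x, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ns), function(s) {
    if (s == ref) return(1)
    keep <- counts[, s] > 0 & counts[, ref] > 0
    if (!any(keep))
      stop("sample ", colnames(counts)[s] %||% s,
           " shares no nonzero genes with the reference")
    ys <- counts[keep, s]; yr <- counts[keep, ref]
    ns_ <- lib_sizes[s]; nr <- lib_sizes[ref]
    m <- log2((ys / ns_) / (yr / nr))
    a <- 0.5 * log2((ys / ns_) * (yr / nr))
    w <- (ns_ - ys) / (ns_ * ys) + (nr - yr) / (nr * yr)
    n <- length(m)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abs_expr_trim) + 1
    hiA <- n + 1 - loA
    rM <- rank(m); rA <- rank(a)
    use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(use)) return(1)
    2^(sum(m[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
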