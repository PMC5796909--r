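#' Negative binomial GLM likelihood-ratio tests, gene by gene
#'
#' Fits the full and reduced NB GLM (log link, log effective library size
#' offset) per gene at the supplied dispersions and tests the extra terms
#' with a likelihood-ratio chi-square whose degrees of freedom equal the
#' design-rank difference. The reported log2 fold change is the tested
#' coefficient divided by log(2) (shrinkage-free GLM estimate).
#'
#' @param counts genes x samples count matrix.
#' @param design data.frame of sample covariates.
#' @param dispersion a `dispersion_fit` or a numeric vector/scalar of
#'   per-gene dispersions.
#' @param full,reduced model formulas over columns of `design`; the full
#'   model must nest the reduced one.
#' @param offset per-sample log effective library sizes (default: TMM).
#' @param contrast_label label stored in the result (e.g. "IL1B:8h").
#' @return data.frame of class `de_result`: gene_id, log2fc, avg_log_cpm,
#'   lr_stat, p, q (BH over converged genes), converged, contrast.
#' @export
fit_nb_lrt <- function(counts, design, dispersion,
                       full = ~ treatment + cell_line,
                       reduced = ~ cell_line,
                       offset = NULL, contrast_label = NA_character_) {
  counts <- as.matrix(counts)
  Xf <- model.matrix(full, design)
  Xr <- model.matrix(reduced, design)
  if (nrow(Xf) != ncol(counts)) stop("design rows must match count columns")
  rf <- qr(Xf)$rank; rr <- qr(Xr)$rank
  if (rf < ncol(Xf)) stop("full design matrix is not of full rank")
  if (!all(colnames(Xr) %in% colnames(Xf)))
    stop("reduced model is not nested in the full model")
  df <- rf - rr
  if (df < 1) stop("full model adds no tested terms")
  tested <- setdiff(colnames(Xf), colnames(Xr))
  coef_name <- if (length(tested) == 1L) tested else tested[1]
  if (is.null(offset)) {
    f <- tmm_factors(counts)
    offset <- log(colSums(counts) * f)
  }
  phi <- dispersion_vector(dispersion, counts)
  alc <- avg_log_cpm(counts, exp(offset))
  ng <- nrow(counts)
  log2fc <- lr <- rep(NA_real_, ng)
  conv <- rep(FALSE, ng)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    ff <- nb_fit_core(y, Xf, offset, phi[g])
    fr <- nb_fit_core(y, Xr, offset, phi[g])
    if (is.null(ff) || is.null(fr) || !ff$converged || !fr$converged) next
    conv[g] <- TRUE
    lr[g] <- max(0, 2 * (ff$loglik - fr$loglik))
    log2fc[g] <- ff$beta[coef_name] / log(2)
  }
  if (!all(conv))
    message(sum(!conv), " gene(s) failed to converge; p set to missing")
  p <- ifelse(conv, pchisq(lr, df = df, lower.tail = FALSE), NA_real_)
  p[conv] <- pmax(p[conv], .Machine$double.xmin)
  q <- rep(NA_real_, ng)
  q[conv] <- bh_adjust(p[conv])
  out <- data.frame(gene_id = rownames(counts) %||% as.character(seq_len(ng)),
                    log2fc = log2fc, avg_log_cpm = alc, lr_stat = lr,
                    p = p, q = q, converged = conv,
                    contrast = contrast_label, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

dispersion_vector <- function(dispersion, counts) {
  if (inherits(dispersion, "dispersion_fit")) {
    phi <- dispersion$phi[rownames(counts)]
    if (anyNA(phi)) phi[is.na(phi)] <- 0
    return(phi)
  }
  if (length(dispersion) == 1L) return(rep(dispersion, nrow(counts)))
  if (length(dispersion) != nrow(counts))
    stop("dispersion length must be 1 or nrow(counts)")
  as.numeric(dispersion)
}

#' One differential-expression contrast: cytokine vs control at one time
#'
#' Convenience driver reproducing the per-condition testing scheme:
#' subset to the cytokine and control samples at one time point, filter to
#' detectably expressed genes, TMM-normalize, estimate the trended
#' dispersion under the full model (treatment + cell line), and run the
#' likelihood-ratio test of treatment.
#'
#' @param counts full genes x samples count matrix.
#' @param design full sample design (sample_id, treatment, time, cell_line).
#' @param treatment cytokine label to test.
#' @param time time point label.
#' @param ref control label (default "CTL").
#' @param dispersion optional precomputed dispersions; estimated if NULL.
#' @param filter apply the detection filter before testing (default TRUE).
#' @return `de_result` data.frame (see [fit_nb_lrt()]).
#' @export
run_de <- function(counts, design, treatment, time, ref = "CTL",
                   dispersion = NULL, filter = TRUE) {
  sel <- design$time == time & design$treatment %in% c(ref, treatment)
  if (!any(design$treatment == treatment & design$time == time))
    stop("no samples for ", treatment, " at ", time)
  des <- design[sel, , drop = FALSE]
  cts <- as.matrix(counts)[, des$sample_id, drop = FALSE]
  if (filter) {
    keep <- detect_expressed(cts)
    cts <- cts[keep, , drop = FALSE]
  }
  des$treatment <- factor(des$treatment, levels = c(ref, treatment))
  multi_line <- length(unique(des$cell_line)) > 1
  full <- if (multi_line) ~ treatment + cell_line else ~ treatment
  reduced <- if (multi_line) ~ cell_line else ~ 1
  f <- tmm_factors(cts)
  offset <- log(colSums(cts) * f)
  if (is.null(dispersion))
    dispersion <- estimate_trended_dispersion(cts, des, full, offset = offset)
  fit_nb_lrt(cts, des, dispersion, full, reduced, offset = offset,
             contrast_label = paste(treatment, time, sep = ":"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in (0, 1]; NA entries propagate.
#' @return q-values of the same length, order-preserving, capped at 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Call differentially expressed genes by FDR and fold-change thresholds
#'
#' All inequalities are strict: up means FC > `fc_min` and q < `fdr_max`;
#' down means FC < `fc_max` and q < `fdr_max`. The `"heatmap"` preset
#' instead uses raw P < 0.05 with FC > 1.50 or FC < 0.67 (the looser
#' criterion used for global heatmap displays).
#'
#' @param results a `de_result` data.frame.
#' @param fdr_max FDR threshold (default 0.10).
#' @param fc_min fold-change threshold for up calls (default 2.00).
#' @param fc_max fold-change threshold for down calls (default 0.50).
#' @param preset `"primary"` (FDR-based) or `"heatmap"` (raw-p-based).
#' @return data.frame gene_id, direction ("up"/"down"); thresholds in
#'   `attr(, "thresholds")`.
#' @export
call_degs <- function(results, fdr_max = 0.10, fc_min = 2.00, fc_max = 0.50,
                      preset = c("primary", "heatmap")) {
  preset <- match.arg(preset)
  if (preset == "heatmap") {
    crit <- !is.na(results$p) & results$p < 0.05
    fc_min <- 1.50; fc_max <- 0.67
    thr <- list(p_max = 0.05, fc_min = fc_min, fc_max = fc_max,
                preset = preset)
  } else {
    crit <- !is.na(results$q) & results$q < fdr_max
    thr <- list(fdr_max = fdr_max, fc_min = fc_min, fc_max = fc_max,
                preset = preset)
  }
  fc <- 2^results$log2fc
  up <- crit & !is.na(fc) & fc > fc_min
  dn <- crit & !is.na(fc) & fc < fc_max
  out <- data.frame(
    gene_id = c(results$gene_id[up], results$gene_id[dn]),
    direction = rep(c("up", "down"), c(sum(up), sum(dn))),
    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  out
}

#' Treatment-by-time interaction test
#'
#' Tests, per gene, whether the cytokine response differs between the two
#' time points: LRT of the model with a treatment x time interaction
#' against the additive model (both including cell line). Significant genes
#' are classified into sign patterns from the two per-time log2 FC
#' estimates.
#'
#' @param counts full genes x samples count matrix.
#' @param design full sample design.
#' @param treatment cytokine label to test against the control.
#' @param ref control label.
#' @param dispersion optional precomputed dispersions.
#' @param fdr_max FDR threshold used for the pattern classification
#'   (default 0.10).
#' @param filter apply the detection filter (default TRUE).
#' @return data.frame: gene_id, log2fc_early, log2fc_late, lr_stat, p, q,
#'   converged, pattern ("up_down", "down_up", "same" or NA when not
#'   significant).
#' @export
interaction_test <- function(counts, design, treatment, ref = "CTL",
                             dispersion = NULL, fdr_max = 0.10,
                             filter = TRUE) {
  sel <- design$treatment %in% c(ref, treatment)
  des <- design[sel, , drop = FALSE]
  times <- unique(design$time)
  if (length(times) < 2) stop("both time points must be present")
  for (ti in times)
    if (!any(des$time == ti & des$treatment == treatment) ||
        !any(des$time == ti & des$treatment == ref))
      stop("missing time point ", ti, " for ", treatment, " or ", ref)
  cts <- as.matrix(counts)[, des$sample_id, drop = FALSE]
  if (filter) cts <- cts[detect_expressed(cts), , drop = FALSE]
  des$treatment <- factor(des$treatment, levels = c(ref, treatment))
  des$time <- factor(des$time, levels = times)
  full <- ~ treatment * time + cell_line
  reduced <- ~ treatment + time + cell_line
  f <- tmm_factors(cts)
  offset <- log(colSums(cts) * f)
  if (is.null(dispersion))
    dispersion <- estimate_trended_dispersion(cts, des, full, offset = offset)
  phi <- dispersion_vector(dispersion, cts)
  Xf <- model.matrix(full, des)
  Xr <- model.matrix(reduced, des)
  trt_col <- paste0("treatment", treatment)
  int_col <- paste0("treatment", treatment, ":time", times[2])
  ng <- nrow(cts)
  lfc1 <- lfc2 <- lr <- rep(NA_real_, ng)
  conv <- rep(FALSE, ng)
  for (g in seq_len(ng)) {
    y <- cts[g, ]
    ff <- nb_fit_core(y, Xf, offset, phi[g])
    fr <- nb_fit_core(y, Xr, offset, phi[g])
    if (is.null(ff) || is.null(fr) || !ff$converged || !fr$converged) next
    conv[g] <- TRUE
    lr[g] <- max(0, 2 * (ff$loglik - fr$loglik))
    lfc1[g] <- ff$beta[trt_col] / log(2)
    lfc2[g] <- (ff$beta[trt_col] + ff$beta[int_col]) / log(2)
  }
  p <- ifelse(conv, pchisq(lr, df = 1, lower.tail = FALSE), NA_real_)
  p[conv] <- pmax(p[conv], .Machine$double.xmin)
  q <- rep(NA_real_, ng)
  q[conv] <- bh_adjust(p[conv])
  pattern <- rep(NA_character_, ng)
  sig <- !is.na(q) & q < fdr_max
  pattern[sig & lfc1 > 0 & lfc2 < 0] <- "up_down"
  pattern[sig & lfc1 < 0 & lfc2 > 0] <- "down_up"
  pattern[sig & sign(lfc1) == sign(lfc2)] <- "same"
  data.frame(gene_id = rownames(cts), log2fc_early = lfc1,
             log2fc_late = lfc2, lr_stat = lr, p = p, q = q,
             converged = conv, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Paired two-sample t-test per gene
#'
#' Classical paired t on log-scale abundance between a cytokine group and
#' its control at one time point, with pairs matched by cell line.
#'
#' @param expr genes x samples matrix of log-scale abundances.
#' @param design sample design data.frame.
#' @param treatment treatment label.
#' @param time time point label.
#' @param ref control label.
#' @param pairing design column identifying pairs (default "cell_line").
#' @return data.frame gene_id, t, df, p, n_pairs. With fewer than 2
#'   complete pairs, p is missing (with a warning). Zero-variance
#'   differences give p = 1 when the mean difference is 0, otherwise the
#'   smallest representable double.
#' @export
group_ttest <- function(expr, design, treatment, time, ref = "CTL",
                        pairing = "cell_line") {
  expr <- as.matrix(expr)
  a <- design$sample_id[design$treatment == treatment & design$time == time]
  b <- design$sample_id[design$treatment == ref & design$time == time]
  pa <- design[[pairing]][match(a, design$sample_id)]
  pb <- design[[pairing]][match(b, design$sample_id)]
  common <- intersect(pa, pb)
  k <- length(common)
  if (k < 2) {
    warning("fewer than 2 complete pairs; p-values missing")
    return(data.frame(gene_id = rownames(expr), t = NA_real_, df = NA_real_,
                      p = NA_real_, n_pairs = k, stringsAsFactors = FALSE))
  }
  d <- expr[, a[match(common, pa)], drop = FALSE] -
       expr[, b[match(common, pb)], drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (k - 1))
  t <- ifelse(s > 0, m / (s / sqrt(k)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(is.finite(t), 2 * pt(abs(t), df = k - 1, lower.tail = FALSE),
              .Machine$double.xmin)
  data.frame(gene_id = rownames(expr), t = t, df = k - 1, p = p,
             n_pairs = k, stringsAsFactors = FALSE)
}

#' Per-factor variance explained across genes
#'
#' For each gene and design factor, the R-squared of the one-factor linear
#' model on log-scale abundance; summarized over genes. Constant gene rows
#' get R-squared 0 by convention.
#'
#' @param expr genes x samples matrix of log-scale abundances.
#' @param design sample design data.frame.
#' @param factors design columns to assess.
#' @return list with `per_gene` (genes x factors matrix of R-squared) and
#'   `summary` (data.frame factor, mean_r2, median_r2).
#' @export
variance_components <- function(expr, design,
                                factors = c("treatment", "time",
                                            "cell_line")) {
  expr <- as.matrix(expr)
  for (f in factors)
    if (length(unique(design[[f]])) < 2)
      stop("factor ", f, " has fewer than 2 levels")
  ctr <- expr - rowMeans(expr)
  sst <- rowSums(ctr^2)
  r2 <- sapply(factors, function(f) {
    g <- design[[f]][match(colnames(expr), design$sample_id)]
    gm <- t(apply(ctr, 1, function(row) ave(row, g)))
    ssb <- rowSums(gm^2)
    ifelse(sst > 0, ssb / sst, 0)
  })
  rownames(r2) <- rownames(expr)
  list(per_gene = r2,
       summary = data.frame(factor = factors,
                            mean_r2 = colMeans(r2),
                            median_r2 = apply(r2, 2, median),
                            stringsAsFactors = FALSE))
}
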