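test_that("detection filter applies strict cpm and ceiling sample rules", {
  ## 8 samples, library size 1e6 each -> cpm == counts
  cts <- matrix(0, 3, 8, dimnames = list(c("at_thr", "zero", "two_samples"),
                                         paste0("s", 1:8)))
  lib <- rep(1e6, 8)
  cts["at_thr", ] <- 0.25          # exactly at threshold: not detected
  cts["two_samples", c(1, 5)] <- 10 # cpm > 0.25 in exactly 2 of 8
  keep <- detect_expressed(cts, lib, min_cpm = 0.25,
                           min_sample_fraction = 0.25)
  expect_false(keep["at_thr"])     # strict inequality
  expect_false(keep["zero"])
  expect_true(keep["two_samples"]) # 2 >= ceiling(0.25 * 8)
  expect_error(detect_expressed(cts, c(lib[-1], 0)), "library size")
})

test_that("TMM factors are 1 for identical columns and absorb pure depth", {
  cts <- matrix(rpois(600, 50), 200, 3)
  same <- cbind(cts[, 1], cts[, 1], cts[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)

  ## doubling depth without DE: factor ratio stays ~1
  base <- make_two_group_counts(2000, 2, phi = 0, seed = 3)$counts
  doubled <- cbind(base[, 1:2], d = rpois(2000, 2 * rowMeans(base[, 1:2])))
  f <- tmm_factors(doubled)
  expect_gt(f[3] / f[1], 0.97)
  expect_lt(f[3] / f[1], 1.03)
})

test_that("TMM compensates planted composition bias", {
  withr::with_seed(5, {
    ng <- 2000
    mu <- exp(runif(ng, log(20), log(2000)))
    c1 <- rpois(ng, mu)
    shift <- c(rep(4, 600), rep(1, 1400))   # 30% of genes 4-fold up
    c2 <- rpois(ng, mu * shift)
  })
  cts <- cbind(s1 = c1, s2 = c2)
  f <- tmm_factors(cts)
  eff <- colSums(cts) * f
  unchanged <- 601:2000
  ratio <- (c2[unchanged] / eff[2]) / (c1[unchanged] / eff[1])
  expect_gt(mean(ratio[is.finite(ratio)]), 0.95)
  expect_lt(mean(ratio[is.finite(ratio)]), 1.05)
  ## factors always multiply to 1 and ignore gene order
  expect_equal(prod(f), 1, tolerance = 1e-12)
  expect_equal(unname(tmm_factors(cts[sample(ng), ])), unname(f))
})

test_that("trended dispersion recovers Poisson and constant-NB truth", {
  fx <- make_two_group_counts(2000, 6, phi = 0, seed = 7)
  dfit <- estimate_trended_dispersion(fx$counts, fx$design, ~ treatment)
  expect_lt(median(dfit$phi), 0.01)

  fx2 <- make_two_group_counts(2000, 6, phi = 0.1, seed = 8)
  dfit2 <- estimate_trended_dispersion(fx2$counts, fx2$design, ~ treatment)
  expect_true(all(dfit2$bins$smoothed > 0.08))
  expect_true(all(dfit2$bins$smoothed < 0.12))
})

test_that("equal counts in a single group drive the CR estimate to zero", {
  y <- rep(7, 6)
  X <- matrix(1, 6, 1)
  off <- rep(0, 6)
  apl <- vapply(c(1e-6, 1e-3, 0.1, 1),
                function(phi) cytoresponse:::cr_apl(y, X, off, phi),
                numeric(1))
  expect_identical(which.max(apl), 1L)
})

test_that("NB LRT gives null results on identical groups and recovers effects", {
  cts <- matrix(rep(c(10, 20, 30, 10, 20, 30), each = 4), 4, byrow = FALSE)
  rownames(cts) <- paste0("g", 1:4)
  colnames(cts) <- paste0("s", 1:6)
  des <- data.frame(sample_id = colnames(cts),
                    treatment = factor(rep(c("CTL", "TRT"), each = 3),
                                       levels = c("CTL", "TRT")))
  res <- fit_nb_lrt(cts, des, 0.1, ~ treatment, ~ 1,
                    offset = rep(0, 6))
  expect_equal(res$log2fc, rep(0, 4), tolerance = 1e-6)
  expect_true(all(res$lr_stat < 1e-8))
  expect_true(all(res$p > 0.999))

  ## parameter recovery at planted log2 FC 2, mean >= 50
  lfc <- c(rep(2, 100), rep(0, 1900))
  fx <- make_two_group_counts(2000, 3, mu_range = c(50, 500), lfc = lfc,
                              phi = 0.1, seed = 11)
  dfit <- estimate_trended_dispersion(fx$counts, fx$design, ~ treatment)
  res2 <- fit_nb_lrt(fx$counts, fx$design, dfit, ~ treatment, ~ 1)
  expect_gt(mean(res2$log2fc[1:100]), 1.85)
  expect_lt(mean(res2$log2fc[1:100]), 2.15)
  expect_true(all(res2$lr_stat >= 0, na.rm = TRUE))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  withr::with_seed(13, {
    for (i in 1:50) {
      p <- runif(sample(2:40, 1))
      expect_equal(bh_adjust(p), naive_bh(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling uses strict thresholds and is threshold-monotone", {
  res <- data.frame(gene_id = paste0("g", 1:4),
                    log2fc = c(log2(2.5), log2(2.5), log2(0.4), log2(1.6)),
                    p = c(0.001, 0.001, 0.001, 0.04),
                    q = c(0.09, 0.10, 0.05, 0.20))
  calls <- call_degs(res)
  expect_identical(calls$gene_id[calls$direction == "up"], "g1")
  expect_identical(calls$gene_id[calls$direction == "down"], "g3")
  ## q = 0.10 exactly is excluded (strict)
  expect_false("g2" %in% calls$gene_id)
  ## heatmap preset: raw p with looser FC bounds
  heat <- call_degs(res, preset = "heatmap")
  expect_true("g4" %in% heat$gene_id)
  ## tightening the FDR never adds genes
  tight <- call_degs(res, fdr_max = 0.05)
  expect_true(all(tight$gene_id %in% calls$gene_id))
})

test_that("interaction test flags planted time-flips and spares stable genes", {
  cfg <- sim_config(n_genes = 600, pi_shared_up = 0.05, pi_shared_down = 0,
                    pi_specific = 0, pi_timeflip = 0.1, seed = 17)
  s <- simulate_counts(cfg)
  it <- interaction_test(s$counts, s$design, "IL1B")
  tf <- s$truth$gene_id[s$truth$class == "timeflip"]
  hit <- !is.na(it$q) & it$q < 0.10
  expect_gte(mean(tf %in% it$gene_id[hit]), 0.9)
  expect_true(all(it$pattern[match(tf, it$gene_id)] %in%
                    c("up_down", NA)))
  ## shared_up genes respond equally at both times: not interaction hits
  su <- s$truth$gene_id[s$truth$class == "shared_up"]
  expect_lt(mean(su %in% it$gene_id[hit]), 0.2)
  expect_error(interaction_test(s$counts,
                                s$design[s$design$time == "8h", ], "IL1B"),
               "time point")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  expr <- rbind(gA = c(1, 2, 3, 2, 4, 6),   # differences 1, 2, 3
                gB = c(5, 5, 5, 5, 5, 5),   # identical pairs
                gC = c(1, 1, 1, 2, 2, 2))   # constant shift, zero variance
  colnames(expr) <- paste0("s", 1:6)
  des <- data.frame(sample_id = colnames(expr),
                    treatment = rep(c("CTL", "TRT"), each = 3),
                    time = "8h",
                    cell_line = rep(c("A", "B", "C"), 2))
  tt <- group_ttest(expr, des, "TRT", "8h")
  expect_equal(tt$t[1], 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(tt$p[1], 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(tt$p[1], 0.0742, tolerance = 1e-3)
  expect_equal(tt$t[2], 0)
  expect_equal(tt$p[2], 1)
  expect_identical(tt$p[3], .Machine$double.xmin)  # no division error
  expect_warning(group_ttest(expr[, c(1, 4)],
                             des[c(1, 4), ], "TRT", "8h"),
                 "pairs")
})

test_that("variance decomposition attributes variation to the right factor", {
  des <- expand.grid(treatment = c("CTL", "TRT"), time = c("8h", "24h"),
                     cell_line = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  des$sample_id <- paste0("s", seq_len(nrow(des)))
  ## expression equal to a pure cell-line offset
  off <- c(A = 0, B = 2, C = 5)
  expr <- rbind(g1 = off[des$cell_line] + 0,
                g2 = off[des$cell_line] * -1)
  colnames(expr) <- des$sample_id
  vc <- variance_components(expr, des)
  expect_equal(unname(vc$per_gene[, "cell_line"]), c(1, 1))
  expect_lt(max(vc$per_gene[, c("treatment", "time")]), 1e-10)

  ## pure noise: mean R2 ~ (levels - 1) / (n - 1)
  withr::with_seed(23, {
    expr2 <- matrix(rnorm(2000 * nrow(des)), 2000,
                    dimnames = list(NULL, des$sample_id))
  })
  vc2 <- variance_components(expr2, des)
  n <- nrow(des)
  expect_equal(unname(vc2$summary$mean_r2[vc2$summary$factor == "treatment"]),
               (2 - 1) / (n - 1), tolerance = 0.05)
  expect_equal(unname(vc2$summary$mean_r2[vc2$summary$factor == "cell_line"]),
               (3 - 1) / (n - 1), tolerance = 0.05)

  ## dominant cell-line variability ranks the cell-line factor first
  cfg <- sim_config(n_genes = 300, cellline_sd = 1, effect_log2fc = 0.3,
                    seed = 29)
  s <- simulate_counts(cfg)
  expr3 <- log2(cpm(s$counts) + 1)
  vc3 <- variance_components(expr3, s$design)
  best <- vc3$summary$factor[which.max(vc3$summary$mean_r2)]
  expect_identical(best, "cell_line")
})

test_that("normalization and DE agree with an independent NB-GLM implementation", {
  skip_if_not_installed("edgeR")
  lfc <- c(rep(2, 60), rep(0, 940))
  fx <- make_two_group_counts(1000, 3, mu_range = c(30, 500), lfc = lfc,
                              phi = 0.1, seed = 37)
  ## TMM factors within 2% of edgeR's
  f_pkg <- tmm_factors(fx$counts)
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(fx$counts))$samples$norm.factors
  expect_lt(max(abs(log(f_pkg / f_ref))), log(1.02))

  ## trended dispersion and LRT land close to edgeR's (not identical:
  ## binning, smoothing and convergence rules differ by design)
  des_mm <- model.matrix(~ treatment, fx$design)
  dfit <- estimate_trended_dispersion(fx$counts, fx$design, ~ treatment)
  res <- fit_nb_lrt(fx$counts, fx$design, dfit, ~ treatment, ~ 1)
  y <- edgeR::DGEList(fx$counts)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateGLMTrendedDisp(y, des_mm)
  fit <- edgeR::glmFit(y, des_mm)
  ref <- edgeR::glmLRT(fit)$table
  expect_gt(cor(res$log2fc, ref$logFC), 0.99)
  expect_lt(median(abs(res$log2fc - ref$logFC)), 0.05)
  expect_gt(cor(log10(res$p), log10(ref$PValue)), 0.95)
  ## both pipelines call essentially the same DEGs
  deg_pkg <- call_degs(res)$gene_id
  ref$q <- p.adjust(ref$PValue, "BH")
  deg_ref <- rownames(ref)[ref$q < 0.10 &
                             (2^ref$logFC > 2 | 2^ref$logFC < 0.5)]
  jacc <- length(intersect(deg_pkg, deg_ref)) /
    length(union(deg_pkg, deg_ref))
  expect_gt(jacc, 0.9)
})
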