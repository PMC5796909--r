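test_that("simulation is deterministic and accounts for every gene class", {
  cfg <- sim_config(n_genes = 500, seed = 9)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  tab <- table(s1$truth$class)
  expect_identical(sum(tab), 500L)
  expect_equal(unname(tab["shared_up"]), round(0.04 * 500))
  expect_equal(unname(tab["shared_down"]), round(0.01 * 500))

  ## shared_up genes: identical positive log2 FC in every condition
  lfc_cols <- grep("^lfc_", names(s1$truth), value = TRUE)
  up <- s1$truth[s1$truth$class == "shared_up", lfc_cols]
  expect_true(all(up == cfg$effect_log2fc))
  dn <- s1$truth[s1$truth$class == "shared_down", lfc_cols]
  expect_true(all(dn == -cfg$effect_log2fc))
  ## timeflip genes: opposite signs between the two times
  tf <- s1$truth[s1$truth$class == "timeflip", ]
  expect_true(all(tf$lfc_IL1B_8h == cfg$effect_log2fc))
  expect_true(all(tf$lfc_IL1B_24h == -cfg$effect_log2fc))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(pi_shared_up = 0.8, pi_specific = 0.4),
               "sum to more than 1")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
  expect_error(sim_config(replicates_per_group = c(4, 4), n_cell_lines = 3),
               "cell lines")
})

test_that("null configuration plants nothing and groups differ only by noise", {
  cfg <- sim_config(n_genes = 300, pi_shared_up = 0, pi_shared_down = 0,
                    pi_specific = 0, pi_timeflip = 0, seed = 4)
  s <- simulate_counts(cfg)
  expect_true(all(s$truth$class == "null"))
  expect_true(all(truth_mean_lfc(s$truth) == 0))
})

test_that("Poisson limit: variance tracks the mean when phi0 = a = 0", {
  cfg <- sim_config(n_genes = 2000, phi0 = 0, a = 0, cellline_sd = 0,
                    pi_shared_up = 0, pi_shared_down = 0, pi_specific = 0,
                    pi_timeflip = 0, depth_fold_range = 1, seed = 21)
  s <- simulate_counts(cfg)
  ctl <- s$design$sample_id[s$design$treatment == "CTL"]
  m <- rowMeans(s$counts[, ctl])
  v <- apply(s$counts[, ctl], 1, var)
  ## brute-force moment check: regression of variance on mean has slope ~ 1
  slope <- coef(lm(v ~ 0 + m))
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("NB moment fidelity: (var - mu) on mu^2 recovers phi", {
  cfg <- sim_config(n_genes = 5000, phi0 = 0.2, a = 0, cellline_sd = 0,
                    pi_shared_up = 0, pi_shared_down = 0, pi_specific = 0,
                    pi_timeflip = 0, depth_fold_range = 1, seed = 2)
  s <- simulate_counts(cfg)
  ctl <- s$design$sample_id[s$design$treatment == "CTL"]
  m <- rowMeans(s$counts[, ctl])
  v <- apply(s$counts[, ctl], 1, var)
  slope <- coef(lm(I(v - m) ~ 0 + I(m^2)))
  expect_gt(slope, 0.18)
  expect_lt(slope, 0.22)
})

test_that("ranked signatures hit their target Spearman correlation", {
  ## continuous truth: every gene has its own response size
  truth <- withr::with_seed(31, data.frame(
    gene_id = sprintf("g%05d", 1:5000), class = "null",
    lfc_A_8h = rnorm(5000), stringsAsFactors = FALSE))
  sig1 <- simulate_signature(truth, 1, seed = 1)
  expect_identical(sig1$gene_id,
                   truth$gene_id[order(-truth$lfc_A_8h)])

  x <- truth_mean_lfc(truth)
  for (target in c(0, 0.7)) {
    sig <- simulate_signature(truth, target, seed = 7)
    rho <- cor(sig$score[match(names(x), sig$gene_id)], x,
               method = "spearman")
    expect_gt(rho, target - 0.05)
    expect_lt(rho, target + 0.05)
  }
  expect_error(simulate_signature(truth[0, ], 0.5), "empty")
  expect_error(simulate_signature(truth, 1.2), "target_rank_corr")
})

test_that("heavy ties in the truth cap the attainable rank correlation", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      class = "null",
                      lfc_A_8h = c(rep(0, 196), 2, 2, -2, -2),
                      stringsAsFactors = FALSE)
  expect_error(simulate_signature(truth, 0.95, seed = 1), "unattainable")
})

test_that("promoter simulation plants countable consensus instances", {
  truth <- data.frame(gene_id = c("gA", "gB", "gC"),
                      class = c("shared_up", "null", "null"),
                      lfc_X_8h = c(2, 0, 0), stringsAsFactors = FALSE)
  mot <- list(M1 = make_consensus_pwm("M1", "ACGTACGTAC"))
  pro <- simulate_promoters(truth, mot, enrichment_rate_deg = 3,
                            base_rate = 0.5, length = 1000, seed = 5)
  expect_identical(names(pro$sequences), truth$gene_id)
  expect_true(all(Biostrings::width(pro$sequences) == 1000))
  counts <- attr(pro$truth, "planted_counts")
  ## brute-force substring oracle finds exactly the planted instances
  for (g in truth$gene_id) {
    sq <- as.character(pro$sequences[[g]])
    found <- if (grepl("ACGTACGTAC", sq, fixed = TRUE))
      length(gregexpr("ACGTACGTAC", sq, fixed = TRUE)[[1]]) else 0L
    expect_identical(as.integer(found), unname(counts[g, "M1"]))
  }
  expect_error(simulate_promoters(truth, mot, length = 5),
               "wider than promoter")
})

test_that("empty planting leaves promoters at background rates", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:50), class = "null",
                      lfc_X_8h = 0, stringsAsFactors = FALSE)
  mot <- list(M1 = make_consensus_pwm("M1", "ACGTACGTAC"))
  pro <- simulate_promoters(truth, mot, enrichment_rate_deg = 0,
                            base_rate = 0, length = 500, seed = 2)
  expect_true(all(attr(pro$truth, "planted_counts") == 0))
})

test_that("promoter GC fractions follow the configured Beta", {
  truth <- data.frame(gene_id = sprintf("g%04d", 1:1000), class = "null",
                      lfc_X_8h = 0, stringsAsFactors = FALSE)
  mot <- list(M1 = make_consensus_pwm("M1", "ACGT"))
  pro <- simulate_promoters(truth, mot, enrichment_rate_deg = 0,
                            base_rate = 0, length = 200, seed = 3)
  expect_gt(mean(pro$truth$gc_fraction), 0.48)
  expect_lt(mean(pro$truth$gc_fraction), 0.52)
})

test_that("SNP planting respects the distance bound", {
  loci <- make_gene_loci(sprintf("g%04d", 1:200))
  targets <- sprintf("g%04d", 1:20)
  ## boundary: zero distance means inside the gene span
  sc0 <- simulate_snp_catalog(loci, targets, n_background_snps = 0,
                              n_planted = 30, max_planted_distance = 0,
                              seed = 6)
  tr <- sc0$truth
  rows <- loci[match(tr$planted_near_gene, loci$gene_id), ]
  expect_true(all(tr$pos >= rows$start & tr$pos < rows$end))

  sc <- simulate_snp_catalog(loci, targets, n_background_snps = 100,
                             n_planted = 30, max_planted_distance = 5e4,
                             seed = 7)
  planted <- sc$truth[!is.na(sc$truth$planted_near_gene), ]
  dd <- distance_to_nearest_snp(loci, sc$catalog, "IBD")
  expect_true(all(dd$distance[match(planted$planted_near_gene,
                                    dd$gene_id)] <= 5e4))
  expect_error(simulate_snp_catalog(loci[0, ], targets), "empty")
  expect_error(simulate_snp_catalog(loci, c("nope")), "absent")
})
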