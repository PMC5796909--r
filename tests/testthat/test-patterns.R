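make_profile <- function(mat) {
  class(mat) <- c("response_profile", class(mat))
  mat
}

test_that("response profiles assemble and filter like a brute-force row scan", {
  mk <- function(lfc, p) {
    d <- data.frame(gene_id = paste0("g", seq_along(lfc)), log2fc = lfc,
                    p = p, q = p, stringsAsFactors = FALSE)
    class(d) <- c("de_result", "data.frame")
    d
  }
  d1 <- mk(c(1, 0.1, -1.2), c(0.01, 0.5, 0.01))
  d2 <- mk(c(0.2, 0.3, -0.2), c(0.2, 0.6, 0.9))
  prof <- build_response_profile(list(A = d1, B = d2))
  expect_equal(dim(prof), c(3L, 2L))
  expect_equal(unname(prof[, "A"]), d1$log2fc)

  crit <- list(p_max = 0.05, fc_min = 1.5, fc_max = 0.67)
  filt <- build_response_profile(list(A = d1, B = d2), filter = crit)
  ## brute-force scan: keep a gene qualifying in >= 1 condition
  keep <- sapply(1:3, function(i) any(
    sapply(list(d1, d2), function(d)
      d$p[i] < 0.05 && (2^d$log2fc[i] > 1.5 || 2^d$log2fc[i] < 0.67))))
  expect_identical(rownames(filt), paste0("g", which(keep)))

  d3 <- mk(c(1, 1), c(0.1, 0.1))
  expect_error(build_response_profile(list(A = d1, B = d3)), "universes")
})

test_that("Spearman correlations follow the rank formula with tied handling", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  prof <- make_profile(cbind(a = x, b = y, c = -x))
  rc <- response_correlation(prof)
  expect_equal(unname(diag(rc)), rep(1, 3))
  ## brute-force rank formula: 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 0.8
  expect_equal(rc["a", "b"], 1 - 6 * sum((rank(x) - rank(y))^2) / (5 * 24))
  expect_equal(rc["a", "b"], 0.8)
  expect_equal(rc["a", "c"], -1)
  expect_warning(response_correlation(make_profile(cbind(a = x, k = rep(1, 5)))),
                 "constant")
})

test_that("condition clustering agglomerates by hand-checkable heights", {
  ## distances: d(A,B) = 0.1, d(A,C) = d(B,C) = 0.5
  corr <- matrix(c(1, 0.9, 0.5,
                   0.9, 1, 0.5,
                   0.5, 0.5, 1), 3, dimnames = list(LETTERS[1:3],
                                                    LETTERS[1:3]))
  hc <- cluster_conditions(corr)
  expect_equal(hc$height, c(0.1, 0.5))
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first_pair, c("A", "B"))
  ## permuting input order leaves the topology alone
  perm <- c(3, 1, 2)
  hc2 <- cluster_conditions(corr[perm, perm])
  expect_equal(sort(hc2$height), sort(hc$height))
  expect_error(cluster_conditions(matrix(c(1, NA, NA, 1), 2)), "missing")
})

test_that("gene clustering separates planted blobs and hits both cut extremes", {
  withr::with_seed(41, {
    blob1 <- matrix(rnorm(40, 0, 0.1), 20, 2)
    blob2 <- matrix(rnorm(40, 10, 0.1), 20, 2)
  })
  prof <- make_profile(rbind(blob1, blob2))
  rownames(prof) <- paste0("g", 1:40)
  cl <- cluster_genes(prof, k = 2)
  expect_equal(length(unique(cl[1:20])), 1L)
  expect_equal(length(unique(cl[21:40])), 1L)
  expect_false(cl[1] == cl[40])
  expect_equal(length(unique(cluster_genes(prof, k = 40))), 40L)
  expect_error(cluster_genes(prof, k = 41), "exceeds")
  ## duplicate profiles stay together at any k < n
  dup <- make_profile(rbind(prof, g_dup = prof[1, ]))
  cl2 <- cluster_genes(dup, k = 5)
  expect_equal(unname(cl2["g1"]), unname(cl2["g_dup"]))
})

test_that("PC response vectors are group-mean arrows in PC space", {
  withr::with_seed(43, {
    expr <- matrix(rnorm(50 * 8), 50, 8,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  })
  des <- data.frame(sample_id = paste0("s", 1:8),
                    treatment = rep(c("CTL", "TRT"), each = 4))
  ## identical groups: zero-length arrow
  expr_same <- cbind(expr[, 1:4], expr[, 1:4])
  colnames(expr_same) <- paste0("s", 1:8)
  v0 <- pc_response_vectors(expr_same, des)
  expect_equal(v0$x1 - v0$x0, 0, tolerance = 1e-10)
  expect_equal(v0$y1 - v0$y0, 0, tolerance = 1e-10)

  ## a dominant single-gene shift lands on PC1 with its full magnitude
  expr2 <- expr
  expr2[1, 5:8] <- expr2[1, 5:8] + 100
  v <- pc_response_vectors(expr2, des)
  len <- sqrt((v$x1 - v$x0)^2 + (v$y1 - v$y0)^2)
  expect_equal(len, 100, tolerance = 1)
  expect_error(pc_response_vectors(expr, des, treatments = "MISSING"),
               "no samples")
})

test_that("SOM training is deterministic and respects nearest-codebook assignment", {
  withr::with_seed(47, {
    centers <- matrix(c(0, 0, 0, 8, 8, 0, 8, 8), 4, 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:4, function(i)
      sweep(matrix(rnorm(60, 0, 0.3), 30, 2), 2, centers[i, ], "+")))
  })
  rownames(x) <- paste0("g", 1:120)
  prof <- make_profile(x)
  m1 <- fit_som(prof, grid = c(2, 2), epochs = 30, seed = 5)
  m2 <- fit_som(prof, grid = c(2, 2), epochs = 30, seed = 5)
  expect_identical(m1$codebook, m2$codebook)

  ## each node captures one blob (purity >= 0.95)
  truth <- rep(1:4, each = 30)
  purity <- mean(sapply(split(truth, m1$assignment), function(v)
    max(table(v)) / length(v)))
  expect_gte(purity, 0.95)

  ## assignments are global nearest codebooks, checked exhaustively
  for (i in seq_len(nrow(x))) {
    d2 <- rowSums(sweep(m1$codebook, 2, x[i, ])^2)
    expect_identical(unname(m1$assignment[i]), which.min(d2))
  }

  ## identical genes collapse to one node whose summary is their profile
  same <- make_profile(matrix(rep(c(1, -2), each = 30), 30, 2,
                              dimnames = list(paste0("h", 1:30), c("c1", "c2"))))
  ms <- fit_som(same, grid = c(1, 2), epochs = 10, seed = 3)
  expect_equal(length(unique(ms$assignment)), 1L)
  node <- unique(ms$assignment)
  expect_equal(summarize_som(ms, same, "c1")[node], 1)
  expect_true(is.na(summarize_som(ms, same, "c1")[3 - node]))
})

test_that("representative selection is an exact medoid with a stable tie rule", {
  prof <- make_profile(matrix(c(0, 1, 10, 0, 0, 0), 3, 2,
                              dimnames = list(c("gA", "gB", "gC"), NULL)))
  cl <- setNames(c(1, 1, 1), rownames(prof))
  expect_identical(unname(select_representatives(prof, cl)), "gB")

  ## brute-force O(n^2) oracle on random clusters
  withr::with_seed(53, {
    for (trial in 1:5) {
      n <- sample(20:200, 1)
      m <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("g%03d", 1:n),
                                                      NULL))
      cl <- setNames(sample(1:3, n, replace = TRUE), rownames(m))
      reps <- select_representatives(make_profile(m), cl)
      for (k in unique(cl)) {
        ids <- sort(names(cl)[cl == k])
        if (length(ids) == 1) { expect_identical(unname(reps[as.character(k)]), ids); next }
        dm <- as.matrix(dist(m[ids, , drop = FALSE]))
        best <- ids[which.min(rowSums(dm) / (length(ids) - 1))]
        expect_identical(unname(reps[as.character(k)]), best)
      }
    }
  })

  ## exact tie: lexicographically smaller id wins
  tie <- make_profile(matrix(c(0, 2, 1, 0, 0, 0), 3, 2,
                             dimnames = list(c("gB", "gA", "gM"), NULL)))
  cl3 <- setNames(rep(1, 3), rownames(tie))
  expect_identical(unname(select_representatives(tie, cl3)), "gM")
})

test_that("Chernoff mapping clips, centers and is deterministic", {
  genes <- sprintf("rep%02d", 1:15)
  prof <- make_profile(matrix(0, 15, 2,
                              dimnames = list(genes, c("c1", "c2"))))
  spec0 <- chernoff_mapping(prof, genes, "c1")
  expect_equal(unname(spec0$features), rep(0.5, 15))
  expect_equal(unname(spec0$colors), rep(0.5, 6))

  prof2 <- prof
  prof2[1, "c1"] <- 5      # beyond the +3 clip
  prof2[2, "c1"] <- -9     # beyond the -3 clip
  spec <- chernoff_mapping(prof2, genes, "c1")
  expect_equal(unname(spec$features[["face_height"]]), 1)
  expect_equal(unname(spec$features[["face_width"]]), 0)

  expect_identical(chernoff_mapping(prof2, genes, "c2")$features,
                   chernoff_mapping(prof2, genes, "c2")$features)
  expect_error(chernoff_mapping(prof, c(genes[-1], "nope"), "c1"), "nope")
  expect_error(chernoff_mapping(prof, genes[1:10], "c1"), "15")
})

test_that("Mahalanobis ellipse matches the chi-square quantile and counts points", {
  withr::with_seed(59, {
    x <- rnorm(10000); y <- rnorm(10000)
  })
  ell <- mahalanobis_ellipse(x, y, coverage = 0.75)
  expect_equal(ell$radius2, qchisq(0.75, df = 2), tolerance = 0.04)
  expect_identical(sum(ell$inside), as.integer(floor(0.75 * 10000)))

  ## data on a circle: all distances equal, the ellipse holds every point
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  circ <- mahalanobis_ellipse(cos(th), sin(th))
  expect_true(all(circ$inside))

  ## affine equivariance: transformed data give the transformed ellipse
  A <- matrix(c(2, 1, 0, 3), 2)
  b <- c(5, -4)
  m2 <- cbind(x, y) %*% t(A) + rep(b, each = 10000)
  ell2 <- mahalanobis_ellipse(m2[, 1], m2[, 2])
  expect_equal(unname(ell2$center), unname(A %*% ell$center + b)[, 1],
               tolerance = 1e-8)
  expect_equal(ell2$radius2, ell$radius2, tolerance = 1e-8)
  expect_identical(ell2$inside, ell$inside)

  expect_error(mahalanobis_ellipse(x[1:5], 2 * x[1:5]), "singular")
  expect_error(mahalanobis_ellipse(1:2, 2:3), "3 points")
})
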