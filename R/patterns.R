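#' Assemble the gene x condition log2 fold-change response profile
#'
#' Binds per-condition differential-expression tables into one matrix,
#' optionally restricted to genes passing a (p, FC) criterion in at least
#' one condition (the criterion used for global heatmap displays:
#' P < 0.05 with FC > 1.50 or FC < 0.67).
#'
#' @param de_list named list of `de_result` tables, one per condition; all
#'   must share the same gene universe.
#' @param filter NULL for no filtering, or a list with `p_max`, `fc_min`,
#'   `fc_max` (strict inequalities, gene kept if it qualifies in >= 1
#'   condition).
#' @return matrix of log2 FCs, genes x conditions, of class
#'   `response_profile`.
#' @export
build_response_profile <- function(de_list,
                                   filter = NULL) {
  stopifnot(length(de_list) >= 1)
  genes <- de_list[[1]]$gene_id
  for (i in seq_along(de_list)) {
    gi <- de_list[[i]]$gene_id
    if (!identical(sort(gi), sort(genes))) {
      d1 <- setdiff(genes, gi); d2 <- setdiff(gi, genes)
      stop("condition gene universes differ; e.g. ",
           paste(head(c(d1, d2), 5), collapse = ", "))
    }
  }
  prof <- sapply(de_list, function(d) d$log2fc[match(genes, d$gene_id)])
  rownames(prof) <- genes
  if (!is.null(filter)) {
    keep <- rep(FALSE, length(genes))
    for (d in de_list) {
      d <- d[match(genes, d$gene_id), ]
      fc <- 2^d$log2fc
      keep <- keep | (!is.na(d$p) & d$p < filter$p_max &
                      (fc > filter$fc_min | fc < filter$fc_max))
    }
    prof <- prof[keep, , drop = FALSE]
  }
  class(prof) <- c("response_profile", class(prof))
  prof
}

#' Spearman correlation among condition responses
#'
#' @param profile genes x conditions log2 FC matrix (>= 3 genes).
#' @return symmetric condition x condition Spearman matrix; constant
#'   columns yield NA entries with a warning.
#' @export
response_correlation <- function(profile) {
  if (nrow(profile) < 3) stop("need at least 3 genes")
  const <- apply(profile, 2, function(x) length(unique(x)) == 1L)
  if (any(const))
    warning("constant condition column(s): correlations undefined for ",
            paste(colnames(profile)[const], collapse = ", "))
  suppressWarnings(cor(unclass(profile), method = "spearman"))
}

#' Cluster conditions on correlation distance
#'
#' Average-linkage agglomeration on 1 - Spearman correlation.
#'
#' @param correlations condition x condition correlation matrix.
#' @return an `hclust` dendrogram.
#' @export
cluster_conditions <- function(correlations) {
  if (anyNA(correlations)) stop("missing correlations")
  hclust(as.dist(1 - correlations), method = "average")
}

#' Cluster genes on their response profiles
#'
#' @param profile genes x conditions log2 FC matrix.
#' @param k number of clusters to cut at.
#' @param linkage agglomeration method (default "average").
#' @param metric distance metric (default "euclidean").
#' @return named integer vector of cluster assignments.
#' @export
cluster_genes <- function(profile, k, linkage = "average",
                          metric = "euclidean") {
  if (nrow(profile) < 2) stop("need at least 2 genes")
  if (k > nrow(profile)) stop("k exceeds the number of genes")
  hc <- hclust(dist(unclass(profile), method = metric), method = linkage)
  cutree(hc, k = k)
}

#' Principal-component response vectors
#'
#' Computes sample principal components from centered log-scale expression
#' and, per treatment, the arrow from the control group's bivariate
#' (PC1, PC2) mean to the treatment group's mean.
#'
#' @param expr genes x samples matrix of log-scale abundances
#'   (e.g. log2(cpm + 1) of detected genes).
#' @param design sample design data.frame.
#' @param ref control label.
#' @param treatments treatments to draw arrows for (default: all
#'   non-control).
#' @param time optional time point to restrict to.
#' @return data.frame: treatment, x0, y0, x1, y1 (PC1/PC2 coordinates);
#'   sample scores in `attr(, "scores")`.
#' @export
pc_response_vectors <- function(expr, design, ref = "CTL",
                                treatments = NULL, time = NULL) {
  if (!is.null(time)) {
    design <- design[design$time == time, , drop = FALSE]
    expr <- expr[, design$sample_id, drop = FALSE]
  }
  if (is.null(treatments))
    treatments <- setdiff(unique(design$treatment), ref)
  pc <- prcomp(t(as.matrix(expr)), center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  grp_mean <- function(trt) {
    ids <- design$sample_id[design$treatment == trt]
    if (length(ids) == 0) stop("no samples for group ", trt)
    colMeans(sc[ids, , drop = FALSE])
  }
  ctl <- grp_mean(ref)
  out <- do.call(rbind, lapply(treatments, function(tr) {
    m <- grp_mean(tr)
    data.frame(treatment = tr, x0 = ctl[1], y0 = ctl[2],
               x1 = m[1], y1 = m[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "scores") <- sc
  out
}

#' Fit a self-organizing map to response profiles
#'
#' Online SOM training on a rectangular grid: codebooks are initialized on
#' the plane of the first two principal components, then updated by
#' stochastic presentation of gene profiles with a linearly decaying
#' learning rate and a Gaussian neighborhood whose radius shrinks linearly
#' from half the larger grid dimension to 0.5. Final assignments are exact
#' nearest codebooks (checked exhaustively).
#'
#' @param profile genes x conditions log2 FC matrix.
#' @param grid c(rows, cols); rows * cols >= 2.
#' @param epochs passes over the genes (default 100).
#' @param alpha learning rate, decaying linearly from `alpha[1]` to
#'   `alpha[2]` (default 0.05 to 0.01).
#' @param seed integer seed (presentation order and PC jitter).
#' @return object of class `som_model`: `codebook` (nodes x conditions),
#'   `grid`, `assignment` (named node index per gene), `meta`.
#' @export
fit_som <- function(profile, grid = c(10, 10), epochs = 100,
                    alpha = c(0.05, 0.01), seed = 1L) {
  x <- unclass(as.matrix(profile))
  n <- nrow(x); d <- ncol(x)
  nodes <- grid[1] * grid[2]
  if (nodes < 2) stop("grid must have at least 2 nodes")
  if (n < nodes) stop("need at least as many genes as nodes")
  gx <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
  with_seed(seed, {
    ## initialize codebooks on the PC1/PC2 plane spanning +/- 2 sd
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    v <- pc$rotation[, seq_len(min(2, ncol(pc$rotation))), drop = FALSE]
    sdv <- pc$sdev[seq_len(ncol(v))]
    u1 <- seq(-2, 2, length.out = grid[1]) * sdv[1]
    u2 <- if (ncol(v) > 1) seq(-2, 2, length.out = grid[2]) * sdv[2]
          else rep(0, grid[2])
    cb <- matrix(rep(colMeans(x), each = nodes), nodes, d)
    for (i in seq_len(nodes)) {
      cb[i, ] <- cb[i, ] + u1[gx[i, 1]] * v[, 1] +
        (if (ncol(v) > 1) u2[gx[i, 2]] * v[, 2] else 0)
    }
    r0 <- max(grid) / 2
    total <- epochs * n
    step <- 0
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        frac <- step / max(1, total - 1)
        a <- alpha[1] + (alpha[2] - alpha[1]) * frac
        r <- r0 + (0.5 - r0) * frac
        dists <- rowSums(sweep(cb, 2, x[i, ])^2)
        bmu <- which.min(dists)
        gd2 <- (gx[, 1] - gx[bmu, 1])^2 + (gx[, 2] - gx[bmu, 2])^2
        h <- a * exp(-gd2 / (2 * r^2))
        upd <- which(h > 1e-4)
        cb[upd, ] <- cb[upd, ] +
          h[upd] * (matrix(x[i, ], length(upd), d, byrow = TRUE) -
                      cb[upd, , drop = FALSE])
        step <- step + 1
      }
    }
    asg <- som_assign(cb, x)
    structure(list(codebook = cb, grid = grid, grid_coords = gx,
                   assignment = asg,
                   meta = list(epochs = epochs, alpha = alpha,
                               radius0 = r0, seed = seed)),
              class = "som_model")
  })
}

som_assign <- function(codebook, x) {
  ## exact nearest codebook per row of x
  cross <- x %*% t(codebook)
  d2 <- outer(rowSums(x^2), rowSums(codebook^2), "+") - 2 * cross
  asg <- max.col(-d2, ties.method = "first")
  names(asg) <- rownames(x)
  asg
}

#' Per-node mean fold change for one condition
#'
#' @param model a `som_model`.
#' @param profile the profile the model was fitted on (or any profile with
#'   the same genes).
#' @param condition condition column to summarize.
#' @return numeric vector over nodes; empty nodes are NA.
#' @export
summarize_som <- function(model, profile, condition) {
  x <- unclass(as.matrix(profile))[names(model$assignment), condition]
  out <- rep(NA_real_, nrow(model$codebook))
  agg <- tapply(x, model$assignment, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Medoid representative of each gene cluster
#'
#' Selects, per cluster, the gene with the lowest average Euclidean
#' distance to all other members; ties break to the lexicographically
#' smallest gene id.
#'
#' @param profile genes x conditions log2 FC matrix.
#' @param clusters named cluster assignment (as from [cluster_genes()]).
#' @return named character vector: cluster -> representative gene id.
#' @export
select_representatives <- function(profile, clusters) {
  x <- unclass(as.matrix(profile))
  vapply(split(names(clusters), clusters), function(members) {
    members <- sort(members)
    if (length(members) == 1L) return(members)
    dm <- as.matrix(dist(x[members, , drop = FALSE]))
    avg <- rowSums(dm) / (length(members) - 1)
    members[which.min(avg)]        # ties: first of the sorted ids
  }, character(1))
}

chernoff_features <- c("face_height", "face_width", "face_structure",
                       "mouth_height", "mouth_width", "smiling",
                       "eye_height", "eye_width", "hair_height",
                       "hair_width", "hair_style", "nose_height",
                       "nose_width", "ear_width", "ear_height")

chernoff_color_groups <- list(face = c("face_height", "face_width"),
                              lips = c("face_height", "face_width",
                                       "face_structure"),
                              eyes = c("eye_height", "eye_width"),
                              hair = c("hair_height", "hair_width",
                                       "hair_style"),
                              nose = c("nose_height", "nose_width"),
                              ears = c("ear_width", "ear_height"))

#' Map 15 representative-gene responses to Chernoff-face parameters
#'
#' log2 FCs are clipped to [-clip, clip] and affinely mapped to [0, 1]
#' (so a neutral response gives 0.5). Feature-group colors are the mean
#' mapped value of the genes in the group.
#'
#' @param profile response profile containing the 15 genes.
#' @param genes character vector of 15 gene ids, in the canonical feature
#'   order (face height, face width, face structure, mouth height, mouth
#'   width, smiling, eye height, eye width, hair height, hair width, hair
#'   style, nose height, nose width, ear width, ear height).
#' @param condition condition column to map.
#' @param clip clip range in log2 units (default 3).
#' @return list of class `face_spec`: `features` (named 15-vector in
#'   [0, 1]), `colors` (named group means), `genes` (feature -> gene map),
#'   `condition`.
#' @export
chernoff_mapping <- function(profile, genes, condition, clip = 3) {
  if (length(genes) != 15) stop("exactly 15 genes are required")
  missing <- setdiff(genes, rownames(profile))
  if (length(missing) > 0)
    stop("gene(s) absent from profile: ", paste(missing, collapse = ", "))
  lfc <- unclass(as.matrix(profile))[genes, condition]
  val <- (pmin(pmax(lfc, -clip), clip) + clip) / (2 * clip)
  names(val) <- chernoff_features
  cols <- vapply(chernoff_color_groups, function(g) mean(val[g]), numeric(1))
  structure(list(features = val, colors = cols,
                 genes = setNames(genes, chernoff_features),
                 condition = condition, clip = clip),
            class = "face_spec")
}

#' Mahalanobis coverage ellipse of a bivariate fold-change cloud
#'
#' The ellipse is the Mahalanobis-distance contour at the empirical
#' `coverage` quantile of squared distances, so at least
#' floor(coverage * n) points lie inside or on the boundary (exactly that
#' many for distinct distances).
#'
#' @param x,y numeric vectors (>= 3 points).
#' @param coverage fraction of points to enclose (default 0.75).
#' @return list: `center`, `cov`, `radius2` (squared Mahalanobis radius),
#'   `axes` (semi-axis lengths), `angle` (radians of the major axis),
#'   `inside` (logical per point).
#' @export
mahalanobis_ellipse <- function(x, y, coverage = 0.75) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  m <- cbind(x, y)
  ctr <- colMeans(m)
  S <- cov(m)
  if (abs(det(S)) < 1e-12) stop("singular covariance")
  d2 <- mahalanobis(m, ctr, S)
  r2 <- sort(d2)[floor(coverage * n)]
  eg <- eigen(S, symmetric = TRUE)
  list(center = ctr, cov = S, radius2 = r2,
       axes = sqrt(eg$values * r2),
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       inside = d2 <= r2 + 1e-12)
}
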