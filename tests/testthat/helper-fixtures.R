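## Shared fixture builders; everything is generated in code.

## small two-group count matrix with optional planted log2 fold changes
make_two_group_counts <- function(n_genes, n_per_group = 3, mu_range = c(20, 500),
                                  lfc = rep(0, n_genes), phi = 0.1,
                                  seed = 1) {
  withr::with_seed(seed, {
    mu <- exp(runif(n_genes, log(mu_range[1]), log(mu_range[2])))
    ns <- 2 * n_per_group
    grp <- rep(0:1, each = n_per_group)
    cts <- sapply(seq_len(ns), function(s) {
      m <- mu * 2^(lfc * grp[s])
      if (phi < 1e-12) rpois(n_genes, m)
      else rnbinom(n_genes, mu = m, size = 1 / phi)
    })
    dimnames(cts) <- list(sprintf("g%05d", seq_len(n_genes)),
                          paste0("s", seq_len(ns)))
    des <- data.frame(sample_id = colnames(cts),
                      treatment = factor(rep(c("CTL", "TRT"),
                                             each = n_per_group),
                                         levels = c("CTL", "TRT")))
    list(counts = cts, design = des)
  })
}

## sharp PWM whose consensus is the given word
make_consensus_pwm <- function(id, cons, p = 0.97) {
  b <- c(A = 1, C = 2, G = 3, T = 4)
  m <- matrix((1 - p) / 3, nchar(cons), 4)
  for (i in seq_len(nchar(cons))) m[i, b[substr(cons, i, i)]] <- p
  pwm(id, m)
}

random_dna <- function(n, seed = 1, letters = c("A", "C", "G", "T")) {
  withr::with_seed(seed,
    paste(sample(letters, n, replace = TRUE), collapse = ""))
}

## naive O(L * w) window rescoring oracle for the PWM scanner
naive_scan <- function(seq_char, motif, threshold_fraction = 0.8,
                       both_strands = TRUE, pseudocount = 1e-3) {
  S <- log2(t(t(motif$mat + pseudocount) / motif$background))
  thr <- sum(apply(S, 1, min)) +
    threshold_fraction * (sum(apply(S, 1, max)) - sum(apply(S, 1, min)))
  count_fwd <- function(sq) {
    ch <- strsplit(sq, "")[[1]]
    w <- nrow(S)
    n <- 0L
    if (length(ch) < w) return(0L)
    for (st in seq_len(length(ch) - w + 1)) {
      win <- ch[st:(st + w - 1)]
      if (any(win == "N")) next
      sc <- 0
      for (j in seq_len(w)) sc <- sc + S[j, win[j]]
      if (sc >= thr - 1e-9) n <- n + 1L
    }
    n
  }
  n <- count_fwd(seq_char)
  if (both_strands) {
    comp <- chartr("ACGTN", "TGCAN", seq_char)
    rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
    n <- n + count_fwd(rc)
  }
  n
}

## brute-force BH step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in (m - 1):1)
    q[o[i]] <- min(q[o[i + 1]], m * p[o[i]] / i)
  pmin(q, 1)
}

## enumeration oracle for the upper hypergeometric tail: probability that a
## uniformly drawn DEG set of size k overlaps the annotation set (size m,
## universe n) in at least x genes
enum_hyper_tail <- function(x, m, n, k) {
  combos <- combn(n, k)
  mean(colSums(combos <= m) >= x)
}
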