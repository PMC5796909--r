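#' Construct a position-probability matrix motif
#'
#' @param id motif identifier.
#' @param mat width x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1 (tolerance 1e-6).
#' @param background base composition used for log-odds scoring (default
#'   uniform).
#' @return object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  if (nrow(mat) < 1) stop("empty matrix")
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("PWM rows must sum to 1 (motif ", id, ")")
  structure(list(id = id, mat = mat, background = background),
            class = "pwm")
}

#' Consensus sequence of a PWM (argmax base per position)
#'
#' Ties resolve to the alphabetically first base, making the consensus
#' deterministic (and the planted-instance counting oracle exact).
#'
#' @param x a `pwm` object.
#' @return character scalar.
#' @export
consensus <- function(x) {
  paste(colnames(x$mat)[max.col(x$mat, ties.method = "first")],
        collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections.
#'
#' @param path path to a MEME-format file.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    h <- s + grep("letter-probability matrix",
                  lines[(s + 1):min(s + 10, length(lines))])[1]
    if (is.na(h)) stop("motif ", id, " lacks a letter-probability matrix")
    rows <- list()
    i <- h + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    if (length(rows) == 0) stop("empty matrix for motif ", id)
    out[[id]] <- pwm(id, do.call(rbind, rows))
  }
  out
}

#' Read motifs in JASPAR PFM format
#'
#' Count matrices (`>ID` header, then four `A [ ... ]` style rows) are
#' column-normalized to probabilities on read.
#'
#' @param path path to a JASPAR-format file.
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR records found in ", path)
  out <- list()
  for (h in heads) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    rows <- lapply(lines[h + 1:4], function(l) {
      as.numeric(strsplit(trimws(gsub("[^0-9.eE+-]+", " ", l)),
                          "\\s+")[[1]])
    })
    m <- do.call(cbind, rows)       # width x 4, rows were A C G T
    m <- m / rowSums(m)
    out[[id]] <- pwm(id, m)
  }
  out
}

encode_dna <- function(seq_char, record = "?") {
  code <- match(strsplit(toupper(seq_char), "")[[1]],
                c("A", "C", "G", "T", "N"))
  if (anyNA(code))
    stop("invalid alphabet in record ", record)
  code[code == 5L] <- NA_integer_     # N: windows covering it never score
  code
}

#' Count PWM hits in a set of sequences
#'
#' Scores every window of width w with the log-odds matrix
#' log2((p + pseudocount) / background); a window is a hit when its score
#' reaches `threshold_fraction` of the attainable score range
#' (min + fraction * (max - min)). Overlapping hits are counted
#' individually; with `both_strands` the reverse complement is scanned as
#' well (a palindromic instance therefore counts once per strand). Windows
#' containing N never score.
#'
#' @param sequences a named character vector or
#'   [Biostrings::DNAStringSet] of promoter sequences over A/C/G/T/N.
#' @param motif a `pwm` object.
#' @param threshold_fraction relative score threshold in (0, 1]
#'   (default 0.8).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param pseudocount added to probabilities before log-odds (default
#'   1e-3).
#' @return named integer vector of hit counts per sequence.
#' @export
scan_pwm <- function(sequences, motif, threshold_fraction = 0.8,
                     both_strands = TRUE, pseudocount = 1e-3) {
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  S <- log2(t(t(motif$mat + pseudocount) / motif$background))
  smax <- sum(apply(S, 1, max))
  smin <- sum(apply(S, 1, min))
  thr <- smin + threshold_fraction * (smax - smin)
  w <- nrow(S)
  count_one <- function(code) {
    L <- length(code)
    if (L < w) return(0L)
    nwin <- L - w + 1L
    sc <- numeric(nwin)
    bad <- logical(nwin)
    for (j in seq_len(w)) {
      cj <- code[j:(j + nwin - 1L)]
      bad <- bad | is.na(cj)
      v <- S[j, ifelse(is.na(cj), 1L, cj)]
      sc <- sc + v
    }
    sum(!bad & sc >= thr - 1e-9)
  }
  vapply(seq_along(sequences), function(i) {
    code <- encode_dna(sequences[i], names(sequences)[i] %||% i)
    n <- count_one(code)
    if (both_strands) {
      rc <- rev(5L - code)              # A<->T, C<->G; NA stays NA
      n <- n + count_one(rc)
    }
    as.integer(n)
  }, integer(1)) -> counts
  names(counts) <- names(sequences)
  counts
}

#' Count hits for a motif dictionary over a promoter set
#'
#' @param sequences promoter sequences (see [scan_pwm()]).
#' @param motifs named list of `pwm` objects.
#' @inheritParams scan_pwm
#' @return gene x motif integer matrix with scan parameters in
#'   `attr(, "meta")`.
#' @export
scan_motifs <- function(sequences, motifs, threshold_fraction = 0.8,
                        both_strands = TRUE, pseudocount = 1e-3) {
  hits <- vapply(motifs, function(m)
    scan_pwm(sequences, m, threshold_fraction, both_strands, pseudocount),
    integer(length(sequences)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(sequences))
  dimnames(hits) <- list(names(sequences), names(motifs))
  attr(hits, "meta") <- list(threshold_fraction = threshold_fraction,
                             both_strands = both_strands,
                             pseudocount = pseudocount)
  hits
}

#' Spline-adjusted logistic enrichment of motif counts in DEG promoters
#'
#' Per motif, fits logit P(DEG) = a + b * count + s(GC) with s a fixed
#' natural cubic spline basis (df = 4), and tests b = 0 with a two-sided
#' likelihood-ratio chi-square. The GC smooth absorbs compositional
#' confounding between promoter GC content and both DEG status and motif
#' GC-richness. BH adjustment runs across converged motifs; degenerate
#' (constant-count) or non-converged fits are flagged and excluded.
#'
#' @param hits gene x motif count matrix from [scan_motifs()].
#' @param deg logical vector (or character vector of DEG gene ids) over
#'   the rows of `hits`.
#' @param gc per-gene GC fraction (named or in row order of `hits`).
#' @param spline_df spline degrees of freedom (default 4); 0 disables the
#'   GC adjustment.
#' @param fdr_max FDR threshold for the enriched/depleted label
#'   (default 0.10).
#' @return data.frame: motif, beta (log-odds per extra site), p, q,
#'   direction ("enriched"/"depleted"/NA), converged.
#' @export
motif_logistic_enrichment <- function(hits, deg, gc, spline_df = 4,
                                      fdr_max = 0.10) {
  if (is.character(deg)) deg <- rownames(hits) %in% deg
  stopifnot(length(deg) == nrow(hits))
  if (!any(deg) || all(deg)) stop("both DEG and background must be non-empty")
  if (!is.null(names(gc))) gc <- gc[rownames(hits)]
  base <- if (spline_df > 0) splines::ns(gc, df = spline_df) else NULL
  rows <- lapply(colnames(hits), function(mo) {
    cnt <- hits[, mo]
    if (length(unique(cnt)) < 2L)
      return(data.frame(motif = mo, beta = NA_real_, p = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    d1 <- if (is.null(base)) data.frame(deg = deg, cnt = cnt)
          else data.frame(deg = deg, cnt = cnt, base = I(base))
    f1 <- if (is.null(base)) deg ~ cnt else deg ~ cnt + base
    f0 <- if (is.null(base)) deg ~ 1 else deg ~ base
    fit1 <- suppressWarnings(glm(f1, family = binomial(), data = d1))
    fit0 <- suppressWarnings(glm(f0, family = binomial(), data = d1))
    beta <- coef(fit1)[["cnt"]]
    ok <- fit1$converged && fit0$converged && is.finite(beta) &&
      abs(beta) < 15
    p <- if (ok) pchisq(fit0$deviance - fit1$deviance, df = 1,
                        lower.tail = FALSE) else NA_real_
    data.frame(motif = mo, beta = beta, p = p, converged = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$converged))
    warning(sum(!out$converged),
            " motif(s) degenerate or non-converged; excluded from BH")
  out$q <- NA_real_
  out$q[out$converged] <- bh_adjust(out$p[out$converged])
  out$direction <- ifelse(!out$converged, NA_character_,
                          ifelse(out$beta > 0, "enriched", "depleted"))
  out
}

#' Family-level summary of enriched motifs
#'
#' Counts enriched motifs (beta > 0, q < fdr_max) per transcription-factor
#' family and tests family over-representation among enriched motifs with
#' the hypergeometric test over all tested motifs.
#'
#' @param rows output of [motif_logistic_enrichment()].
#' @param family_map named character vector motif -> family; motifs
#'   without a mapping count as "unknown".
#' @param fdr_max FDR threshold defining "enriched" (default 0.10).
#' @return data.frame per family: set_id (family), overlap (enriched
#'   motifs in family), set_size, p, q (see
#'   [hypergeometric_enrichment()]), plus `n_enriched` attribute.
#' @export
summarize_enriched_motifs <- function(rows, family_map, fdr_max = 0.10) {
  fam <- family_map[rows$motif]
  fam[is.na(fam)] <- "unknown"
  enriched <- rows$motif[!is.na(rows$q) & rows$q < fdr_max & rows$beta > 0]
  sets <- split(rows$motif, fam)
  out <- hypergeometric_enrichment(enriched, sets, universe = rows$motif)
  attr(out, "n_enriched") <- length(enriched)
  out
}
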