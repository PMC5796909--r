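#' @keywords internal
#' @import stats
#' @import utils
#' @importFrom splines ns
#' @importFrom tools md5sum
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom Biostrings DNAStringSet
"_PACKAGE"

## Run code under a fixed RNG state, restoring the caller's state afterwards.
## Every generator in the package is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a per-stage sub-seed from a global seed so that toggling one stage
## cannot shift the random stream of another. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Counts per million mapped reads
#'
#' Library-size-scaled abundance used by the detection filter and for
#' display-scale fold changes.
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return numeric matrix of the same shape as `counts`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    if (is.null(bad)) bad <- which(lib_sizes <= 0)
    stop("zero or negative library size for sample(s): ",
         paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, lib_sizes / 1e6, "/")
}

## TSV writer with '#'-prefixed provenance header lines (greppable, diffable).
write_tsv_meta <- function(x, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member genes, tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
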