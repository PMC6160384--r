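#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as input and output, which is what the simulators and
#' the exact placer work with internally.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. All simulators use this so that "one seeded RNG per call" holds
## and repeated calls are byte-identical.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Random DNA string(s) of the given lengths (vectorized: one draw of
## sum(lengths) bases chopped at cumulative offsets).
random_dna <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  s <- paste(sample(DNA_BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(s, ends - lengths + 1L, ends)
}

#' Read and write tab-separated tables
#'
#' All tabular inputs and outputs of the pipeline (count matrices, truth
#' tables, result tables) are plain TSV with a header line and no quoting.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

## Write a features x samples matrix as TSV with an `id` first column.
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## uniform integer draw from [a, b] (safe when a == b, unlike sample(x, 1))
sample_range <- function(a, b, n = 1L) {
  if (a >= b) rep(a, n) else sample(seq(a, b), n, replace = TRUE)
}
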