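#' Trim the 3' adapter from reads
#'
#' Scans candidate adapter start positions left to right and removes the
#' first admissible occurrence (full or 3'-truncated) together with
#' everything after it. An occurrence is admissible when the overlap
#' between the adapter prefix and the read is at least `min_overlap` bases
#' with at most `max_mismatch` mismatches. When no occurrence is found the
#' last 6 bases are removed instead. Reads whose remainder is shorter than
#' `min_len` are discarded (returned as `NA`).
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap minimum adapter/read overlap in bases.
#' @param max_mismatch maximum mismatches allowed in the overlap.
#' @param min_len minimum insert length kept after trimming.
#' @return character vector of trimmed inserts, `NA` where discarded.
#' @examples
#' trim_adapter(paste0(strrep("ACGT", 5), TRUSEQ_ADAPTER), TRUSEQ_ADAPTER)
#' @export
trim_adapter <- function(reads, adapter = TRUSEQ_ADAPTER,
                         min_overlap = 6L, max_mismatch = 2L, min_len = 10L) {
  if (nchar(adapter) < min_overlap) stopf("adapter shorter than min_overlap")
  n <- length(reads)
  if (n == 0L) return(character(0))
  lens <- nchar(reads)
  W <- max(lens, 1L)
  padded <- formatC(reads, width = W, flag = "-")   # right-pad with spaces
  bytes <- matrix(as.integer(charToRaw(paste(padded, collapse = ""))), nrow = W)
  a <- as.integer(charToRaw(adapter))
  alen <- length(a)

  found <- rep(NA_integer_, n)
  max_s <- max(lens) - min_overlap + 1L
  s <- 1L
  while (s <= max_s) {
    active <- is.na(found) & (s <= lens - min_overlap + 1L)
    if (!any(active)) break
    ov <- pmin(alen, lens - s + 1L)
    jmax <- min(alen, W - s + 1L)
    run <- integer(n)
    mm <- rep(NA_integer_, n)
    for (j in seq_len(jmax)) {
      run <- run + (bytes[s + j - 1L, ] != a[j])
      hit <- ov == j
      if (any(hit)) mm[hit] <- run[hit]
    }
    adm <- active & ov >= min_overlap & !is.na(mm) & mm <= max_mismatch
    found[adm] <- s
    s <- s + 1L
  }
  trimmed <- ifelse(is.na(found),
                    substr(reads, 1L, pmax(lens - 6L, 0L)),
                    substr(reads, 1L, found - 1L))
  trimmed[nchar(trimmed) < min_len | lens == 0L] <- NA_character_
  trimmed
}

#' Collapse trimmed reads into unique reads
#'
#' Groups identical sequences, counts multiplicities, drops sequences seen
#' fewer than `min_count` times, and orders the result by count descending
#' then sequence lexicographically.
#'
#' @param trimmed character vector of trimmed reads (`NA`s are ignored).
#' @param min_count minimum multiplicity kept.
#' @return data.frame with columns `sequence`, `count`.
#' @export
collapse_reads <- function(trimmed, min_count = 3L) {
  trimmed <- trimmed[!is.na(trimmed)]
  if (length(trimmed) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  tab <- table(trimmed)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[df$count >= min_count, , drop = FALSE]
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Hash index of all genome substrings of the given length; returns an
## environment mapping sequence -> integer vector of 0-based start positions.
substring_index <- function(seq, L) {
  G <- nchar(seq)
  if (L > G) return(list())
  starts <- seq_len(G - L + 1L)
  subs <- substring(seq, starts, starts + L - 1L)
  split(starts - 1L, subs)
}

#' Place unique reads on a genome by exact match
#'
#' Reports every zero-mismatch occurrence of each unique read on both
#' strands of every chromosome. Minus-strand placements store the genomic
#' interval of the reverse complement. Reads containing `N` never match.
#' Reads with no placement are omitted.
#'
#' @param unique_reads data.frame with `sequence`, `count` (from
#'   [collapse_reads()]).
#' @param genome named character vector of chromosome sequences, or a
#'   `mirna_reference`.
#' @return data.frame with columns `sequence, count, chrom, start, end,
#'   strand, mismatches` (0-based half-open intervals, `mismatches` always
#'   0).
#' @export
place_exact <- function(unique_reads, genome) {
  if (inherits(genome, "mirna_reference")) genome <- genome$genome
  if (length(genome) == 0L) stopf("genome is empty")
  empty <- data.frame(sequence = character(0), count = integer(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0))
  if (nrow(unique_reads) == 0L) return(empty)
  lens <- nchar(unique_reads$sequence)
  rc <- revcomp(unique_reads$sequence)
  out <- list()
  for (chrom in names(genome)) {
    for (L in sort(unique(lens))) {
      idx <- substring_index(genome[[chrom]], L)
      if (length(idx) == 0L) next
      sel <- which(lens == L)
      for (i in sel) {
        fw <- idx[[unique_reads$sequence[i]]]
        if (!is.null(fw)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = unique_reads$sequence[i], count = unique_reads$count[i],
            chrom = chrom, start = fw, end = fw + L, strand = "+",
            mismatches = 0L, stringsAsFactors = FALSE)
        }
        rv <- idx[[rc[i]]]
        if (!is.null(rv)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = unique_reads$sequence[i], count = unique_reads$count[i],
            chrom = chrom, start = rv, end = rv + L, strand = "-",
            mismatches = 0L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full read-preprocessing stage
#'
#' Adapter trimming, read collapsing with a multiplicity floor, and exact
#' placement of the surviving unique reads on the genome.
#'
#' @param reads character vector of raw reads, or a FASTQ path.
#' @param genome named character vector or `mirna_reference`.
#' @param adapter 3' adapter sequence.
#' @param min_count multiplicity floor for unique reads.
#' @param ... passed to [trim_adapter()].
#' @return list with `unique_reads`, `placements`, `unplaced` (unique reads
#'   with zero exact placements, used downstream for non-template 3'
#'   extension calls) and `stats` (total, trimmed, collapsed, placed read
#'   counts).
#' @export
preprocess_reads <- function(reads, genome, adapter = TRUSEQ_ADAPTER,
                             min_count = 3L, ...) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  trimmed <- trim_adapter(reads, adapter, ...)
  uniq <- collapse_reads(trimmed, min_count = min_count)
  plc <- place_exact(uniq, genome)
  unplaced <- uniq[!(uniq$sequence %in% plc$sequence), , drop = FALSE]
  stats <- c(total = length(reads), kept = sum(!is.na(trimmed)),
             unique = nrow(uniq), placed_unique = length(unique(plc$sequence)))
  list(unique_reads = uniq, placements = plc, unplaced = unplaced, stats = stats)
}

#' Write placements as BED6
#'
#' 0-based half-open intervals; the score column carries the read count.
#'
#' @param placements data.frame from [place_exact()].
#' @param path output path.
#' @export
write_placements_bed <- function(placements, path) {
  bed <- data.frame(placements$chrom, placements$start, placements$end,
                    placements$sequence, placements$count, placements$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
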