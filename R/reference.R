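#' Default 3' sequencing adapter
#'
#' The TruSeq small-RNA 3' adapter. The library-preparation kit sequence is
#' configurable everywhere it is used; this constant is only the default.
#' @export
TRUSEQ_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

## Introduce `k` substitutions at distinct positions of `seq`.
wobble_seq <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Build a toy hairpin reference genome
#'
#' Constructs a single-chromosome genome with `n_precursors` embedded
#' miRNA hairpins. Each hairpin is, in transcript orientation, a 5' mature
#' arm, a fixed-length terminal loop, and a 3' mature arm equal to the
#' reverse complement of the 5' arm with 1-2 planted substitutions (so the
#' two arms can base-pair into a stem-loop but their mature sequences are
#' distinct). Precursors alternate between the + and - genomic strand and
#' are separated by random spacer sequence.
#'
#' All coordinates in the returned object are 0-based half-open on the
#' genomic + strand; [write_reference()] converts to 1-based inclusive GFF3.
#'
#' @param n_precursors number of hairpins to embed (>= 1).
#' @param seed RNG seed; the same seed gives a byte-identical reference.
#' @param arm_len_range inclusive range of mature arm lengths in nt.
#' @param loop_len terminal loop length in nt.
#' @param spacer_range inclusive range of inter-hairpin spacer lengths.
#' @param max_wobbles maximum number of substitutions planted in the 3' arm
#'   relative to the reverse complement of the 5' arm (1 to `max_wobbles`
#'   are used, so arms are never perfect palindromes).
#' @param frac_single_annotated fraction of precursors for which only one
#'   arm carries a named mature product (the other arm is left un-annotated,
#'   emulating gaps in miRNA databases).
#' @param adapter 3' adapter sequence carried along for the read simulator.
#' @return an object of class `mirna_reference`: a list with elements
#'   `genome` (named character vector of chromosome sequences),
#'   `precursors` (data.frame with columns `id, chrom, start, end, strand,
#'   arm5_start, arm5_end, arm3_start, arm3_end, mature5_id, mature3_id`),
#'   `loop_len` and `adapter`.
#' @examples
#' ref <- build_reference(5, seed = 1)
#' mature_sequences(ref)
#' @export
build_reference <- function(n_precursors, seed = NULL,
                            arm_len_range = c(20L, 24L),
                            loop_len = 12L,
                            spacer_range = c(40L, 80L),
                            max_wobbles = 2L,
                            frac_single_annotated = 0,
                            adapter = TRUSEQ_ADAPTER) {
  if (n_precursors < 1) stopf("n_precursors must be >= 1")
  if (max_wobbles < 1 || max_wobbles > 2) stopf("max_wobbles must be 1 or 2")
  with_seed(seed, {
    pieces <- character(0)
    pos <- 0L
    rows <- vector("list", n_precursors)
    for (i in seq_len(n_precursors)) {
      L <- sample_range(arm_len_range[1], arm_len_range[2])
      arm5 <- random_dna(L)
      arm3 <- wobble_seq(revcomp(arm5), sample_range(1L, max_wobbles))
      hairpin <- paste0(arm5, random_dna(loop_len), arm3)   # transcript orientation
      strand <- if (i %% 2L == 1L) "+" else "-"
      locus_seq <- if (strand == "+") hairpin else revcomp(hairpin)
      spacer <- random_dna(sample_range(spacer_range[1], spacer_range[2]))
      pieces <- c(pieces, spacer, locus_seq)
      ps <- pos + nchar(spacer)
      pe <- ps + nchar(hairpin)
      pos <- pe
      plen <- nchar(hairpin)
      if (strand == "+") {
        a5 <- c(ps, ps + L); a3 <- c(pe - L, pe)
      } else {
        a5 <- c(pe - L, pe); a3 <- c(ps, ps + L)
      }
      rows[[i]] <- data.frame(
        id = sprintf("pre-mir-%d", i), chrom = "chr1",
        start = ps, end = pe, strand = strand,
        arm5_start = a5[1], arm5_end = a5[2],
        arm3_start = a3[1], arm3_end = a3[2],
        mature5_id = sprintf("miR-%d-5p", i),
        mature3_id = sprintf("miR-%d-3p", i),
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, random_dna(sample_range(spacer_range[1], spacer_range[2])))
    pre <- do.call(rbind, rows)
    if (frac_single_annotated > 0) {
      k <- round(frac_single_annotated * n_precursors)
      if (k > 0) {
        drop <- sample(n_precursors, k)
        which5 <- runif(k) < 0.5
        pre$mature5_id[drop[which5]] <- NA_character_
        pre$mature3_id[drop[!which5]] <- NA_character_
      }
    }
    ref <- structure(
      list(genome = c(chr1 = paste(pieces, collapse = "")),
           precursors = pre, loop_len = loop_len, adapter = adapter),
      class = "mirna_reference")
    validate_reference(ref)
    ref
  })
}

validate_reference <- function(ref) {
  p <- ref$precursors
  glen <- nchar(ref$genome[p$chrom])
  if (any(p$start < 0 | p$end > glen)) stopf("precursor interval out of bounds")
  ok_in <- p$arm5_start >= p$start & p$arm5_end <= p$end &
    p$arm3_start >= p$start & p$arm3_end <= p$end
  if (!all(ok_in)) stopf("mature arm outside its precursor")
  overlap <- pmax(0, pmin(p$arm5_end, p$arm3_end) - pmax(p$arm5_start, p$arm3_start))
  if (any(overlap > 0)) stopf("mature arms of one precursor overlap")
  alen5 <- p$arm5_end - p$arm5_start
  if (any(alen5 < 20 | alen5 > 24)) stopf("arm length outside [20,24]")
  invisible(ref)
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("mirna_reference: %d chromosome(s), %d precursors, genome %d nt\n",
              length(x$genome), nrow(x$precursors), sum(nchar(x$genome))))
  invisible(x)
}

## Extract a genomic interval in transcript orientation.
## start/end 0-based half-open on the + strand.
extract_tx <- function(genome, chrom, start, end, strand) {
  s <- substring(genome[chrom], start + 1L, end)
  ifelse(strand == "-", revcomp(s), s)
}

#' Mature miRNA sequences of a reference
#'
#' @param ref a `mirna_reference`.
#' @return named character vector of mature sequences in transcript
#'   orientation, including sequences of un-annotated arms under synthetic
#'   ids of the form `<precursor>:unannotated-<arm>` (those names never
#'   appear in the GFF3).
#' @export
mature_sequences <- function(ref) {
  p <- ref$precursors
  id5 <- ifelse(is.na(p$mature5_id), paste0(p$id, ":unannotated-5p"), p$mature5_id)
  id3 <- ifelse(is.na(p$mature3_id), paste0(p$id, ":unannotated-3p"), p$mature3_id)
  s5 <- extract_tx(ref$genome, p$chrom, p$arm5_start, p$arm5_end, p$strand)
  s3 <- extract_tx(ref$genome, p$chrom, p$arm3_start, p$arm3_end, p$strand)
  setNames(c(s5, s3), c(id5, id3))
}

## Long-format mature arm table used by the profiler: one row per arm.
mature_table <- function(ref, include_unannotated = FALSE) {
  p <- ref$precursors
  arm <- function(which) {
    idcol <- if (which == "5p") p$mature5_id else p$mature3_id
    scol <- if (which == "5p") p$arm5_start else p$arm3_start
    ecol <- if (which == "5p") p$arm5_end else p$arm3_end
    data.frame(mirna_id = idcol, precursor_id = p$id, arm = which,
               chrom = p$chrom, start = scol, end = ecol, strand = p$strand,
               stringsAsFactors = FALSE)
  }
  m <- rbind(arm("5p"), arm("3p"))
  if (!include_unannotated) m <- m[!is.na(m$mirna_id), , drop = FALSE]
  m <- m[order(m$precursor_id, m$arm), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Write a reference as FASTA and miRBase-style GFF3
#'
#' The GFF3 uses 1-based inclusive coordinates, feature types
#' `miRNA_primary_transcript` and `miRNA`, and attributes `ID`, `Name` and
#' `Derives_from`. The terminal loop length is recorded on each primary
#' transcript so the annotation is self-describing.
#'
#' @param ref a `mirna_reference`.
#' @param dir output directory (created if missing).
#' @return named character vector with paths `fasta` and `gff3`.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), fa)
  p <- ref$precursors
  gr_pre <- GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
    strand = p$strand,
    type = "miRNA_primary_transcript",
    ID = p$id, Name = p$id, Derives_from = NA_character_,
    loop_len = as.integer(ref$loop_len))
  m <- mature_table(ref)
  gr_m <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = m$start + 1L, end = m$end),
    strand = m$strand,
    type = "miRNA",
    ID = m$mirna_id, Name = m$mirna_id, Derives_from = m$precursor_id,
    loop_len = NA_integer_)
  rtracklayer::export(c(gr_pre, gr_m), gff, format = "gff3")
  c(fasta = fa, gff3 = gff)
}

#' Read a reference back from FASTA + GFF3
#'
#' Inverse of [write_reference()]; accepts any miRBase-dialect GFF3 with
#' `miRNA_primary_transcript` and `miRNA` features and `ID`/`Derives_from`
#' attributes. Arms are oriented by strand: the 5' arm is the 5'-most mature
#' interval in transcript orientation.
#'
#' @param fasta genome FASTA path.
#' @param gff3 annotation GFF3 path.
#' @param adapter adapter sequence to carry in the bundle.
#' @return a `mirna_reference`.
#' @export
read_reference <- function(fasta, gff3, adapter = TRUSEQ_ADAPTER) {
  gen <- Biostrings::readDNAStringSet(fasta)
  genome <- setNames(as.character(gen), sub("\\s.*$", "", names(gen)))
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- as.data.frame(gr)
  pre <- df[df$type == "miRNA_primary_transcript", , drop = FALSE]
  mat <- df[df$type == "miRNA", , drop = FALSE]
  loop_len <- if ("loop_len" %in% names(pre) && !all(is.na(pre$loop_len))) {
    as.integer(stats::na.omit(as.integer(pre$loop_len))[1])
  } else 12L
  rows <- lapply(seq_len(nrow(pre)), function(i) {
    pid <- pre$ID[i]
    kids <- mat[mat$Derives_from == pid, , drop = FALSE]
    strand <- as.character(pre$strand[i])
    out <- data.frame(
      id = pid, chrom = as.character(pre$seqnames[i]),
      start = pre$start[i] - 1L, end = pre$end[i], strand = strand,
      arm5_start = NA_integer_, arm5_end = NA_integer_,
      arm3_start = NA_integer_, arm3_end = NA_integer_,
      mature5_id = NA_character_, mature3_id = NA_character_,
      stringsAsFactors = FALSE)
    if (nrow(kids) > 0) {
      ## 5'-most in transcript orientation: smallest start on +, largest end on -
      ord <- if (strand == "+") order(kids$start) else order(-kids$end)
      kids <- kids[ord, , drop = FALSE]
      fill_arm <- function(out, k, which) {
        if (which == "5p") {
          out$arm5_start <- kids$start[k] - 1L; out$arm5_end <- kids$end[k]
          out$mature5_id <- kids$ID[k]
        } else {
          out$arm3_start <- kids$start[k] - 1L; out$arm3_end <- kids$end[k]
          out$mature3_id <- kids$ID[k]
        }
        out
      }
      if (nrow(kids) == 2) {
        out <- fill_arm(out, 1, "5p"); out <- fill_arm(out, 2, "3p")
      } else {
        ## single annotated arm: decide 5p/3p by position within the precursor
        mid_tx <- if (strand == "+") {
          (kids$start[1] + kids$end[1]) / 2 - pre$start[i]
        } else {
          pre$end[i] - (kids$start[1] + kids$end[1]) / 2
        }
        which <- if (mid_tx <= (pre$end[i] - pre$start[i] + 1) / 2) "5p" else "3p"
        out <- fill_arm(out, 1, which)
        ## reconstruct the nameless arm window from hairpin geometry
        named_len <- kids$end[1] - kids$start[1] + 1L
        if (which == "5p") {
          if (strand == "+") {
            out$arm3_start <- out$arm5_end + loop_len; out$arm3_end <- out$end
          } else {
            out$arm3_end <- out$arm5_start - loop_len; out$arm3_start <- out$start
          }
        } else {
          if (strand == "+") {
            out$arm5_start <- out$start; out$arm5_end <- out$arm3_start - loop_len
          } else {
            out$arm5_end <- out$end; out$arm5_start <- out$arm3_end + loop_len
          }
        }
        ## keep the reconstructed window within plausible arm lengths
        recon_len <- if (which == "5p") out$arm3_end - out$arm3_start else out$arm5_end - out$arm5_start
        if (recon_len < 15 || recon_len > 30) {
          if (which == "5p") { out$arm3_start <- NA_integer_; out$arm3_end <- NA_integer_ }
          else { out$arm5_start <- NA_integer_; out$arm5_end <- NA_integer_ }
        }
      }
    }
    out
  })
  ref <- structure(
    list(genome = genome, precursors = do.call(rbind, rows),
         loop_len = loop_len, adapter = adapter),
    class = "mirna_reference")
  ref
}
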