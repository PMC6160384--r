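#' Default isomiR end-offset distribution
#'
#' Distribution over (5' offset, 3' offset) pairs, both in nt and both in
#' \[-2, +2\], used by [simulate_small_rna_library()]. Negative = trimming,
#' positive = templated addition, in transcript orientation. The default
#' puts most mass on the canonical ends and makes 3'-end variation dominate
#' 5'-end variation, the pattern typically seen in small RNA libraries.
#'
#' @return data.frame with columns `offset5`, `offset3`, `prob`.
#' @export
default_offset_probs <- function() {
  d <- data.frame(
    offset5 = c(0,  0,  0,  0,  0, -1,  1, -2,  2, -1, -1,  1,  1),
    offset3 = c(0, -1,  1, -2,  2,  0,  0,  0,  0, -1,  1, -1,  1),
    prob    = c(0.60, 0.12, 0.09, 0.035, 0.025,
                0.045, 0.025, 0.010, 0.005,
                0.015, 0.010, 0.007, 0.003))
  d$prob <- d$prob / sum(d$prob)
  d
}

#' Parameters for the small RNA library simulator
#'
#' @param library_size target number of reads.
#' @param read_length fixed sequenced read length in nt.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for the
#'   per-mature-miRNA baseline abundance weights.
#' @param fold_changes named numeric vector, mature id -> condition-2 over
#'   condition-1 expression ratio (unnamed miRNAs have ratio 1).
#' @param arm5_fraction named list or vector, precursor id -> fraction of
#'   that precursor's reads drawn from the 5' arm; a single number applies
#'   to both conditions, a length-2 vector gives per-condition fractions.
#'   Precursors not named keep their baseline arm weights.
#' @param isomir_offset_probs data.frame as [default_offset_probs()].
#' @param p_3e probability that a read is a 3' non-template single-nucleotide
#'   extension of the canonical mature sequence.
#' @param ext_probs composition of the non-template added nucleotide
#'   (renormalized after excluding the genome-templated next base, so the
#'   addition is guaranteed non-templated).
#' @param base_error_rate per-base uniform miscall probability.
#' @param frac_unannotated fraction of reads drawn as random unannotated
#'   inserts (a stand-in for rRNA/tRNA/piRNA background).
#' @param min_insert,max_insert inclusive bounds on insert length; offset
#'   pairs that would push an insert outside these bounds are resampled.
#' @param seed RNG seed for the simulation.
#' @return a list of class `small_rna_params`.
#' @export
small_rna_params <- function(library_size = 50000L,
                             read_length = 86L,
                             baseline_meanlog = log(500),
                             baseline_sdlog = 1,
                             fold_changes = numeric(0),
                             arm5_fraction = list(),
                             isomir_offset_probs = default_offset_probs(),
                             p_3e = 0.05,
                             ext_probs = c(A = 0.5, T = 0.4, C = 0.05, G = 0.05),
                             base_error_rate = 0,
                             frac_unannotated = 0,
                             min_insert = 17L, max_insert = 26L,
                             seed = 1L) {
  op <- isomir_offset_probs
  stopifnot(all(c("offset5", "offset3", "prob") %in% names(op)))
  if (abs(sum(op$prob) - 1) > 1e-8) stopf("offset distribution must sum to 1")
  if (any(op$prob < 0) || any(abs(op$offset5) > 2) || any(abs(op$offset3) > 2)) {
    stopf("offsets must lie in [-2,2] with non-negative probabilities")
  }
  probs <- c(p_3e, base_error_rate, frac_unannotated)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (read_length < max_insert + 6) stopf("read_length must be >= longest insert + 6")
  structure(list(
    library_size = as.integer(library_size), read_length = as.integer(read_length),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    fold_changes = fold_changes, arm5_fraction = arm5_fraction,
    isomir_offset_probs = op, p_3e = p_3e, ext_probs = ext_probs,
    base_error_rate = base_error_rate, frac_unannotated = frac_unannotated,
    min_insert = as.integer(min_insert), max_insert = as.integer(max_insert),
    seed = as.integer(seed)), class = "small_rna_params")
}

## Insert sequence for one mature arm and an offset pair, in transcript
## orientation. Positive offsets extend into templated flanking sequence.
insert_for_offsets <- function(ref, arm_row, off5, off3) {
  if (arm_row$strand == "+") {
    s <- arm_row$start - off5; e <- arm_row$end + off3
  } else {
    s <- arm_row$start - off3; e <- arm_row$end + off5
  }
  extract_tx(ref$genome, arm_row$chrom, s, e, arm_row$strand)
}

## Genome-templated base immediately 3' of a mature arm (transcript
## orientation); the non-template extension must differ from it.
templated_next_base <- function(ref, arm_row) {
  if (arm_row$strand == "+") {
    extract_tx(ref$genome, arm_row$chrom, arm_row$end, arm_row$end + 1L, "+")
  } else {
    extract_tx(ref$genome, arm_row$chrom, arm_row$start - 1L, arm_row$start, "-")
  }
}

#' Simulate a small RNA sequencing library
#'
#' Draws `library_size` reads from the mature arms of a reference. Each read
#' is an insert (the mature sequence, possibly end-shifted within the
#' templated hairpin/flank, or carrying one non-templated 3' nucleotide),
#' followed by the 3' adapter and uniform-random filler, truncated to the
#' fixed read length. Per-mature baseline abundances are log-normal and
#' shared between conditions; condition 2 applies the planted fold changes;
#' per-precursor 5'-arm fractions override the arm split where given.
#'
#' @param ref a `mirna_reference` from [build_reference()].
#' @param params a `small_rna_params` object.
#' @param condition 1 or 2 (fold changes apply in condition 2).
#' @param fastq optional path; when given, reads are written as Phred+33
#'   FASTQ with constant quality `I`.
#' @param truth optional path for the per-read truth table TSV.
#' @return list with `reads` (character vector named by read id), `truth`
#'   (data.frame: `read_id, mirna_id, precursor_id, class, offset5, offset3,
#'   added_nt, insert`), and the file paths if written. The truth `class`
#'   uses the same labels as the profiler: `CANONICAL`, `ISOMIR_5P`,
#'   `ISOMIR_3P`, `ISOMIR_53P`, `ISOMIR_3E`, plus `UNANNOTATED` for
#'   background reads.
#' @export
simulate_small_rna_library <- function(ref, params, condition = 1L,
                                       fastq = NULL, truth = NULL) {
  stopifnot(inherits(ref, "mirna_reference"), inherits(params, "small_rna_params"))
  condition <- as.integer(condition)
  if (!condition %in% c(1L, 2L)) stopf("condition must be 1 or 2")
  arms <- mature_table(ref, include_unannotated = TRUE)
  arms$mirna_id <- ifelse(is.na(arms$mirna_id),
                          paste0(arms$precursor_id, ":unannotated-", arms$arm),
                          arms$mirna_id)
  bad <- setdiff(names(params$fold_changes), arms$mirna_id)
  if (length(bad)) stopf("fold-change key not a known mature id: %s", bad[1])
  bad <- setdiff(names(params$arm5_fraction), ref$precursors$id)
  if (length(bad)) stopf("arm5_fraction key not a known precursor: %s", bad[1])

  ## baseline weights shared across conditions: drawn under the params seed
  base <- with_seed(params$seed, {
    stats::rlnorm(nrow(arms), params$baseline_meanlog, params$baseline_sdlog)
  })
  names(base) <- arms$mirna_id
  w <- base
  if (condition == 2L && length(params$fold_changes)) {
    w[names(params$fold_changes)] <- w[names(params$fold_changes)] * params$fold_changes
  }
  ## per-precursor arm-fraction overrides (redistribute the precursor total)
  for (pid in names(params$arm5_fraction)) {
    f <- params$arm5_fraction[[pid]]
    f <- if (length(f) >= 2) f[condition] else f[1]
    if (f < 0 || f > 1) stopf("arm5_fraction must lie in [0,1]")
    i5 <- which(arms$precursor_id == pid & arms$arm == "5p")
    i3 <- which(arms$precursor_id == pid & arms$arm == "3p")
    tot <- w[i5] + w[i3]
    w[i5] <- tot * f; w[i3] <- tot * (1 - f)
  }

  with_seed(params$seed * 7L + condition, {
    n <- params$library_size
    n_un <- round(params$frac_unannotated * n)
    n_mi <- n - n_un
    arm_idx <- sample.int(nrow(arms), n_mi, replace = TRUE, prob = w)

    ## variant draw: 3' non-template extension, else an offset pair
    is3e <- stats::runif(n_mi) < params$p_3e
    op <- params$isomir_offset_probs
    off5 <- integer(n_mi); off3 <- integer(n_mi)
    todo <- which(!is3e)
    arm_len <- arms$end - arms$start
    while (length(todo)) {
      k <- sample.int(nrow(op), length(todo), replace = TRUE, prob = op$prob)
      off5[todo] <- op$offset5[k]; off3[todo] <- op$offset3[k]
      ilen <- arm_len[arm_idx[todo]] + off5[todo] + off3[todo]
      todo <- todo[ilen < params$min_insert | ilen > params$max_insert]
    }

    ## precompute insert sequences per (arm, off5, off3) combination
    key <- paste(arm_idx, off5, off3)
    inserts <- character(n_mi)
    added <- rep(NA_character_, n_mi)
    non3 <- which(!is3e)
    if (length(non3)) {
      reps <- non3[!duplicated(key[non3])]
      vals <- vapply(reps, function(j) {
        insert_for_offsets(ref, arms[arm_idx[j], ], off5[j], off3[j])
      }, character(1))
      names(vals) <- key[reps]
      inserts[non3] <- vals[key[non3]]
    }
    if (any(is3e)) {
      mats <- mature_sequences(ref)
      for (a in unique(arm_idx[is3e])) {
        sel <- which(is3e & arm_idx == a)
        tmpl <- templated_next_base(ref, arms[a, ])
        probs <- params$ext_probs[setdiff(names(params$ext_probs), tmpl)]
        nt <- sample(names(probs), length(sel), replace = TRUE, prob = probs)
        added[sel] <- nt
        inserts[sel] <- paste0(mats[[arms$mirna_id[a]]], nt)
      }
    }

    cls <- ifelse(is3e, "ISOMIR_3E",
           ifelse(off5 == 0 & off3 == 0, "CANONICAL",
           ifelse(off5 != 0 & off3 == 0, "ISOMIR_5P",
           ifelse(off5 == 0 & off3 != 0, "ISOMIR_3P", "ISOMIR_53P"))))

    mirna_id <- arms$mirna_id[arm_idx]
    precursor_id <- arms$precursor_id[arm_idx]
    if (n_un > 0) {
      un <- random_dna(sample(params$min_insert:params$max_insert, n_un, replace = TRUE))
      inserts <- c(inserts, un)
      mirna_id <- c(mirna_id, rep(NA_character_, n_un))
      precursor_id <- c(precursor_id, rep(NA_character_, n_un))
      cls <- c(cls, rep("UNANNOTATED", n_un))
      off5 <- c(off5, rep(NA_integer_, n_un)); off3 <- c(off3, rep(NA_integer_, n_un))
      added <- c(added, rep(NA_character_, n_un))
      is3e <- c(is3e, rep(FALSE, n_un))
    }
    off5[cls %in% c("ISOMIR_3E")] <- 0L
    off3[cls %in% c("ISOMIR_3E")] <- 0L

    ## sequencing errors on the insert portion
    if (params$base_error_rate > 0) {
      ilen <- nchar(inserts)
      nerr <- stats::rbinom(length(inserts), ilen, params$base_error_rate)
      for (i in which(nerr > 0)) {
        ch <- strsplit(inserts[i], "")[[1]]
        pos <- sample(length(ch), min(nerr[i], length(ch)))
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
        inserts[i] <- paste(ch, collapse = "")
      }
    }

    ## read = insert + adapter + random filler, truncated to read_length
    need <- pmax(0L, params$read_length - nchar(inserts) - nchar(ref$adapter))
    filler <- random_dna(need)
    reads <- substr(paste0(inserts, ref$adapter, filler), 1L, params$read_length)
    ids <- sprintf("read%06d", seq_along(reads))
    names(reads) <- ids

    truth_df <- data.frame(
      read_id = ids, mirna_id = mirna_id, precursor_id = precursor_id,
      class = cls, offset5 = off5, offset3 = off3, added_nt = added,
      insert = inserts, stringsAsFactors = FALSE)

    out <- list(reads = reads, truth = truth_df)
    if (!is.null(fastq)) { write_fastq(reads, fastq); out$fastq <- fastq }
    if (!is.null(truth)) { write_tsv(truth_df, truth); out$truth_path <- truth }
    out
  })
}

#' Read and write FASTQ
#'
#' FASTQ I/O via Biostrings; written qualities are constant `I` (Phred+33).
#'
#' @param reads named character vector of read sequences.
#' @param path FASTQ path.
#' @return `read_fastq()` returns a named character vector.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
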