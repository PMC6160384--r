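ISOMIR_CLASSES <- c("CANONICAL", "ISOMIR_5P", "ISOMIR_3P", "ISOMIR_53P", "ISOMIR_3E")

#' Assign placed reads to mature miRNA arms
#'
#' A placement is assigned to a mature arm when the read length lies in
#' `[min_len, max_len]`, the strand matches the annotation, and at least
#' `min_overlap` of its bases fall inside the arm interval extended by
#' `flank` nt at each end. A read overlapping both arms of one precursor is
#' assigned to the arm with the larger overlap (exact tie: the 5' arm). A
#' read whose sequence occurs at the arms of two different precursors
#' contributes its full count to each. Each (read, arm) pair is assigned at
#' most once.
#'
#' @param placements data.frame from [place_exact()].
#' @param ref a `mirna_reference`, or an arm table as returned by the
#'   internal annotation accessor (columns `mirna_id, precursor_id, arm,
#'   chrom, start, end, strand`).
#' @param min_len,max_len inclusive read length bounds in nt.
#' @param min_overlap minimum bases of the read inside the extended arm.
#' @param flank extension of the arm interval at each end, in nt.
#' @param include_unannotated also assign reads to arms that carry no named
#'   mature product (ids of the form `<precursor>:unannotated-<arm>`);
#'   needed for annotation-gap detection.
#' @return data.frame of assignments: `sequence, count, chrom, start, end,
#'   strand, mirna_id, precursor_id, arm, arm_start, arm_end, overlap,
#'   annotated`.
#' @export
assign_reads <- function(placements, ref, min_len = 17L, max_len = 26L,
                         min_overlap = 17L, flank = 2L,
                         include_unannotated = TRUE) {
  arms <- if (inherits(ref, "mirna_reference")) {
    a <- mature_table(ref, include_unannotated = TRUE)
    a$annotated <- !is.na(a$mirna_id)
    a$mirna_id <- ifelse(is.na(a$mirna_id),
                         paste0(a$precursor_id, ":unannotated-", a$arm), a$mirna_id)
    a
  } else ref
  if (!include_unannotated) arms <- arms[arms$annotated, , drop = FALSE]
  arms <- arms[!is.na(arms$start), , drop = FALSE]
  empty <- data.frame(sequence = character(0), count = integer(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mirna_id = character(0),
                      precursor_id = character(0), arm = character(0),
                      arm_start = integer(0), arm_end = integer(0),
                      overlap = integer(0), annotated = logical(0))
  if (nrow(placements) == 0L || nrow(arms) == 0L) return(empty)
  rlen <- placements$end - placements$start
  len_ok <- rlen >= min_len & rlen <= max_len
  out <- vector("list", nrow(arms))
  for (k in seq_len(nrow(arms))) {
    ws <- arms$start[k] - flank; we <- arms$end[k] + flank
    ov <- pmin(placements$end, we) - pmax(placements$start, ws)
    hit <- which(len_ok & placements$chrom == arms$chrom[k] &
                   placements$strand == arms$strand[k] & ov >= min_overlap)
    if (length(hit)) {
      out[[k]] <- data.frame(
        placements[hit, c("sequence", "count", "chrom", "start", "end", "strand")],
        mirna_id = arms$mirna_id[k], precursor_id = arms$precursor_id[k],
        arm = arms$arm[k], arm_start = arms$start[k], arm_end = arms$end[k],
        overlap = ov[hit], annotated = arms$annotated[k],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  ## within one precursor, keep the arm with the larger overlap (tie -> 5p)
  key <- paste(res$sequence, res$chrom, res$start, res$strand, res$precursor_id)
  res <- res[order(key, -res$overlap, match(res$arm, c("5p", "3p"))), , drop = FALSE]
  res <- res[!duplicated(paste(res$sequence, res$chrom, res$start, res$strand,
                               res$precursor_id)), , drop = FALSE]
  ## each (read, arm) at most once
  res <- res[!duplicated(paste(res$sequence, res$mirna_id)), , drop = FALSE]
  res <- res[order(res$mirna_id, res$sequence), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify assigned reads into canonical and isomiR variants
#'
#' End offsets are computed in transcript orientation against the annotated
#' mature ends: negative = trimming, positive = templated addition. Classes
#' follow the offset pattern: both zero is `CANONICAL`, a 5'-only shift is
#' `ISOMIR_5P`, a 3'-only shift `ISOMIR_3P`, shifts at both ends
#' `ISOMIR_53P`. Reads one nucleotide longer than the mature sequence whose
#' extra 3' base differs from the genome-templated next base are
#' `ISOMIR_3E`; those reads do not map to the genome exactly and are
#' supplied separately (see [find_3e_reads()]). Offsets beyond `max_offset`
#' are dropped into the spill log.
#'
#' @param assignments data.frame from [assign_reads()].
#' @param max_offset largest |offset| classified, in nt.
#' @return list with `records` (data.frame: `mirna_id, precursor_id, arm,
#'   annotated, class, offset5, offset3, added_nt, sequence, count`) and
#'   `spill` (assignments dropped for out-of-window offsets).
#' @export
classify_isomir <- function(assignments, max_offset = 2L) {
  a <- assignments
  if (nrow(a) == 0L) {
    return(list(records = empty_isomir_records(), spill = a))
  }
  plus <- a$strand == "+"
  off5 <- ifelse(plus, a$arm_start - a$start, a$end - a$arm_end)
  off3 <- ifelse(plus, a$end - a$arm_end, a$arm_start - a$start)
  ok <- abs(off5) <= max_offset & abs(off3) <= max_offset
  cls <- ifelse(off5 == 0 & off3 == 0, "CANONICAL",
         ifelse(off5 != 0 & off3 == 0, "ISOMIR_5P",
         ifelse(off5 == 0 & off3 != 0, "ISOMIR_3P", "ISOMIR_53P")))
  rec <- data.frame(
    mirna_id = a$mirna_id, precursor_id = a$precursor_id, arm = a$arm,
    annotated = a$annotated, class = cls, offset5 = as.integer(off5),
    offset3 = as.integer(off3), added_nt = NA_character_,
    sequence = a$sequence, count = a$count, stringsAsFactors = FALSE)
  list(records = rec[ok, , drop = FALSE], spill = a[!ok, , drop = FALSE])
}

empty_isomir_records <- function() {
  data.frame(mirna_id = character(0), precursor_id = character(0),
             arm = character(0), annotated = logical(0), class = character(0),
             offset5 = integer(0), offset3 = integer(0),
             added_nt = character(0), sequence = character(0),
             count = integer(0))
}

#' Detect 3' non-template single-nucleotide extensions
#'
#' Scans unique reads that had no exact genome placement for reads equal to
#' an annotated mature sequence plus exactly one trailing nucleotide. By
#' construction such a read's extra base differs from the genome-templated
#' next base (a templated extension would have mapped exactly and been
#' classified `ISOMIR_3P`).
#'
#' @param unplaced data.frame of unique reads (`sequence`, `count`) with no
#'   exact placement.
#' @param ref a `mirna_reference`.
#' @return data.frame of `ISOMIR_3E` records in the same layout as
#'   [classify_isomir()] records.
#' @export
find_3e_reads <- function(unplaced, ref) {
  if (nrow(unplaced) == 0L) return(empty_isomir_records())
  arms <- mature_table(ref, include_unannotated = TRUE)
  arms$annotated <- !is.na(arms$mirna_id)
  arms$mirna_id <- ifelse(is.na(arms$mirna_id),
                          paste0(arms$precursor_id, ":unannotated-", arms$arm),
                          arms$mirna_id)
  mats <- mature_sequences(ref)
  prefix <- substr(unplaced$sequence, 1L, nchar(unplaced$sequence) - 1L)
  last <- substr(unplaced$sequence, nchar(unplaced$sequence), nchar(unplaced$sequence))
  m <- match(prefix, mats[arms$mirna_id])
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(empty_isomir_records())
  k <- m[hit]
  data.frame(
    mirna_id = arms$mirna_id[k], precursor_id = arms$precursor_id[k],
    arm = arms$arm[k], annotated = arms$annotated[k], class = "ISOMIR_3E",
    offset5 = 0L, offset3 = 0L, added_nt = last[hit],
    sequence = unplaced$sequence[hit], count = unplaced$count[hit],
    stringsAsFactors = FALSE)
}

#' Aggregate isomiR records into expression profiles
#'
#' Produces per-miRNA totals with per-class counts and the count of the
#' single most abundant sequence variant (used downstream as the miRNA's
#' expression estimate in differential testing), and per-precursor arm
#' totals. Every annotated miRNA and precursor of the reference appears in
#' the output, with zeros where no reads were observed.
#'
#' @param records isomiR record data.frame ([classify_isomir()] records,
#'   optionally rbind-ed with [find_3e_reads()] output).
#' @param ref a `mirna_reference`.
#' @return list with `profiles` (per annotated miRNA: `mirna_id,
#'   total_count, canonical, isomir_5p, isomir_3p, isomir_53p, isomir_3e,
#'   top_variant_count`) and `arm_counts` (per precursor: `precursor_id,
#'   count5p, count3p`, summed over all variants of each annotated or
#'   unannotated arm).
#' @export
profile_expression <- function(records, ref) {
  arms <- mature_table(ref, include_unannotated = TRUE)
  arms$annotated <- !is.na(arms$mirna_id)
  arms$mirna_id <- ifelse(is.na(arms$mirna_id),
                          paste0(arms$precursor_id, ":unannotated-", arms$arm),
                          arms$mirna_id)
  agg <- function(ids, what) {
    if (nrow(records) == 0L) return(setNames(numeric(length(ids)), ids))
    sel <- records$mirna_id %in% ids & what(records)
    s <- tapply(records$count[sel], factor(records$mirna_id[sel], levels = ids), sum)
    s[is.na(s)] <- 0
    s
  }
  ids <- arms$mirna_id
  per_class <- sapply(ISOMIR_CLASSES, function(cl) {
    agg(ids, function(r) r$class == cl)
  })
  if (is.null(dim(per_class))) per_class <- matrix(per_class, nrow = length(ids),
                                                   dimnames = list(ids, ISOMIR_CLASSES))
  top <- setNames(numeric(length(ids)), ids)
  if (nrow(records) > 0L) {
    mx <- tapply(records$count, factor(records$mirna_id, levels = ids), max)
    top[!is.na(mx)] <- mx[!is.na(mx)]
  }
  profiles <- data.frame(
    mirna_id = ids, precursor_id = arms$precursor_id, arm = arms$arm,
    annotated = arms$annotated,
    total_count = as.integer(rowSums(per_class)),
    canonical = as.integer(per_class[, "CANONICAL"]),
    isomir_5p = as.integer(per_class[, "ISOMIR_5P"]),
    isomir_3p = as.integer(per_class[, "ISOMIR_3P"]),
    isomir_53p = as.integer(per_class[, "ISOMIR_53P"]),
    isomir_3e = as.integer(per_class[, "ISOMIR_3E"]),
    top_variant_count = as.integer(top),
    stringsAsFactors = FALSE)
  profiles <- profiles[order(profiles$mirna_id), , drop = FALSE]
  rownames(profiles) <- NULL
  pre_ids <- sort(unique(arms$precursor_id))
  tot <- function(arm) {
    vapply(pre_ids, function(p) {
      sum(profiles$total_count[profiles$precursor_id == p & profiles$arm == arm])
    }, numeric(1))
  }
  arm_counts <- data.frame(precursor_id = pre_ids,
                           count5p = as.integer(tot("5p")),
                           count3p = as.integer(tot("3p")),
                           stringsAsFactors = FALSE)
  rownames(arm_counts) <- NULL
  list(profiles = profiles, arm_counts = arm_counts)
}

#' Report precursors with reads on an un-annotated arm
#'
#' For precursors where only one arm carries a named mature product,
#' reports those whose nameless arm accumulated at least `floor` reads -
#' evidence of a gap in the annotation.
#'
#' @param profiles the `profiles` table from [profile_expression()].
#' @param ref a `mirna_reference`.
#' @param floor minimum read count on the nameless arm.
#' @return data.frame `precursor_id, arm, count` of reported gap arms.
#' @export
annotate_gap_arms <- function(profiles, ref, floor = 5L) {
  p <- ref$precursors
  single <- p$id[xor(is.na(p$mature5_id), is.na(p$mature3_id))]
  un <- profiles[!profiles$annotated & profiles$precursor_id %in% single &
                   profiles$total_count >= floor, , drop = FALSE]
  out <- data.frame(precursor_id = un$precursor_id, arm = un$arm,
                    count = un$total_count, stringsAsFactors = FALSE)
  out[order(out$precursor_id), , drop = FALSE]
}

#' Profile one small RNA sample end to end
#'
#' Convenience wrapper: preprocessing ([preprocess_reads()]), assignment,
#' classification, non-template 3' extension detection, and aggregation.
#'
#' @param reads raw reads (character vector or FASTQ path).
#' @param ref a `mirna_reference`.
#' @param min_count multiplicity floor for unique reads.
#' @param ... passed to [assign_reads()].
#' @return list with `profiles`, `arm_counts`, `records`, `spill`, `stats`.
#' @export
profile_sample <- function(reads, ref, min_count = 3L, ...) {
  pp <- preprocess_reads(reads, ref$genome, adapter = ref$adapter,
                         min_count = min_count)
  asg <- assign_reads(pp$placements, ref, ...)
  cl <- classify_isomir(asg)
  rec3e <- find_3e_reads(pp$unplaced, ref)
  records <- rbind(cl$records, rec3e)
  prof <- profile_expression(records, ref)
  list(profiles = prof$profiles, arm_counts = prof$arm_counts,
       records = records, spill = cl$spill, stats = pp$stats)
}
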