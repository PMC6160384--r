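# a hand-built single-precursor reference where everything is known:
# chrom = 30 nt pad + [arm5 (22) + loop (12) + arm3 (22)] + 30 nt pad
toy_ref <- local({
  set.seed(123)
  build_reference(1, seed = 42, arm_len_range = c(22L, 22L))
})
toy_arm5 <- toy_ref$precursors$arm5_start[1]

placement_row <- function(start, end, strand = "+", count = 1L, seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", end - start)
  data.frame(sequence = seq, count = count, chrom = "chr1",
             start = start, end = end, strand = strand, mismatches = 0L,
             stringsAsFactors = FALSE)
}

test_that("read assignment enforces length, strand and overlap rules", {
  p <- toy_ref$precursors
  s <- p$arm5_start[1]; e <- p$arm5_end[1]; str <- p$strand[1]
  # 16-nt read perfectly inside the arm: too short
  a <- assign_reads(placement_row(s + 2, s + 18, str), toy_ref)
  expect_equal(nrow(a), 0)
  # 22-nt read exactly matching the arm: assigned with overlap 22
  a <- assign_reads(placement_row(s, e, str), toy_ref)
  expect_equal(nrow(a), 1)
  expect_equal(a$overlap, 22)
  expect_equal(a$arm, "5p")
  # 20-nt read with only 16 bases inside the extended window: unassigned
  a <- assign_reads(placement_row(e + 2 - 16, e + 2 - 16 + 20, str), toy_ref)
  expect_equal(nrow(a), 0)
  # wrong strand: unassigned
  a <- assign_reads(placement_row(s, e, if (str == "+") "-" else "+"), toy_ref)
  expect_equal(nrow(a), 0)
})

test_that("offset classification matches the class definitions", {
  p <- toy_ref$precursors
  str <- p$strand[1]
  s <- p$arm5_start[1]; e <- p$arm5_end[1]
  shift <- function(d5, d3) {
    # genomic interval realizing transcript-orientation offsets (d5, d3)
    if (str == "+") placement_row(s - d5, e + d3, str)
    else placement_row(s - d3, e + d5, str)
  }
  cl <- function(pl) classify_isomir(assign_reads(pl, toy_ref))$records
  r <- cl(shift(0, 0))
  expect_equal(r$class, "CANONICAL")
  expect_equal(c(r$offset5, r$offset3), c(0L, 0L))
  # mature minus last 2 nt: 3' trimming
  r <- cl(shift(0, -2))
  expect_equal(r$class, "ISOMIR_3P")
  expect_equal(r$offset3, -2L)
  # templated one-base 3' extension stays ISOMIR_3P
  r <- cl(shift(0, 1))
  expect_equal(r$class, "ISOMIR_3P")
  expect_equal(r$offset3, 1L)
  r <- cl(shift(1, 0))
  expect_equal(r$class, "ISOMIR_5P")
  r <- cl(shift(-1, 2))
  expect_equal(r$class, "ISOMIR_53P")
  # offsets beyond +-2 go to the spill log
  out <- classify_isomir(assign_reads(shift(0, -3), toy_ref,
                                      min_overlap = 17L))
  expect_equal(nrow(out$records), 0)
})

test_that("non-template 3' extensions are detected against mature sequences", {
  mats <- mature_sequences(toy_ref)
  m5 <- mats[toy_ref$precursors$mature5_id[1]]
  mt <- mirnadelta:::mature_table(toy_ref)
  tmpl <- mirnadelta:::templated_next_base(
    toy_ref, mt[mt$mirna_id == toy_ref$precursors$mature5_id[1], ])
  non <- setdiff(c("A", "C", "G", "T"), tmpl)[1]
  rec <- find_3e_reads(data.frame(sequence = paste0(m5, non), count = 7L,
                                  stringsAsFactors = FALSE), toy_ref)
  expect_equal(rec$class, "ISOMIR_3E")
  expect_equal(rec$added_nt, non)
  expect_equal(rec$count, 7L)
  # a read that is not mature + 1 nt is ignored
  none <- find_3e_reads(data.frame(sequence = paste0(m5, non, non), count = 1L),
                        toy_ref)
  expect_equal(nrow(none), 0)
})

test_that("profiles aggregate counts, expose the top variant, and keep zero rows", {
  recs <- data.frame(
    mirna_id = "miR-1-5p", precursor_id = "pre-mir-1", arm = "5p",
    annotated = TRUE, class = c("CANONICAL", "ISOMIR_3P", "ISOMIR_5P"),
    offset5 = c(0L, 0L, -1L), offset3 = c(0L, -1L, 0L),
    added_nt = NA_character_, sequence = c("AAA", "BBB", "CCC"),
    count = c(12L, 5L, 3L), stringsAsFactors = FALSE)
  prof <- profile_expression(recs, ref5)
  row <- prof$profiles[prof$profiles$mirna_id == "miR-1-5p", ]
  expect_equal(row$total_count, 20L)
  expect_equal(row$top_variant_count, 12L)
  expect_equal(row$isomir_3p, 5L)
  # every annotated miRNA appears, zeros where unobserved
  expect_true(all(ref5$precursors$mature3_id %in% prof$profiles$mirna_id))
  zero <- prof$profiles[prof$profiles$mirna_id == "miR-2-3p", ]
  expect_equal(zero$total_count, 0L)
  # arm counts aggregate per precursor
  ac <- prof$arm_counts[prof$arm_counts$precursor_id == "pre-mir-1", ]
  expect_equal(ac$count5p, 20L)
  expect_equal(ac$count3p, 0L)
})

test_that("classification is exact on an error-free library and conserves counts", {
  prm <- small_rna_params(library_size = 10000, p_3e = 0.06,
                          base_error_rate = 0, seed = 11)
  sim <- simulate_small_rna_library(ref20, prm, condition = 1)
  ps <- profile_sample(sim$reads, ref20, min_count = 1)
  m <- match(sim$truth$insert, ps$records$sequence)
  expect_false(anyNA(m))
  expect_true(all(ps$records$class[m] == sim$truth$class))
  expect_true(all(ps$records$offset5[m] == sim$truth$offset5))
  expect_true(all(ps$records$offset3[m] == sim$truth$offset3))
  e3 <- sim$truth$class == "ISOMIR_3E"
  expect_true(all(ps$records$added_nt[m[e3]] == sim$truth$added_nt[e3]))
  # conservation: per-class totals equal the number of simulated reads
  expect_equal(sum(ps$profiles$total_count), nrow(sim$truth))
  expect_equal(nrow(ps$spill), 0)
})

test_that("extension calls never fire when the simulator plants none", {
  prm <- small_rna_params(library_size = 4000, p_3e = 0, base_error_rate = 0,
                          seed = 12)
  sim <- simulate_small_rna_library(ref5, prm, condition = 1)
  ps <- profile_sample(sim$reads, ref5, min_count = 1)
  expect_equal(sum(ps$profiles$isomir_3e), 0L)
})

test_that("gap arms are reported above the floor only for single-annotated precursors", {
  ref <- build_reference(6, seed = 13, frac_single_annotated = 0.5)
  prm <- small_rna_params(library_size = 6000, p_3e = 0, base_error_rate = 0,
                          seed = 13)
  sim <- simulate_small_rna_library(ref, prm, condition = 1)
  ps <- profile_sample(sim$reads, ref, min_count = 1)
  gaps <- annotate_gap_arms(ps$profiles, ref, floor = 5)
  p <- ref$precursors
  single <- p$id[xor(is.na(p$mature5_id), is.na(p$mature3_id))]
  expect_true(all(gaps$precursor_id %in% single))
  expect_true(all(gaps$count >= 5))
  # abundant nameless arms are found (baseline abundance makes most exceed 5)
  expect_gt(nrow(gaps), 0)
  # fully annotated precursors are never reported
  expect_false(any(setdiff(p$id, single) %in% gaps$precursor_id))
  # a high floor silences reporting
  expect_equal(nrow(annotate_gap_arms(ps$profiles, ref, floor = 1e9)), 0)
})
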