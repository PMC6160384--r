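adapter <- TRUSEQ_ADAPTER

test_that("adapter trimming follows the three stated rules", {
  insert17 <- "ACGTACGTACGTACGTA"
  # full exact adapter: everything from the adapter on is removed
  expect_identical(trim_adapter(paste0(insert17, adapter, "GGGG"), adapter), insert17)
  # no adapter anywhere: the last 6 bases are removed
  read30 <- strrep("AC", 15)
  expect_identical(trim_adapter(read30, adapter), substr(read30, 1, 24))
  # remainder shorter than 10 nt is discarded
  expect_true(is.na(trim_adapter(paste0("ACGTACGT", adapter), adapter)))
  # empty read is discarded
  expect_true(is.na(trim_adapter("", adapter)))
})

test_that("truncated and mismatched adapter occurrences are honored", {
  insert <- "TTGACCGGAACCTTGGAACCT"
  # 3'-truncated adapter at the read end, overlap >= 6
  expect_identical(trim_adapter(paste0(insert, substr(adapter, 1, 8)), adapter), insert)
  # overlap of 5 is below the floor: falls back to removing 6 bases
  r5 <- paste0(insert, substr(adapter, 1, 5))
  expect_identical(trim_adapter(r5, adapter), substr(r5, 1, nchar(r5) - 6))
  # up to two mismatches allowed in a full occurrence
  a2 <- adapter
  substr(a2, 3, 3) <- "A"; substr(a2, 10, 10) <- "A"
  stopifnot(sum(strsplit(a2, "")[[1]] != strsplit(adapter, "")[[1]]) == 2)
  expect_identical(trim_adapter(paste0(insert, a2, "AAA"), adapter), insert)
  # three mismatches: occurrence rejected, fallback trims 6
  a3 <- a2
  substr(a3, 15, 15) <- "A"
  stopifnot(sum(strsplit(a3, "")[[1]] != strsplit(adapter, "")[[1]]) == 3)
  r3 <- paste0(insert, a3)
  expect_identical(trim_adapter(r3, adapter), substr(r3, 1, nchar(r3) - 6))
  # leftmost admissible occurrence wins
  two <- paste0(insert, adapter, "ACGTACGTAC", adapter)
  expect_identical(trim_adapter(two, adapter), insert)
})

test_that("trimming already-trimmed reads only costs the sacrificial tail", {
  set.seed(1)
  inserts <- random_dna(rep(22, 20))
  once <- trim_adapter(paste0(inserts, adapter), adapter)
  expect_identical(once, inserts)
  # a second pass on insert + 6 sacrificial bases returns the insert
  twice <- trim_adapter(paste0(inserts, "AAAAAA"), adapter)
  expect_identical(twice, inserts)
})

test_that("read collapsing counts, filters and orders deterministically", {
  expect_equal(collapse_reads(c("AAA", "AAA", "AAA", "CCC")),
               data.frame(sequence = "AAA", count = 3L))
  expect_equal(nrow(collapse_reads(character(0))), 0)
  tie <- collapse_reads(rep(c("TTT", "GGG"), each = 5), min_count = 1)
  expect_equal(tie$sequence, c("GGG", "TTT"))
  # conservation: total collapsed == total input at min_count = 1
  set.seed(2)
  reads <- sample(c("ACGTACGTAC", "TTTTTTTTTT", "GGGGGGGGGG"), 100, replace = TRUE)
  expect_equal(sum(collapse_reads(reads, min_count = 1)$count), 100)
  expect_lte(sum(collapse_reads(reads, min_count = 30)$count), 100)
})

test_that("exact placement reports both strands and omits non-matching reads", {
  # A/C-only chromosome: minus-strand text is G/T-only, so the two strands
  # can never collide by accident
  genome <- c(chrA = "AACCACAACCCACACAACACCACA")
  r_plus <- substr(genome[[1]], 5, 12)
  r_minus <- revcomp(substr(genome[[1]], 9, 16))
  u <- data.frame(sequence = c(r_plus, r_minus,
                               "GGGGGGGG",    # absent
                               "AANCACAA"),   # N never matches
                  count = c(5L, 2L, 1L, 9L), stringsAsFactors = FALSE)
  plc <- place_exact(u, genome)
  # oracle: every occurrence found by fixed-string search on either strand
  occ <- function(s) as.integer(gregexpr(s, genome[[1]], fixed = TRUE)[[1]])
  fw_exp <- occ(r_plus) - 1L
  rv_exp <- occ(revcomp(r_minus)) - 1L
  fw <- plc[plc$strand == "+", ]
  expect_equal(sort(fw$start), sort(fw_exp))
  expect_true(all(fw$sequence == r_plus))
  rv <- plc[plc$strand == "-", ]
  expect_equal(sort(rv$start), sort(rv_exp))
  expect_true(all(rv$sequence == r_minus))
  expect_false(any(c("GGGGGGGG", "AANCACAA") %in% plc$sequence))
  expect_true(all(plc$mismatches == 0))
  expect_equal(plc$end - plc$start, nchar(plc$sequence))
})

test_that("error-free libraries survive preprocessing with full recall", {
  prm <- small_rna_params(library_size = 8000, p_3e = 0, base_error_rate = 0,
                          seed = 10)
  sim <- simulate_small_rna_library(ref5, prm, condition = 1)
  pp <- preprocess_reads(sim$reads, ref5$genome, adapter = ref5$adapter,
                         min_count = 1)
  # every surviving unique read is a planted insert
  expect_true(all(pp$unique_reads$sequence %in% sim$truth$insert))
  # and every planted insert is recovered and placed (recall 100%)
  expect_true(all(sim$truth$insert %in% pp$unique_reads$sequence))
  expect_true(all(sim$truth$insert %in% pp$placements$sequence))
  expect_equal(sum(pp$unique_reads$count), length(sim$reads))
})
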