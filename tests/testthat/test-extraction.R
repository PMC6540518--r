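# Telomeric-read extraction: threshold formula, repeat counting in both
# modes, and the telomeric decision.

test_that("repeat threshold follows floor(read_length * 0.06), clamped to 1", {
  expect_identical(compute_repeat_threshold(100), 6L)
  expect_identical(compute_repeat_threshold(151), 9L)
  expect_identical(compute_repeat_threshold(10), 1L) # floor(0.6) clamped
  expect_identical(compute_repeat_threshold(c(36, 75, 125, 250)),
                   c(2L, 4L, 7L, 15L))
  expect_error(compute_repeat_threshold(0), "read_length")
  expect_error(compute_repeat_threshold(numeric(0)), "read_length")
})

test_that("pattern sets validate and derive reverse complements", {
  ps <- repeat_pattern_set()
  expect_setequal(ps$search_set,
                  c("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG",
                    "CCCTAA", "CCCTGA", "CCCTCA", "CCCCAA"))
  expect_identical(repeat_pattern_set("TTAGGG",
                                      include_reverse_complement = FALSE)$search_set,
                   "TTAGGG")
  expect_error(repeat_pattern_set("TTAXGG"), "A,C,G,T")
  expect_error(repeat_pattern_set(character(0)), "A,C,G,T")
  expect_error(extraction_config(threshold_override = 0), ">= 1")
})

test_that("non-consecutive counting sums non-overlapping hits of any pattern", {
  ps <- repeat_pattern_set()
  expect_identical(count_repeat_hits(strrep("TTAGGG", 6), ps), 6L)
  # three isolated hits with non-telomeric spacers
  expect_identical(
    count_repeat_hits("TTAGGGACGTTTAGGGACGTTCAGGG", ps), 3L)
  # reverse complement of the t-type repeat
  expect_identical(count_repeat_hits(strrep("CCCTAA", 6), ps), 6L)
  # mixed pattern types all count toward one total
  expect_identical(
    count_repeat_hits(paste0("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG"), ps), 4L)
  # non-ACGT characters never match
  expect_identical(count_repeat_hits("TTANGGTTANGG", ps), 0L)
  expect_identical(count_repeat_hits("ACGTACGTACGT", ps), 0L)
})

test_that("consecutive mode measures the longest adjacent run", {
  ps <- repeat_pattern_set(consecutive = TRUE)
  expect_identical(
    count_repeat_hits(paste0(strrep("TTAGGG", 2), "ACGT", "TTAGGG"), ps), 2L)
  # runs may mix patterns of the search set
  expect_identical(
    count_repeat_hits(paste0("TTAGGGTCAGGGTGAGGG", "AAAA", "TTAGGG"), ps), 3L)
  expect_identical(count_repeat_hits("ACGTACGT", ps), 0L)
})

test_that("is_telomeric applies the per-read-length threshold", {
  cfg <- extraction_config()
  pure <- strrep("TTAGGG", 16) # 96 bp
  expect_true(is_telomeric(pure, cfg))
  spacer <- "CACACACACA"
  five <- paste0(strrep(paste0("TTAGGG", spacer), 5), strrep("CA", 10)) # 100 bp
  expect_identical(nchar(five), 100L)
  expect_false(is_telomeric(five, cfg))
  six_c <- paste0(strrep(paste0("TCAGGG", spacer), 6), "CACA") # 100 bp
  expect_identical(nchar(six_c), 100L)
  expect_true(is_telomeric(six_c, cfg))
  # override replaces the formula
  expect_true(is_telomeric(five, extraction_config(threshold_override = 5)))
})

test_that("restrict_to_ttype keeps only TTAGGG and its reverse complement", {
  cfg <- restrict_to_ttype(extraction_config())
  expect_setequal(cfg$pattern_set$search_set, c("TTAGGG", "CCCTAA"))
  expect_false(is_telomeric(strrep("TGAGGG", 16), cfg))
  expect_true(is_telomeric(strrep("TTAGGG", 16), cfg))
  expect_true(is_telomeric(strrep("CCCTAA", 16), cfg))
})

test_that("counting agrees with the regex oracle on random sequences", {
  set.seed(101)
  ps <- repeat_pattern_set()
  seqs <- random_scanner_sequences(400)
  got <- count_repeat_hits(seqs, ps)
  want <- vapply(seqs, oracle_count_hits, integer(1),
                 patterns = ps$search_set, USE.NAMES = FALSE)
  expect_identical(got, as.integer(want))
  psc <- repeat_pattern_set(consecutive = TRUE)
  gotc <- count_repeat_hits(seqs, psc)
  wantc <- vapply(seqs, oracle_count_hits, integer(1),
                  patterns = psc$search_set, consecutive = TRUE,
                  USE.NAMES = FALSE)
  expect_identical(gotc, as.integer(wantc))
})

test_that("counting is monotone under appending a pattern instance", {
  set.seed(102)
  ps <- repeat_pattern_set()
  for (i in 1:50) {
    s <- random_scanner_sequences(1)
    p <- sample(ps$search_set, 1)
    expect_gte(count_repeat_hits(paste0(s, p), ps), count_repeat_hits(s, ps))
  }
})

test_that("counts are invariant under reverse complement", {
  set.seed(103)
  ps <- repeat_pattern_set()
  seqs <- random_scanner_sequences(200)
  expect_identical(count_repeat_hits(seqs, ps),
                   count_repeat_hits(rc(seqs), ps))
})

test_that("is_telomeric flips exactly at the threshold repeat count", {
  cfg <- extraction_config()
  # k tiled repeats padded with CA dinucleotides to 100 bp
  for (k in 4:8) {
    s <- paste0(strrep("TTAGGG", k), strrep("CA", (100 - 6 * k) / 2))
    expect_identical(is_telomeric(s, cfg), k >= 6L, label = paste("k =", k))
  }
})
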