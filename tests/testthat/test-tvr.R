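# Variant-repeat quantification: hexamer scan, singletons, contexts,
# profile normalization.

q_at <- function(len, q = 30L, drop_pos = integer(0), drop_q = 10L) {
  qs <- rep(q, len)
  qs[drop_pos] <- drop_q
  rawToChar(as.raw(qs + 33L))
}

test_that("hexamer scan counts tiled repeats and variants", {
  s <- strrep("TTAGGG", 10)
  expect_identical(scan_hexamers(s, q_at(60)), c(TTAGGG = 10L))
  s2 <- paste0(strrep("TTAGGG", 4), "TGAGGG", strrep("TTAGGG", 5))
  expect_identical(scan_hexamers(s2, q_at(60)),
                   c(TTAGGG = 9L, TGAGGG = 1L))
  # antisense reads report forward-strand hexamers
  expect_identical(scan_hexamers(strrep("CCCTAA", 10), q_at(60)),
                   c(TTAGGG = 10L))
  expect_identical(scan_hexamers(reverse_complement(s2), q_at(60)),
                   c(TTAGGG = 9L, TGAGGG = 1L))
  # no quality string disables the filter
  expect_identical(scan_hexamers(s), c(TTAGGG = 10L))
})

test_that("a single low-quality base silences exactly its hexamer", {
  s <- strrep("TTAGGG", 10)
  # one base of the 3rd repeat below 20
  expect_identical(scan_hexamers(s, q_at(60, drop_pos = 15L)),
                   c(TTAGGG = 9L))
  # the same base at exactly 20 still counts
  expect_identical(scan_hexamers(s, q_at(60, drop_pos = 15L, drop_q = 20L)),
                   c(TTAGGG = 10L))
})

test_that("singleton detection requires three canonical flanks and a variant centre", {
  hit <- paste0(strrep("TTAGGG", 3), "TCAGGG", strrep("TTAGGG", 3))
  expect_identical(detect_singletons(hit), c(TCAGGG = 1L))
  # insufficient left flank
  short <- paste0(strrep("TTAGGG", 2), "TCAGGG", strrep("TTAGGG", 3))
  expect_identical(detect_singletons(short), setNames(integer(0), character(0)))
  # canonical centre is not a singleton
  expect_identical(detect_singletons(strrep("TTAGGG", 10)),
                   setNames(integer(0), character(0)))
  # longer flanks still qualify (substring match)
  longer <- paste0(strrep("TTAGGG", 4), "TCAGGG", strrep("TTAGGG", 4))
  expect_identical(detect_singletons(longer), c(TCAGGG = 1L))
  # antisense orientation reports the forward hexamer
  expect_identical(detect_singletons(reverse_complement(hit)),
                   c(TCAGGG = 1L))
  # quality rule applies to the central hexamer only
  expect_identical(detect_singletons(hit, q_at(42, drop_pos = 20L)),
                   setNames(integer(0), character(0)))
  expect_identical(detect_singletons(hit, q_at(42, drop_pos = 3L)),
                   c(TCAGGG = 1L))
})

test_that("context extraction records 18-bp flanks in forward orientation", {
  # TVR with full flanks on both sides
  s <- paste0(strrep("TTAGGG", 3), "TCAGGG", strrep("TTAGGG", 3))
  ctx <- extract_contexts(s)
  expect_identical(nrow(ctx), 1L)
  expect_identical(ctx$left, strrep("TTAGGG", 3))
  expect_identical(ctx$right, strrep("TTAGGG", 3))
  expect_identical(ctx$count, 1L)
  # antisense read yields the identical forward-orientation context
  expect_identical(extract_contexts(reverse_complement(s)), ctx)
  # left flank incomplete: TVR at position 5 of the read
  s2 <- paste0("ACGT", "TCAGGG", strrep("TTAGGG", 4))
  expect_identical(nrow(extract_contexts(s2)), 0L)
  # unlisted TVRs are ignored
  expect_identical(nrow(extract_contexts(s, tvr_list = "TGAGGG")), 0L)
})

test_that("scanners agree with brute-force oracles on random sequences", {
  set.seed(108)
  seqs <- random_scanner_sequences(400)
  quals <- vapply(nchar(seqs), random_qual, "")
  got_h <- scan_hexamers(seqs, quals, per_read = TRUE)
  got_s <- detect_singletons(seqs, quals, per_read = TRUE)
  for (i in seq_along(seqs)) {
    expect_identical(got_h[[i]],
                     tally_hexamers(oracle_scan_hexamers(seqs[i], quals[i])),
                     label = paste("hexamers, seq", i))
    expect_identical(got_s[[i]],
                     tally_hexamers(oracle_singletons(seqs[i], quals[i])),
                     label = paste("singletons, seq", i))
  }
})

test_that("singleton counts never exceed arbitrary-context counts", {
  set.seed(109)
  reads <- vapply(1:200, function(i) {
    make_telomere_sequence(100, c(TCAGGG = 0.1, TGAGGG = 0.05),
                           singleton_rate = 0.5)$seq
  }, "")
  hex <- scan_hexamers(reads)
  sing <- detect_singletons(reads)
  for (h in names(sing)) {
    expect_gte(hex[[h]], sing[[h]])
  }
})

test_that("counts are invariant under reverse complement of telomeric reads", {
  set.seed(110)
  # the greedy hexamer scan is strand-symmetric on its actual domain,
  # telomere-like hexamer tilings (an adversarial G-run such as AGGGGGG can
  # resolve differently per strand); the windowed singleton scan is
  # strand-symmetric on any input
  tel <- vapply(1:200, function(i) {
    make_telomere_sequence(sample(48:250, 1),
                           c(TCAGGG = 0.1, TGAGGG = 0.05, TTGGGG = 0.03),
                           singleton_rate = 0.4)$seq
  }, "")
  expect_identical(scan_hexamers(tel), scan_hexamers(rc(tel)))
  expect_identical(detect_singletons(tel), detect_singletons(rc(tel)))
  seqs <- random_scanner_sequences(200)
  expect_identical(detect_singletons(seqs), detect_singletons(rc(seqs)))
})

test_that("lowering the quality floor never decreases a count", {
  set.seed(111)
  seqs <- random_scanner_sequences(100)
  quals <- vapply(nchar(seqs), random_qual, "")
  for (pair in list(c(30L, 20L), c(20L, 10L), c(10L, 0L))) {
    hi <- scan_hexamers(seqs, quals, pair[1])
    lo <- scan_hexamers(seqs, quals, pair[2])
    for (h in names(hi)) expect_gte(lo[[h]], hi[[h]])
    hi_s <- detect_singletons(seqs, quals, pair[1])
    lo_s <- detect_singletons(seqs, quals, pair[2])
    for (h in names(hi_s)) expect_gte(lo_s[[h]], hi_s[[h]])
  }
})

test_that("profile normalization and log2 ratios follow the definitions", {
  tum <- list(hexamers = c(TTAGGG = 800L, TCAGGG = 40L),
              singletons = c(TCAGGG = 8L),
              n_intratelomeric = 50L, n_total = 10000L)
  # identical composition -> all ratios zero
  p <- summarize_tvr_profile(tum, tum)
  expect_true(all(p$tvr$log2_tc == 0))
  expect_true(all(p$singleton$log2_tc == 0))
  # tumor singleton rate 4x control (same totals) -> ratio 2
  ctl <- tum
  ctl$singletons <- c(TCAGGG = 2L)
  p2 <- summarize_tvr_profile(tum, ctl)
  expect_identical(p2$singleton$log2_tc, 2)
  # hexamers absent from one side are flagged NA, not +-Inf
  ctl2 <- tum
  ctl2$hexamers <- c(TTAGGG = 800L)
  p3 <- summarize_tvr_profile(tum, ctl2)
  expect_true(is.na(p3$tvr$log2_tc[p3$tvr$hexamer == "TCAGGG"]))
  # single-sample normalizations
  p4 <- summarize_tvr_profile(tum)
  expect_identical(p4$tvr$norm[p4$tvr$hexamer == "TCAGGG"], 40 / 50)
  expect_identical(p4$singleton$norm, 8 / 10000)
  # zero intratelomeric reads -> undefined normalization
  p5 <- summarize_tvr_profile(list(hexamers = setNames(integer(0), character(0)),
                                   singletons = setNames(integer(0), character(0)),
                                   n_intratelomeric = 0L, n_total = 100L))
  expect_identical(nrow(p5$tvr), 0L)
})
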