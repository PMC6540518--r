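# Four-way classification of extracted telomeric reads.

tel102 <- strrep("TTAGGG", 17)

test_that("classify_reads follows the documented decision procedure", {
  cfg <- classification_config(test_band_map())
  reads <- rbind(
    # unmapped, mate unmapped -> intratelomeric
    read_row("u", flag = 4L),
    # mapped but mapping quality 0, unpaired -> intratelomeric
    read_row("lowq", flag = 0L, is_mapped = TRUE, chrom = "chr1",
             pos = 1.5e6, mapq = 0L),
    # mapped q60 on the interior band -> intrachromosomal
    read_row("inner", flag = 0L, is_mapped = TRUE, chrom = "chr1",
             pos = 1.5e6, mapq = 60L),
    # mapped q60 on the last band -> subtelomeric
    read_row("last", flag = 0L, is_mapped = TRUE, chrom = "chr2",
             pos = 2.5e6, mapq = 60L),
    # mapped q60 on the first band -> subtelomeric
    read_row("first", flag = 0L, is_mapped = TRUE, chrom = "chr1",
             pos = 10L, mapq = 60L),
    # unmapped, mate mapped to a first band -> junction spanning
    read_row("junc", flag = 5L, is_paired = TRUE, mate_mapped = TRUE,
             mate_chrom = "chr1", mate_pos = 10L),
    # unmapped, mate mapped to an interior band -> no rescue
    read_row("nores", flag = 5L, is_paired = TRUE, mate_mapped = TRUE,
             mate_chrom = "chr1", mate_pos = 1.5e6),
    # high-quality alignment to an unknown decoy contig -> intratelomeric
    read_row("decoy", flag = 0L, is_mapped = TRUE, chrom = "chrUn_gl000220",
             pos = 100L, mapq = 60L)
  )
  got <- classify_reads(reads, cfg)
  expect_identical(as.character(got),
                   c("intratelomeric", "intratelomeric", "intrachromosomal",
                     "subtelomeric", "subtelomeric", "junction_spanning",
                     "intratelomeric", "intratelomeric"))
})

test_that("a mapped low-quality read can be rescued by its terminal-band mate", {
  cfg <- classification_config(test_band_map())
  r <- read_row("m", flag = 1L, is_mapped = TRUE, chrom = "chr1",
                pos = 1.5e6, mapq = 2L, is_paired = TRUE, mate_mapped = TRUE,
                mate_chrom = "chr2", mate_pos = 2.9e6)
  expect_identical(as.character(classify_reads(r, cfg)), "junction_spanning")
})

test_that("every read gets exactly one category and counts partition", {
  set.seed(104)
  cfg <- classification_config(test_band_map())
  n <- 300
  rows <- lapply(seq_len(n), function(i) {
    kind <- sample(1:5, 1)
    switch(kind,
      read_row(paste0("r", i), flag = 4L),
      read_row(paste0("r", i), flag = 0L, is_mapped = TRUE,
               chrom = sample(c("chr1", "chr2", "weird"), 1),
               pos = sample.int(3.2e6, 1), mapq = sample(0:60, 1)),
      read_row(paste0("r", i), flag = 5L, is_paired = TRUE, mate_mapped = TRUE,
               mate_chrom = sample(c("chr1", "chr2"), 1),
               pos = NA, mate_pos = sample.int(3e6, 1)),
      read_row(paste0("r", i), flag = 1L, is_mapped = TRUE, chrom = "chr1",
               pos = sample.int(3e6, 1), mapq = sample(0:10, 1),
               is_paired = TRUE, mate_mapped = TRUE, mate_chrom = "chr2",
               mate_pos = sample.int(3e6, 1)),
      read_row(paste0("r", i), flag = 4L, is_paired = TRUE,
               mate_mapped = FALSE)
    )
  })
  reads <- do.call(rbind, rows)
  got <- classify_reads(reads, cfg)
  expect_false(anyNA(got))
  expect_identical(sum(table(got)), as.integer(n))
})

test_that("raising the mapping-quality threshold never lowers the intratelomeric count", {
  set.seed(105)
  reads <- do.call(rbind, lapply(1:200, function(i) {
    read_row(paste0("r", i), flag = 0L, is_mapped = TRUE,
             chrom = sample(c("chr1", "chr2"), 1),
             pos = sample.int(3e6 - 200, 1), mapq = sample(0:60, 1))
  }))
  counts <- vapply(c(0L, 8L, 20L, 40L, 61L), function(thr) {
    cfg <- classification_config(test_band_map(), thr)
    sum(classify_reads(reads, cfg) == "intratelomeric")
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("per-chromosome spectrum is zero-filled and conserves counts", {
  cfg <- classification_config(test_band_map())
  reads <- rbind(
    read_row("s1", flag = 0L, is_mapped = TRUE, chrom = "chr2", pos = 10,
             mapq = 60L),
    read_row("s2", flag = 0L, is_mapped = TRUE, chrom = "chr2", pos = 20,
             mapq = 60L),
    read_row("s3", flag = 0L, is_mapped = TRUE, chrom = "chr2", pos = 30,
             mapq = 60L),
    read_row("i1", flag = 0L, is_mapped = TRUE, chrom = "chr1", pos = 1.2e6,
             mapq = 60L),
    read_row("j1", flag = 5L, is_paired = TRUE, mate_mapped = TRUE,
             mate_chrom = "chr1", mate_pos = 5L),
    read_row("u1", flag = 4L)
  )
  cats <- classify_reads(reads, cfg)
  sp <- per_chromosome_spectrum(reads, cats, test_band_map())
  expect_setequal(sp$chrom, c("1", "2"))
  expect_identical(sp$subtelomeric[sp$chrom == "2"], 3L)
  expect_identical(sp$subtelomeric[sp$chrom == "1"], 0L)
  expect_identical(sp$intrachromosomal[sp$chrom == "1"], 1L)
  expect_identical(sp$junction_spanning[sp$chrom == "1"], 1L)
  # cell sums equal the non-intratelomeric read count
  expect_identical(sum(sp[, -1]), sum(cats != "intratelomeric"))
  # all-zero table with full chromosome index when nothing is placeable
  sp0 <- per_chromosome_spectrum(reads[0, ], cats[0], test_band_map())
  expect_identical(sum(sp0[, -1]), 0L)
  expect_setequal(sp0$chrom, c("1", "2"))
})
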