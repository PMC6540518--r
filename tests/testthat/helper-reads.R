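# In-code construction of read frames and tiny BAM files for tests.

# a read frame row, defaulting to an unmapped, unpaired read
read_row <- function(qname = "r1", seq = strrep("TTAGGG", 17),
                     qual = strrep("I", nchar(seq)), flag = 4L,
                     is_mapped = FALSE, chrom = NA_character_,
                     pos = NA_integer_, mapq = 0L, is_paired = FALSE,
                     is_proper = FALSE, mate_mapped = FALSE,
                     mate_chrom = NA_character_, mate_pos = NA_integer_,
                     is_duplicate = FALSE) {
  data.frame(qname = qname, flag = flag, seq = seq, qual = qual,
             is_mapped = is_mapped, chrom = chrom, pos = as.integer(pos),
             mapq = as.integer(mapq), is_paired = is_paired,
             is_proper = is_proper, mate_mapped = mate_mapped,
             mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
             is_duplicate = is_duplicate, stringsAsFactors = FALSE)
}

# two chromosomes, three bands each, 1 Mb per band
test_band_map <- function() {
  band_map(chrom = rep(c("chr1", "chr2"), each = 3),
           band = rep(c("p11", "q11", "q12"), 2),
           start = rep(c(0, 1e6, 2e6), 2),
           end = rep(c(1e6, 2e6, 3e6), 2))
}

# write SAM lines (with a minimal header) and convert to an indexed BAM
write_test_bam <- function(body_lines, dir = tempfile("bam"),
                           targets = c(chr1 = 3000000L, chr2 = 3000000L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "test.sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(targets), "\tLN:", unname(targets)))
  writeLines(c(header, body_lines), sam)
  Rsamtools::asBam(sam, file.path(dir, "test"), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_line <- function(qname, flag, rname = "*", pos = 0L, mapq = 0L,
                     cigar = "*", rnext = "*", pnext = 0L, seq, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, 0L, seq, qual,
        sep = "\t")
}
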