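# Synthetic aligned-read fixtures with exact planted ground truth: telomere
# reads of configurable variant-repeat composition, reads placed on known
# bands, junction-spanning pairs, and exact-GC background reads. Ground
# truth (categories, hexamer and singleton counts, expected TRPM) is derived
# combinatorially from the planted hexamer tilings, independently of the
# scanners it is used to test.

#' Specification for a synthetic fixture
#'
#' Defaults describe a small but complete sample: 100-bp reads, a telomere
#' compartment of 50 reads with 5% g-type and 2% c-type variant repeats and
#' a 10% singleton rate, 20 subtelomeric and 20 intrachromosomal reads, 10
#' junction pairs, and 10,000 background reads at exactly 50% GC.
#'
#' @param read_length Read length in bp (default 100).
#' @param n_intratelomeric,n_subtelomeric,n_junction,n_intrachromosomal,n_background
#'   Reads per category (`n_junction` counts pairs: one unmapped telomeric
#'   mate plus one mapped non-telomeric anchor each).
#' @param tvr_freqs Named numeric vector: per-hexamer-slot probability of
#'   each variant repeat (names of the form `NNNGGG`); the remainder is
#'   canonical `TTAGGG`. Frequencies must sum to at most 1.
#' @param singleton_rate Per-read probability of planting one guaranteed
#'   singleton (requires `read_length >= 42`).
#' @param background_gc Target GC percent of background reads; a vector is
#'   sampled uniformly per read. Each read's GC count is exact, so the
#'   GC-matched denominator is known in closed form.
#' @param base_quality Uniform Phred base quality (default 30).
#' @param seed Random seed (fixed seed gives byte-identical output).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(read_length = 100L,
                         n_intratelomeric = 50L,
                         n_subtelomeric = 20L,
                         n_junction = 10L,
                         n_intrachromosomal = 20L,
                         n_background = 10000L,
                         tvr_freqs = c(TGAGGG = 0.05, TCAGGG = 0.02),
                         singleton_rate = 0.1,
                         background_gc = 50L,
                         base_quality = 30L,
                         seed = 1L) {
  if (length(tvr_freqs) > 0) {
    if (is.null(names(tvr_freqs)) ||
        any(!grepl("^[ACGT]{3}GGG$", names(tvr_freqs)))) {
      stop("tvr_freqs must be named by hexamers of the form NNNGGG",
           call. = FALSE)
    }
    if (sum(tvr_freqs) > 1) stop("tvr_freqs must sum to <= 1", call. = FALSE)
  }
  if (singleton_rate > 0 && read_length < 42) {
    stop("singleton planting requires read_length >= 42", call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_spec")
}

# one quality string for all reads of the fixture
.qual_string <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)

#' Generate one telomere-like read sequence with planted truth
#'
#' Builds an in-frame tiling of hexamers: each slot is a variant repeat with
#' the given probability, canonical `TTAGGG` otherwise; with probability
#' `singleton_rate` one slot is forced into singleton context (three
#' canonical repeats on each side). Because every hexamer ends in `GGG`, no
#' out-of-frame telomeric motif can arise, so the tiling itself *is* the
#' ground truth: hexamer counts are the slot tabulation and singleton counts
#' are the slots with a non-canonical centre flanked by three canonical
#' repeats on both sides.
#'
#' @param length Read length in bp.
#' @param tvr_freqs Named per-slot variant frequencies (may be empty).
#' @param singleton_rate Probability of planting one singleton.
#' @return List with `seq`, `hexamers` (named counts over all slots) and
#'   `singletons` (named counts).
#' @export
make_telomere_sequence <- function(length, tvr_freqs = numeric(0),
                                   singleton_rate = 0) {
  if (singleton_rate > 0 && length < 42) {
    stop("singleton planting requires length >= 42", call. = FALSE)
  }
  n_hex <- length %/% 6L
  choices <- c(names(tvr_freqs), .TTYPE)
  probs <- c(as.numeric(tvr_freqs), 1 - sum(tvr_freqs))
  slots <- sample(choices, n_hex, replace = TRUE, prob = probs)
  if (singleton_rate > 0 && runif(1) < singleton_rate) {
    j <- if (n_hex == 7L) 4L else sample(4:(n_hex - 3L), 1L)
    slots[(j - 3L):(j + 3L)] <- .TTYPE
    slots[j] <- if (length(tvr_freqs) > 0) {
      sample(names(tvr_freqs), 1L, prob = as.numeric(tvr_freqs))
    } else {
      "TCAGGG"
    }
  }
  pad <- length - 6L * n_hex
  seq <- paste0(paste(slots, collapse = ""), substr(.TTYPE, 1L, pad))
  is_t <- slots == .TTYPE
  singles <- character(0)
  if (n_hex >= 7L) {
    for (j in 4:(n_hex - 3L)) {
      if (!is_t[j] && all(is_t[(j - 3L):(j - 1L)]) && all(is_t[(j + 1L):(j + 3L)])) {
        singles <- c(singles, slots[j])
      }
    }
  }
  list(seq = seq, hexamers = tally_hexamers(slots),
       singletons = tally_hexamers(singles))
}

# Random sequence with an exact number of G/C bases (target percent applied
# to the full length, round-half-up), rejection-sampled to stay below the
# telomeric extraction threshold.
.background_sequence <- function(length, gc_target, config) {
  n_gc <- as.integer(floor(length * gc_target / 100 + 0.5))
  repeat {
    base <- sample(c("A", "T"), length, replace = TRUE)
    pos <- sample.int(length, n_gc)
    base[pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    seq <- paste(base, collapse = "")
    if (!is_telomeric(seq, config)) return(seq)
  }
}

# merge named count vectors
.add_counts <- function(a, b) {
  if (length(b) == 0) return(a)
  all <- union(names(a), names(b))
  out <- setNames(rep(0L, length(all)), all)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[order(-out, names(out))]
}

#' Emit a synthetic fixture: band file, BAM and ground truth
#'
#' Writes a cytoBand-dialect band file (chr1 and chr2, three bands each over
#' 3 Mb) and a coordinate-sorted, indexed BAM with reads placed per
#' category: intratelomeric reads unmapped; subtelomeric reads on terminal
#' bands and intrachromosomal reads on the interior band at mapping quality
#' 60; junction pairs as one non-telomeric anchor on a terminal band plus
#' one unmapped telomeric mate; background reads of exact target GC mapped
#' to the interior band. Ground truth is returned and also written as
#' `truth.json` / `truth_categories.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing).
#' @param extraction An [extraction_config()] used for background rejection
#'   sampling and telomere-read validation.
#' @return List with `bam`, `band_file`, and `truth` (fields: `categories`
#'   data.frame with `qname`/`category`; `hexamers` and `singletons`,
#'   planted counts over intratelomeric reads; `n_intratelomeric`;
#'   `n_total`; `gc_matched`, the closed-form GC-window denominator;
#'   `expected_trpm`).
#' @export
emit_fixture <- function(spec, out_dir, extraction = extraction_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$read_length
  qual <- .qual_string(spec$base_quality, L)
  band_len <- 1000000L
  chroms <- c("chr1", "chr2")
  band_file <- file.path(out_dir, "cytoband.txt")
  band_lines <- unlist(lapply(chroms, function(cm) {
    paste(cm,
          c(0L, band_len, 2L * band_len),
          c(band_len, 2L * band_len, 3L * band_len),
          c("p11", "q11", "q12"), "gneg", sep = "\t")
  }))
  writeLines(band_lines, band_file)
  bmap <- read_band_file(band_file)

  telomere_read <- function() {
    make_telomere_sequence(L, spec$tvr_freqs, spec$singleton_rate)
  }
  # positions fully inside the chosen band (1-based SAM coordinates)
  rand_terminal <- function(n) {
    first <- runif(n) < 0.5
    lo <- ifelse(first, 1L, 2L * band_len + 1L)
    list(chrom = sample(chroms, n, replace = TRUE),
         pos = lo + floor(runif(n) * (band_len - L)))
  }
  rand_interior <- function(n) {
    list(chrom = sample(chroms, n, replace = TRUE),
         pos = band_len + 1L + floor(runif(n) * (band_len - L)))
  }

  rows <- list()
  truth_cat <- list()
  hex_truth <- setNames(integer(0), character(0))
  sing_truth <- setNames(integer(0), character(0))
  add_rows <- function(qname, flag, seq, chrom = NA_character_,
                       pos = NA_integer_, mapq = 0L,
                       mate_chrom = NA_character_, mate_pos = NA_integer_) {
    data.frame(qname = qname, flag = flag, seq = seq, qual = qual,
               is_mapped = bitwAnd(flag, 4L) == 0L, chrom = chrom,
               pos = as.integer(pos), mapq = as.integer(mapq),
               is_paired = bitwAnd(flag, 1L) != 0L, is_proper = FALSE,
               mate_mapped = bitwAnd(flag, 1L) != 0L & bitwAnd(flag, 8L) == 0L,
               mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
               is_duplicate = FALSE, stringsAsFactors = FALSE)
  }

  if (spec$n_intratelomeric > 0) {
    tel <- replicate(spec$n_intratelomeric, telomere_read(), simplify = FALSE)
    for (t in tel) {
      hex_truth <- .add_counts(hex_truth, t$hexamers)
      sing_truth <- .add_counts(sing_truth, t$singletons)
    }
    qn <- sprintf("intra_%05d", seq_len(spec$n_intratelomeric))
    rows <- c(rows, list(add_rows(qn, 4L, vapply(tel, `[[`, "", "seq"))))
    truth_cat <- c(truth_cat, list(data.frame(qname = qn,
                                              category = "intratelomeric")))
  }
  if (spec$n_subtelomeric > 0) {
    tel <- replicate(spec$n_subtelomeric, telomere_read(), simplify = FALSE)
    loc <- rand_terminal(spec$n_subtelomeric)
    qn <- sprintf("subtel_%05d", seq_len(spec$n_subtelomeric))
    rows <- c(rows, list(add_rows(qn, 0L, vapply(tel, `[[`, "", "seq"),
                                  chrom = loc$chrom, pos = loc$pos, mapq = 60L)))
    truth_cat <- c(truth_cat, list(data.frame(qname = qn,
                                              category = "subtelomeric")))
  }
  if (spec$n_intrachromosomal > 0) {
    tel <- replicate(spec$n_intrachromosomal, telomere_read(), simplify = FALSE)
    loc <- rand_interior(spec$n_intrachromosomal)
    qn <- sprintf("intrachrom_%05d", seq_len(spec$n_intrachromosomal))
    rows <- c(rows, list(add_rows(qn, 0L, vapply(tel, `[[`, "", "seq"),
                                  chrom = loc$chrom, pos = loc$pos, mapq = 60L)))
    truth_cat <- c(truth_cat, list(data.frame(qname = qn,
                                              category = "intrachromosomal")))
  }
  n_bg_like <- 0L # non-telomeric reads whose GC is the background target
  bg_gc_targets <- integer(0)
  if (spec$n_junction > 0) {
    tel <- replicate(spec$n_junction, telomere_read(), simplify = FALSE)
    loc <- rand_terminal(spec$n_junction)
    gc_t <- rep(spec$background_gc, length.out = spec$n_junction)[
      sample.int(spec$n_junction)]
    anchors <- vapply(gc_t, function(g) {
      .background_sequence(L, g, extraction)
    }, character(1))
    bg_gc_targets <- c(bg_gc_targets, gc_t)
    qn <- sprintf("junction_%05d", seq_len(spec$n_junction))
    # anchor: paired, mate unmapped (0x1 + 0x8); telomeric mate: paired,
    # unmapped (0x1 + 0x4), carrying the anchor's coordinates
    rows <- c(rows, list(
      add_rows(qn, 9L, anchors, chrom = loc$chrom, pos = loc$pos, mapq = 60L,
               mate_chrom = loc$chrom, mate_pos = loc$pos),
      add_rows(qn, 5L, vapply(tel, `[[`, "", "seq"), chrom = loc$chrom,
               pos = NA_integer_, mapq = 0L,
               mate_chrom = loc$chrom, mate_pos = loc$pos)
    ))
    truth_cat <- c(truth_cat,
                   list(data.frame(qname = qn, category = "anchor"),
                        data.frame(qname = qn, category = "junction_spanning")))
  }
  if (spec$n_background > 0) {
    gc_t <- rep(spec$background_gc, length.out = spec$n_background)[
      sample.int(spec$n_background)]
    seqs <- vapply(gc_t, function(g) {
      .background_sequence(L, g, extraction)
    }, character(1))
    bg_gc_targets <- c(bg_gc_targets, gc_t)
    loc <- rand_interior(spec$n_background)
    qn <- sprintf("bg_%06d", seq_len(spec$n_background))
    rows <- c(rows, list(add_rows(qn, 0L, seqs, chrom = loc$chrom,
                                  pos = loc$pos, mapq = 60L)))
    truth_cat <- c(truth_cat, list(data.frame(qname = qn,
                                              category = "background")))
  }

  reads <- do.call(rbind, rows)
  categories <- do.call(rbind, truth_cat)
  # every planted telomeric read must pass extraction, or the ground truth
  # would be inconsistent with the pipeline's view of the file
  telomeric_truth <- categories$category %in% c("intratelomeric",
                                                "subtelomeric",
                                                "intrachromosomal",
                                                "junction_spanning")
  if (!all(is_telomeric(reads$seq[telomeric_truth], extraction))) {
    stop("planted telomere reads fail the extraction threshold; ",
         "lower tvr_freqs mass outside the search set or the threshold",
         call. = FALSE)
  }
  targets <- setNames(rep(3L * band_len, length(chroms)), chroms)
  sam <- file.path(out_dir, "fixture.sam")
  writeLines(.reads_to_sam(reads, targets), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "fixture"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)

  # closed-form GC bin of each exact-GC read: same rounding as the emitted
  # sequence construction, known without re-scanning the file
  bg_bins <- floor(100 * floor(L * bg_gc_targets / 100 + 0.5) / L + 0.5)
  gc_matched <- sum(bg_bins >= 48 & bg_bins <= 52)
  truth <- list(
    categories = categories,
    hexamers = hex_truth,
    singletons = sing_truth,
    n_intratelomeric = as.integer(spec$n_intratelomeric),
    n_total = nrow(reads),
    gc_matched = as.integer(gc_matched),
    expected_trpm = if (gc_matched > 0) {
      spec$n_intratelomeric / gc_matched * 1e6
    } else {
      NA_real_
    }
  )
  jsonlite::write_json(truth[setdiff(names(truth), "categories")],
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(categories, file.path(out_dir, "truth_categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(bam = bam, band_file = band_file, band_map = bmap, truth = truth)
}
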