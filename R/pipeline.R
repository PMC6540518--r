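# Pipeline orchestration: one pass per sample (totals and GC distribution,
# extraction, classification, TVR/singleton scans), then optional pairing
# with log2 tumor/control ratios. All results are plain data.frames,
# serialized as TSV when an output directory is given.

#' Run the full profiling pipeline on one sample
#'
#' Every primary, non-supplementary read contributes to the total and (if
#' non-telomeric) to the GC distribution; telomeric reads are classified
#' into the four fractions; the intratelomeric fraction feeds the TVR,
#' singleton and context scans. Extracted telomeric reads themselves are
#' excluded from the GC-matched denominator so that the normalization
#' reflects background sequencing depth at telomere-like GC rather than the
#' telomere compartment being measured.
#'
#' @param path BAM file of the sample.
#' @param band_map A `band_map`, or the path of a cytoBand file.
#' @param sample_name Label used in output tables (default: file name).
#' @param extraction An [extraction_config()].
#' @param mapping_quality_threshold Classification threshold (default 8).
#' @param min_base_quality Per-base Phred floor for TVR counting
#'   (default 20).
#' @param tvr_context Hexamers for 18-bp context extraction
#'   (default [default_tvr_context()]).
#' @param out_dir Optional output directory: result tables and per-category
#'   BAM files are written there.
#' @param exclude_duplicates Drop duplicate-flagged reads (default `FALSE`).
#' @param verbose Log per-stage counts via [message()] (default `FALSE`).
#' @return An object of class `sample_result`: counts per category, the GC
#'   distribution, the [telomere_content()] estimate, TVR bundle, context
#'   table, per-chromosome spectrum, repeat-count histogram, and the
#'   summary/tvr/singleton tables.
#' @export
run_sample <- function(path, band_map,
                       sample_name = basename(path),
                       extraction = extraction_config(),
                       mapping_quality_threshold = 8L,
                       min_base_quality = 20L,
                       tvr_context = default_tvr_context(),
                       out_dir = NULL,
                       exclude_duplicates = FALSE,
                       verbose = FALSE) {
  if (is.character(band_map)) band_map <- read_band_file(band_map)
  stopifnot(inherits(band_map, "band_map"))
  say <- function(...) if (verbose) message("[", sample_name, "] ", ...)

  reads <- stream_reads(path, exclude_duplicates = exclude_duplicates)
  n_total <- nrow(reads)
  skipped <- attr(reads, "skipped")
  say(n_total, " primary reads (skipped: ",
      paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  if (n_total == 0) warning("no reads in ", path, call. = FALSE)

  telomeric <- if (n_total > 0) is_telomeric(reads$seq, extraction) else logical(0)
  say(sum(telomeric), " telomeric reads extracted")

  gc_dist <- accumulate_gc_distribution(reads$seq[!telomeric])
  attr(gc_dist, "total_reads") <- n_total

  tel_reads <- reads[telomeric, , drop = FALSE]
  attr(tel_reads, "targets") <- attr(reads, "targets")
  cls_config <- classification_config(band_map, mapping_quality_threshold)
  categories <- classify_reads(tel_reads, cls_config)
  cat_counts <- table(categories)
  say("categories: ", paste(names(cat_counts), as.integer(cat_counts),
                            sep = "=", collapse = ", "))

  intra <- tel_reads[categories == "intratelomeric", , drop = FALSE]
  content <- telomere_content(nrow(intra), gc_dist)
  say("GC-matched denominator: ", content$gc_matched_denominator,
      "; TRPM: ", format(content$trpm))

  tvr <- tvr_sample_counts(intra$seq, intra$qual, total_reads = n_total,
                           min_base_quality = min_base_quality)
  contexts <- extract_contexts(intra$seq, tvr_context)
  spectrum <- per_chromosome_spectrum(tel_reads, categories, band_map)
  hist_counts <- repeats_per_read_histogram(intra$seq, extraction)

  summary_tab <- data.frame(
    sample = sample_name,
    total_reads = n_total,
    gc_matched_reads = content$gc_matched_denominator,
    intratelomeric = as.integer(cat_counts[["intratelomeric"]]),
    subtelomeric = as.integer(cat_counts[["subtelomeric"]]),
    junction_spanning = as.integer(cat_counts[["junction_spanning"]]),
    intrachromosomal = as.integer(cat_counts[["intrachromosomal"]]),
    trpm = content$trpm,
    trpm_uncorrected = uncorrected_content(nrow(intra), n_total),
    stringsAsFactors = FALSE
  )
  profile <- summarize_tvr_profile(tvr)

  res <- structure(
    list(sample = sample_name,
         n_total = n_total,
         skipped = skipped,
         telomeric = telomeric,
         categories = categories,
         category_counts = setNames(as.integer(cat_counts), names(cat_counts)),
         gc_distribution = gc_dist,
         content = content,
         tvr = tvr,
         contexts = contexts,
         spectrum = spectrum,
         repeat_histogram = hist_counts,
         summary = summary_tab,
         tvr_table = profile$tvr,
         singleton_table = profile$singleton,
         reads = tel_reads),
    class = "sample_result"
  )
  if (!is.null(out_dir)) {
    write_result_tables(
      list(summary = summary_tab, tvr_counts = profile$tvr,
           singletons = profile$singleton, contexts = contexts,
           spectrum = spectrum),
      out_dir)
    for (cat in levels(categories)) {
      write_category_reads(tel_reads[categories == cat, , drop = FALSE],
                           cat, out_dir, targets = attr(reads, "targets"))
    }
  }
  res
}

#' @export
print.sample_result <- function(x, ...) {
  cat("sample_result '", x$sample, "': ", x$n_total, " reads, ",
      sum(x$category_counts), " telomeric (",
      paste(names(x$category_counts), x$category_counts, sep = "=",
            collapse = ", "), "), TRPM ",
      format(x$content$trpm), "\n", sep = "")
  invisible(x)
}

#' Run a matched tumor/control pair
#'
#' Two [run_sample()] passes plus paired statistics: the telomere-content
#' log2 tumor/control ratio and per-hexamer log2 ratios of normalized TVR
#' and singleton counts.
#'
#' @param tumor,control BAM paths.
#' @param band_map A `band_map` or cytoBand file path.
#' @param out_dir Optional output directory; per-sample outputs go to
#'   `tumor/` and `control/` subdirectories, combined tables to the root.
#' @param plot If `TRUE`, write summary plots (PNG) to `out_dir`.
#' @param ... Passed on to [run_sample()].
#' @return An object of class `pair_result`: both `sample_result`s, the
#'   content `log2_tc`, the paired TVR/singleton tables, and the combined
#'   summary table.
#' @export
run_pair <- function(tumor, control, band_map, out_dir = NULL, plot = FALSE,
                     ...) {
  if (is.character(band_map)) band_map <- read_band_file(band_map)
  res_t <- run_sample(tumor, band_map, sample_name = "tumor",
                      out_dir = if (is.null(out_dir)) NULL
                                else file.path(out_dir, "tumor"), ...)
  res_c <- run_sample(control, band_map, sample_name = "control",
                      out_dir = if (is.null(out_dir)) NULL
                                else file.path(out_dir, "control"), ...)
  log2_tc <- log2_tc_ratio(res_t$content, res_c$content)
  profile <- summarize_tvr_profile(res_t$tvr, res_c$tvr)
  summary_tab <- rbind(res_t$summary, res_c$summary)
  summary_tab$log2_tc <- c(log2_tc, -log2_tc)
  res <- structure(
    list(tumor = res_t, control = res_c, log2_tc = log2_tc,
         tvr_table = profile$tvr, singleton_table = profile$singleton,
         summary = summary_tab),
    class = "pair_result"
  )
  if (!is.null(out_dir)) {
    write_result_tables(
      list(summary = summary_tab, tvr_counts = profile$tvr,
           singletons = profile$singleton),
      out_dir)
    if (plot) plot_pair_result(res, out_dir)
  }
  res
}

#' @export
print.pair_result <- function(x, ...) {
  cat("pair_result: tumor TRPM ", format(x$tumor$content$trpm),
      ", control TRPM ", format(x$control$content$trpm),
      ", log2 T/C ", format(x$log2_tc), "\n", sep = "")
  invisible(x)
}

#' Histogram of repeat units per intratelomeric read
#'
#' Tabulates [count_repeat_hits()] over the intratelomeric reads; bins run
#' from the extraction threshold (of the shortest read) to the maximum
#' number of hexamers a read can hold.
#'
#' @param sequences Intratelomeric read sequences.
#' @param extraction The [extraction_config()] used for extraction.
#' @return Named integer vector of counts per repeat number (empty input
#'   gives an empty vector).
#' @export
repeats_per_read_histogram <- function(sequences, extraction = extraction_config()) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0) return(setNames(integer(0), character(0)))
  hits <- count_repeat_hits(sequences, extraction$pattern_set)
  lo <- if (!is.null(extraction$threshold_override)) {
    extraction$threshold_override
  } else {
    min(compute_repeat_threshold(nchar(sequences),
                                 extraction$threshold_coefficient))
  }
  hi <- max(nchar(sequences) %/% 6L, hits)
  bins <- lo:hi
  setNames(vapply(bins, function(b) sum(hits == b), integer(1)),
           as.character(bins))
}
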