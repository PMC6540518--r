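# Four-way classification of extracted telomeric reads by alignment
# position, mapping quality and mate information.

.CATEGORIES <- c("intratelomeric", "junction_spanning", "subtelomeric",
                 "intrachromosomal")

#' Construct a classification configuration
#'
#' @param band_map A `band_map` from [read_band_file()] or [band_map()].
#' @param mapping_quality_threshold Reads aligned below this mapping quality
#'   are treated as unplaced (default 8).
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(band_map, mapping_quality_threshold = 8L) {
  stopifnot(inherits(band_map, "band_map"))
  mapping_quality_threshold <- as.integer(mapping_quality_threshold)
  stopifnot(mapping_quality_threshold >= 0L)
  structure(list(band_map = band_map,
                 mapping_quality_threshold = mapping_quality_threshold),
            class = "classification_config")
}

#' Classify telomeric reads into the four read fractions
#'
#' Decision procedure, in fixed precedence order:
#' 1. A read mapped with mapping quality at or above the threshold is placed
#'    by its own position: terminal band gives `subtelomeric`, interior band
#'    gives `intrachromosomal`, no band (unknown contig or position beyond
#'    all bands) gives `intratelomeric`.
#' 2. Otherwise (unmapped or low mapping quality) the mate is consulted: a
#'    paired read whose mapped mate lies on a terminal band becomes
#'    `junction_spanning`; everything else is `intratelomeric`.
#'
#' @param reads A read frame ([stream_reads()]) of extracted telomeric
#'   reads.
#' @param config A [classification_config()].
#' @return Factor of length `nrow(reads)` with levels `intratelomeric`,
#'   `junction_spanning`, `subtelomeric`, `intrachromosomal`.
#' @export
classify_reads <- function(reads, config) {
  stopifnot(inherits(config, "classification_config"))
  n <- nrow(reads)
  out <- rep("intratelomeric", n)
  mapq <- ifelse(is.na(reads$mapq), 0L, reads$mapq)
  placed <- reads$is_mapped & mapq >= config$mapping_quality_threshold &
    !is.na(reads$pos)
  if (any(placed)) {
    loc <- locate_band(reads$chrom[placed], reads$pos[placed], config$band_map)
    cat_placed <- ifelse(is.na(loc$band), "intratelomeric",
                         ifelse(loc$terminal, "subtelomeric", "intrachromosomal"))
    out[placed] <- cat_placed
  }
  rescue <- !placed & reads$is_paired & reads$mate_mapped &
    !is.na(reads$mate_chrom) & !is.na(reads$mate_pos)
  if (any(rescue)) {
    loc <- locate_band(reads$mate_chrom[rescue], reads$mate_pos[rescue],
                       config$band_map)
    out[rescue][!is.na(loc$band) & loc$terminal %in% TRUE] <- "junction_spanning"
  }
  factor(out, levels = .CATEGORIES)
}

#' Per-chromosome spectrum of placeable telomeric reads
#'
#' Counts subtelomeric, junction-spanning and intrachromosomal reads per
#' chromosome of the band map (intratelomeric reads have no position by
#' definition). Junction-spanning reads are attributed to the mate's
#' chromosome. The table is zero-filled over every band-map chromosome.
#'
#' @param reads Read frame of classified telomeric reads.
#' @param categories Factor from [classify_reads()] (parallel to `reads`).
#' @param band_map The `band_map` used for classification.
#' @return Data.frame `chrom`, `subtelomeric`, `junction_spanning`,
#'   `intrachromosomal`.
#' @export
per_chromosome_spectrum <- function(reads, categories, band_map) {
  stopifnot(inherits(band_map, "band_map"), nrow(reads) == length(categories))
  chroms <- unique(band_map$chrom)
  out <- data.frame(chrom = chroms,
                    subtelomeric = 0L, junction_spanning = 0L,
                    intrachromosomal = 0L, stringsAsFactors = FALSE)
  chrom_of <- normalize_chromosome(
    ifelse(as.character(categories) == "junction_spanning",
           reads$mate_chrom, reads$chrom))
  for (cat in c("subtelomeric", "junction_spanning", "intrachromosomal")) {
    sel <- as.character(categories) == cat & !is.na(chrom_of)
    if (!any(sel)) next
    tab <- table(chrom_of[sel])
    idx <- match(names(tab), out$chrom)
    ok <- !is.na(idx)
    out[[cat]][idx[ok]] <- as.integer(tab)[ok]
  }
  out
}
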