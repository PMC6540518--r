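# Telomere variant repeat (TVR) analysis on intratelomeric reads:
# NNNGGG hexamer quantification in arbitrary context, singleton detection
# ((TTAGGG)3-NNNGGG-(TTAGGG)3), 18-bp flanking-context tables, and
# tumor/control log2 ratios of the normalized counts.

.as_qual_vec <- function(qualities, n) {
  if (is.null(qualities)) return(character(0))
  stopifnot(length(qualities) == n)
  as.character(qualities)
}

#' Scan reads for telomere-type hexamers
#'
#' Non-overlapping left-to-right scan for 6-mers ending in `GGG` (sense) or
#' starting with `CCC` (antisense, reported as the forward-strand reverse
#' complement). A motif hit always advances the scan frame by six bases but
#' is only counted when all six base qualities reach `min_base_quality`;
#' elsewhere the scan advances one base.
#'
#' @param sequences Character vector of read sequences.
#' @param qualities Optional character vector of Phred+33 quality strings
#'   (same length as `sequences`); `NULL` disables quality filtering.
#' @param min_base_quality Minimum Phred quality for every base of a counted
#'   hexamer (default 20).
#' @param per_read If `TRUE`, return a list of per-read named count vectors
#'   instead of the sample-level aggregate.
#' @return Named integer vector of hexamer counts (or a list of them).
#' @export
scan_hexamers <- function(sequences, qualities = NULL, min_base_quality = 20L,
                          per_read = FALSE) {
  sequences <- toupper(as.character(sequences))
  hits <- cpp_scan_hexamers(sequences,
                            .as_qual_vec(qualities, length(sequences)),
                            as.integer(min_base_quality))
  if (per_read) {
    lapply(hits, tally_hexamers)
  } else {
    tally_hexamers(unlist(hits, use.names = FALSE))
  }
}

#' Tally a vector of hexamer occurrences into named counts
#'
#' @param hexamers Character vector of hexamer occurrences.
#' @return Named integer vector sorted by decreasing count.
#' @export
tally_hexamers <- function(hexamers) {
  if (length(hexamers) == 0) return(setNames(integer(0), character(0)))
  tab <- table(hexamers)
  out <- setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Detect singleton variant repeats
#'
#' A singleton is a lone variant hexamer embedded in canonical repeats:
#' `(TTAGGG)3-NNNGGG-(TTAGGG)3` with the central hexamer different from
#' `TTAGGG`, in either orientation (antisense occurrences are reported as
#' the forward hexamer). Every 42-bp window is examined, so longer flanks
#' still qualify. The base-quality rule applies to the central hexamer only.
#'
#' @inheritParams scan_hexamers
#' @return Named integer vector of singleton counts (or a per-read list).
#' @export
detect_singletons <- function(sequences, qualities = NULL,
                              min_base_quality = 20L, per_read = FALSE) {
  sequences <- toupper(as.character(sequences))
  hits <- cpp_detect_singletons(sequences,
                                .as_qual_vec(qualities, length(sequences)),
                                as.integer(min_base_quality))
  if (per_read) {
    lapply(hits, tally_hexamers)
  } else {
    tally_hexamers(unlist(hits, use.names = FALSE))
  }
}

#' Extract flanking contexts around selected TVRs
#'
#' For every scanned occurrence of a listed TVR with at least `flank` bases
#' on both sides, the (left, right) flank pair is recorded in
#' telomere-forward orientation; occurrences closer than `flank` bases to a
#' read end are dropped.
#'
#' @param sequences Character vector of read sequences.
#' @param tvr_list Hexamers to profile (default [default_tvr_context()]).
#' @param flank Flank length in bases (default 18).
#' @return A data.frame `tvr`, `left`, `right`, `count`, one row per
#'   distinct combination.
#' @export
extract_contexts <- function(sequences, tvr_list = default_tvr_context(),
                             flank = 18L) {
  stopifnot(length(tvr_list) > 0)
  tvr_list <- toupper(as.character(tvr_list))
  raw <- cpp_extract_contexts(toupper(as.character(sequences)), tvr_list,
                              as.integer(flank))
  if (nrow(raw) == 0) {
    return(data.frame(tvr = character(0), left = character(0),
                      right = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(raw))),
                          by = raw[c("tvr", "left", "right")], FUN = sum)
  agg <- agg[order(agg$tvr, -agg$count, agg$left), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Normalized count table for one sample: raw counts / denominator.
.norm_table <- function(counts, denom) {
  data.frame(hexamer = names(counts),
             count = as.integer(counts),
             norm = if (denom > 0) as.numeric(counts) / denom
                    else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE)
}

#' Per-sample TVR count bundle
#'
#' Convenience builder running [scan_hexamers()] and [detect_singletons()]
#' over the intratelomeric reads of one sample.
#'
#' @param sequences Intratelomeric read sequences.
#' @param qualities Matching Phred+33 quality strings (or `NULL`).
#' @param total_reads Total primary reads in the sample (singleton
#'   normalization denominator).
#' @param min_base_quality Minimum per-base Phred quality (default 20).
#' @return A list with `hexamers`, `singletons` (named integer vectors),
#'   `n_intratelomeric` and `n_total`.
#' @export
tvr_sample_counts <- function(sequences, qualities = NULL, total_reads,
                              min_base_quality = 20L) {
  list(hexamers = scan_hexamers(sequences, qualities, min_base_quality),
       singletons = detect_singletons(sequences, qualities, min_base_quality),
       n_intratelomeric = length(sequences),
       n_total = as.integer(total_reads))
}

# Merge tumor/control normalized tables and add log2 ratios; hexamers absent
# from one side get NA ratios (flagged undefined, never +-Inf).
.pair_table <- function(tumor, control, denom_t, denom_c) {
  hex <- sort(unique(c(names(tumor), names(control))))
  ct <- setNames(rep(0L, length(hex)), hex); ct[names(tumor)] <- tumor
  cc <- setNames(rep(0L, length(hex)), hex); cc[names(control)] <- control
  nt <- if (denom_t > 0) ct / denom_t else rep(NA_real_, length(hex))
  nc <- if (denom_c > 0) cc / denom_c else rep(NA_real_, length(hex))
  ratio <- ifelse(!is.na(nt) & !is.na(nc) & nt > 0 & nc > 0,
                  log2(nt / nc), NA_real_)
  data.frame(hexamer = hex,
             count_tumor = as.integer(ct), norm_tumor = as.numeric(nt),
             count_control = as.integer(cc), norm_control = as.numeric(nc),
             log2_tc = ratio, stringsAsFactors = FALSE)
}

#' Summarize a TVR profile for one sample or a tumor/control pair
#'
#' Applies the two normalizations of the method: hexamer counts in arbitrary
#' context per intratelomeric read, singleton counts per total sample read.
#' With a control present, per-hexamer `log2(normalized tumor / normalized
#' control)` ratios are computed; hexamers absent on one side are `NA`.
#'
#' @param tumor A [tvr_sample_counts()] bundle.
#' @param control Optional second bundle.
#' @return An object of class `tvr_profile` with data.frames `tvr` and
#'   `singleton` (single-sample runs have columns `hexamer`, `count`,
#'   `norm`; paired runs add control columns and `log2_tc`).
#' @export
summarize_tvr_profile <- function(tumor, control = NULL) {
  stopifnot(is.list(tumor), !is.null(tumor$hexamers))
  if (is.null(control)) {
    out <- list(
      tvr = .norm_table(tumor$hexamers, tumor$n_intratelomeric),
      singleton = .norm_table(tumor$singletons, tumor$n_total),
      paired = FALSE
    )
  } else {
    out <- list(
      tvr = .pair_table(tumor$hexamers, control$hexamers,
                        tumor$n_intratelomeric, control$n_intratelomeric),
      singleton = .pair_table(tumor$singletons, control$singletons,
                              tumor$n_total, control$n_total),
      paired = TRUE
    )
  }
  structure(out, class = "tvr_profile")
}

#' @export
print.tvr_profile <- function(x, ...) {
  cat("tvr_profile (", if (x$paired) "tumor/control pair" else "single sample",
      "): ", nrow(x$tvr), " hexamers, ", nrow(x$singleton),
      " singleton types\n", sep = "")
  invisible(x)
}
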