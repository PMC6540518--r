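# GC-corrected telomere content. The headline statistic is TRPM: telomeric
# reads per GC-content-matched million reads, i.e. the intratelomeric count
# divided by the number of background reads whose GC content lies in the
# 48-52% window typical of the canonical repeat, times 1e6.

#' Integer GC percentage of sequences
#'
#' `round(100 * (G + C) / (A + C + G + T))` with round-half-up; ambiguous
#' bases are excluded from numerator and denominator. A sequence with no
#' unambiguous base returns `NA`.
#'
#' @param sequences Character vector of DNA sequences.
#' @return Integer vector of GC percentages (0-100), `NA` where undefined.
#' @export
gc_percent <- function(sequences) {
  sequences <- toupper(as.character(sequences))
  gc <- nchar(gsub("[^GC]", "", sequences))
  acgt <- nchar(gsub("[^ACGT]", "", sequences))
  out <- rep(NA_integer_, length(sequences))
  ok <- acgt > 0
  out[ok] <- as.integer(floor(100 * gc[ok] / acgt[ok] + 0.5))
  out
}

#' Accumulate a per-sample GC distribution
#'
#' Tallies reads into integer GC-percent bins 0-100. Reads consisting only
#' of ambiguous bases are counted in the total but fall in no bin.
#'
#' @param sequences Character vector of read sequences.
#' @return A `gc_distribution`: integer vector of 101 bin counts (names
#'   `"0"`..`"100"`) with attribute `total_reads`.
#' @export
accumulate_gc_distribution <- function(sequences) {
  pct <- gc_percent(sequences)
  counts <- tabulate(pct[!is.na(pct)] + 1L, nbins = 101L)
  structure(setNames(as.integer(counts), 0:100),
            total_reads = length(sequences),
            class = "gc_distribution")
}

#' GC-corrected telomere content (TRPM)
#'
#' Divides the intratelomeric read count by the number of reads whose GC
#' content lies in `[low, high]` (inclusive) and scales by 1e6. A zero
#' denominator (e.g. bisulfite data, where cytosine conversion empties the
#' 48-52% window) yields an estimate flagged `undefined` with `trpm = NA`
#' rather than an infinity.
#'
#' @param intratelomeric_count Number of intratelomeric reads.
#' @param gc_dist A [accumulate_gc_distribution()] result for the sample.
#' @param low,high Inclusive GC-percent window bounds (defaults 48 and 52).
#' @return An object of class `telomere_content_estimate` with fields
#'   `intratelomeric_count`, `gc_matched_denominator`, `trpm`,
#'   `total_read_count`, `undefined`.
#' @export
telomere_content <- function(intratelomeric_count, gc_dist,
                             low = 48L, high = 52L) {
  stopifnot(inherits(gc_dist, "gc_distribution"), low <= high)
  denom <- sum(gc_dist[as.character(seq.int(low, high))])
  undefined <- denom == 0
  structure(
    list(intratelomeric_count = as.integer(intratelomeric_count),
         gc_matched_denominator = as.integer(denom),
         trpm = if (undefined) NA_real_ else intratelomeric_count / denom * 1e6,
         total_read_count = attr(gc_dist, "total_reads"),
         undefined = undefined),
    class = "telomere_content_estimate"
  )
}

#' @export
print.telomere_content_estimate <- function(x, ...) {
  cat("telomere content:", x$intratelomeric_count, "intratelomeric /",
      x$gc_matched_denominator, "GC-matched reads =",
      if (x$undefined) "undefined (no GC-matched reads)"
      else sprintf("%.2f TRPM", x$trpm), "\n")
  invisible(x)
}

#' Telomere content without GC correction
#'
#' Intratelomeric reads per million reads of the whole sample.
#'
#' @param intratelomeric_count Number of intratelomeric reads.
#' @param total_reads Total primary reads in the sample (> 0).
#' @return Reads per million (`NA` if `total_reads` is 0).
#' @export
uncorrected_content <- function(intratelomeric_count, total_reads) {
  if (total_reads <= 0) return(NA_real_)
  intratelomeric_count / total_reads * 1e6
}

#' Tumor/control log2 telomere content ratio
#'
#' @param tumor,control [telomere_content_estimate][telomere_content]
#'   objects (or plain positive TRPM values).
#' @return `log2(tumor / control)`, or `NA` if either side is undefined,
#'   zero or negative (never a silent infinity).
#' @export
log2_tc_ratio <- function(tumor, control) {
  val <- function(x) {
    if (inherits(x, "telomere_content_estimate")) {
      if (isTRUE(x$undefined)) return(NA_real_)
      x$trpm
    } else {
      as.numeric(x)
    }
  }
  t <- val(tumor); c <- val(control)
  if (is.na(t) || is.na(c) || t <= 0 || c <= 0) return(NA_real_)
  log2(t / c)
}
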