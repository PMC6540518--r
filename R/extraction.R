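# Telomeric-read extraction: hexamer search patterns, the read-length-scaled
# repeat threshold, and the telomeric / non-telomeric decision.

#' Construct a telomere repeat pattern set
#'
#' Defines the motifs used to decide whether a read is telomeric. By default
#' the four hexamer types t (`TTAGGG`), c (`TCAGGG`), g (`TGAGGG`) and
#' j (`TTGGGG`) are searched, together with their reverse complements, in
#' non-consecutive mode (scattered hits count).
#'
#' @param patterns Character vector of DNA motifs over `ACGT`.
#' @param include_reverse_complement Also search the reverse complement of
#'   every pattern (default `TRUE`). Reads are scanned as stored in the
#'   alignment file, so antisense telomere fragments are caught this way.
#' @param consecutive If `TRUE`, a read's repeat count is the length of the
#'   longest run of *adjacent* pattern hits (mixed patterns allowed) rather
#'   than the total number of scattered hits.
#' @return An object of class `repeat_pattern_set`.
#' @export
repeat_pattern_set <- function(patterns = default_repeat_patterns(),
                               include_reverse_complement = TRUE,
                               consecutive = FALSE) {
  patterns <- toupper(as.character(patterns))
  if (length(patterns) == 0 || any(!nzchar(patterns)) ||
      any(grepl("[^ACGT]", patterns))) {
    stop("patterns must be non-empty strings over {A,C,G,T}", call. = FALSE)
  }
  search <- patterns
  if (include_reverse_complement) {
    search <- unique(c(patterns, reverse_complement(patterns)))
  }
  structure(
    list(patterns = patterns,
         include_reverse_complement = include_reverse_complement,
         consecutive = consecutive,
         search_set = search),
    class = "repeat_pattern_set"
  )
}

#' @export
print.repeat_pattern_set <- function(x, ...) {
  cat("repeat_pattern_set:", paste(x$patterns, collapse = ", "),
      if (x$include_reverse_complement) "(+ reverse complements)" else "",
      if (x$consecutive) "[consecutive mode]" else "[non-consecutive mode]",
      "\n")
  invisible(x)
}

#' Construct an extraction configuration
#'
#' @param pattern_set A [repeat_pattern_set()].
#' @param threshold_override Optional fixed repeat threshold (integer >= 1)
#'   replacing the read-length formula (the `-rt` style parameter).
#' @param threshold_coefficient Repeats required per base of read length
#'   (default 0.06, i.e. 6 repeats for a 100-bp read).
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(pattern_set = repeat_pattern_set(),
                              threshold_override = NULL,
                              threshold_coefficient = 0.06) {
  stopifnot(inherits(pattern_set, "repeat_pattern_set"))
  if (!is.null(threshold_override)) {
    threshold_override <- as.integer(threshold_override)
    if (is.na(threshold_override) || threshold_override < 1L) {
      stop("threshold_override must be an integer >= 1", call. = FALSE)
    }
  }
  stopifnot(is.numeric(threshold_coefficient), threshold_coefficient > 0)
  structure(
    list(pattern_set = pattern_set,
         threshold_override = threshold_override,
         threshold_coefficient = threshold_coefficient),
    class = "extraction_config"
  )
}

#' Restrict an extraction configuration to the canonical t-type repeat
#'
#' Returns a copy of `config` whose search set is `TTAGGG` only (plus its
#' reverse complement if enabled), the equivalent of running with
#' `-r TTAGGG`.
#'
#' @param config An [extraction_config()].
#' @return A modified `extraction_config`.
#' @export
restrict_to_ttype <- function(config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  config$pattern_set <- repeat_pattern_set(
    .TTYPE,
    include_reverse_complement = config$pattern_set$include_reverse_complement,
    consecutive = config$pattern_set$consecutive
  )
  config
}

#' Repeat threshold for a given read length
#'
#' The number of telomere repeats a read must carry to be called telomeric:
#' `floor(read_length * coefficient)`, clamped to a minimum of 1. With the
#' default coefficient of 0.06 a 100-bp read needs 6 repeats.
#'
#' @param read_length Integer vector of read lengths (>= 1).
#' @param coefficient Repeats per base (default 0.06).
#' @return Integer vector of thresholds (>= 1).
#' @export
compute_repeat_threshold <- function(read_length, coefficient = 0.06) {
  read_length <- as.numeric(read_length)
  if (length(read_length) == 0 || anyNA(read_length) || any(read_length < 1)) {
    stop("read_length must be >= 1", call. = FALSE)
  }
  pmax(1L, as.integer(floor(read_length * coefficient)))
}

#' Count telomere-repeat hits in sequences
#'
#' Non-overlapping left-to-right greedy scan over the search set (patterns
#' plus reverse complements when enabled). In non-consecutive mode (default)
#' all hits are summed regardless of spacing; in consecutive mode the value
#' is the length of the longest run of adjacent hits, where runs may mix
#' patterns.
#'
#' @param sequences Character vector of uppercase DNA sequences.
#' @param pattern_set A [repeat_pattern_set()].
#' @return Integer vector of per-sequence repeat counts.
#' @export
count_repeat_hits <- function(sequences, pattern_set = repeat_pattern_set()) {
  stopifnot(inherits(pattern_set, "repeat_pattern_set"))
  sequences <- toupper(as.character(sequences))
  cpp_repeat_hits(sequences, pattern_set$search_set, pattern_set$consecutive)
}

#' Decide which reads are telomeric
#'
#' A read is telomeric when its repeat-hit count reaches the threshold; the
#' threshold is `threshold_override` if set, otherwise derived from each
#' read's own length via [compute_repeat_threshold()].
#'
#' @param sequences Character vector of read sequences (or a read frame from
#'   [stream_reads()], in which case the `seq` column is used).
#' @param config An [extraction_config()].
#' @return Logical vector, one entry per read.
#' @export
is_telomeric <- function(sequences, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  if (is.data.frame(sequences)) sequences <- sequences$seq
  sequences <- toupper(as.character(sequences))
  if (any(!nzchar(sequences))) stop("reads must have a sequence", call. = FALSE)
  hits <- count_repeat_hits(sequences, config$pattern_set)
  thr <- if (!is.null(config$threshold_override)) {
    rep(config$threshold_override, length(sequences))
  } else {
    compute_repeat_threshold(nchar(sequences), config$threshold_coefficient)
  }
  hits >= thr
}
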