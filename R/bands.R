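# Cytogenetic band annotation: parsing the UCSC cytoBand dialect and
# locating read positions on bands. The first and last band of each
# chromosome are flagged "terminal"; they define the subtelomeric regions
# used by read classification.

#' Normalize chromosome names
#'
#' Strips a leading `chr` prefix so `chr1` and `1` compare equal between the
#' alignment file and the band file.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chromosome <- function(x) {
  sub("^chr", "", as.character(x))
}

#' Read a UCSC cytoBand annotation file
#'
#' Expects tab-separated rows `chrom, chromStart, chromEnd, name, gieStain`
#' (coordinates 0-based half-open, as distributed by UCSC; the stain column
#' may be absent). Bands are sorted by start within each chromosome before
#' the first and last band are flagged terminal, so row order in the file
#' does not matter.
#'
#' @param path Path to the band file.
#' @return A `band_map`: a data.frame with columns `chrom` (normalized),
#'   `band`, `start`, `end` (0-based half-open) and `terminal` (logical).
#' @export
read_band_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("band file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad) > 0) {
    stop("malformed band file line ", bad[1], " in ", path,
         " (expected >= 4 tab-separated fields)", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  band <- vapply(fields, `[[`, character(1), 4)
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) {
    stop("malformed band file line ", bad[1], " in ", path,
         " (non-numeric or inverted coordinates)", call. = FALSE)
  }
  df <- data.frame(chrom = normalize_chromosome(chrom),
                   band = band, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # non-overlap within chromosome after sorting
  by_start <- split(seq_len(nrow(df)), df$chrom)
  df$terminal <- FALSE
  for (idx in by_start) {
    if (length(idx) > 1 &&
        any(df$start[idx[-1]] < df$end[idx[-length(idx)]])) {
      stop("overlapping bands on chromosome ", df$chrom[idx[1]], call. = FALSE)
    }
    df$terminal[c(idx[1], idx[length(idx)])] <- TRUE
  }
  class(df) <- c("band_map", "data.frame")
  df
}

#' Build a band map from a data.frame
#'
#' Programmatic alternative to [read_band_file()]; mainly used by the
#' fixture generator and tests.
#'
#' @param chrom,band,start,end Vectors defining one band per element;
#'   coordinates 0-based half-open.
#' @return A `band_map` (see [read_band_file()]).
#' @export
band_map <- function(chrom, band, start, end) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(paste(chrom, start, end, band, "gneg", sep = "\t"), tmp)
  read_band_file(tmp)
}

#' Locate positions on chromosome bands
#'
#' @param chrom Character vector of chromosome names (any `chr` prefix is
#'   ignored).
#' @param pos Integer vector of 1-based positions (the convention used by R
#'   alignment readers).
#' @param map A `band_map`.
#' @return A data.frame with columns `band` and `terminal`; `band` is `NA`
#'   for unknown chromosomes or positions beyond all bands.
#' @export
locate_band <- function(chrom, pos, map) {
  stopifnot(inherits(map, "band_map"))
  chrom <- normalize_chromosome(chrom)
  pos0 <- as.numeric(pos) - 1 # to 0-based
  out_band <- rep(NA_character_, length(chrom))
  out_term <- rep(NA, length(chrom))
  for (cm in unique(chrom[!is.na(chrom)])) {
    rows <- which(map$chrom == cm)
    if (length(rows) == 0) next
    sel <- which(!is.na(chrom) & chrom == cm & !is.na(pos0))
    if (length(sel) == 0) next
    idx <- findInterval(pos0[sel], map$start[rows])
    ok <- idx >= 1 & pos0[sel] < map$end[rows][pmax(idx, 1)]
    hit <- rows[idx[ok]]
    out_band[sel[ok]] <- map$band[hit]
    out_term[sel[ok]] <- map$terminal[hit]
  }
  data.frame(band = out_band, terminal = out_term, stringsAsFactors = FALSE)
}
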