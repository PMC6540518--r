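# BAM input and output. Reads are held as a plain data.frame ("read frame"),
# one row per primary, non-supplementary record, with sequence and Phred+33
# quality strings as stored in the file (no re-orientation by strand flag).

.READ_COLS <- c("qname", "flag", "seq", "qual", "is_mapped", "chrom", "pos",
                "mapq", "is_paired", "is_proper", "mate_mapped",
                "mate_chrom", "mate_pos", "is_duplicate")

#' Read primary records from a BAM file
#'
#' Returns every primary, non-supplementary record exactly once; secondary
#' (flag 0x100) and supplementary (flag 0x800) alignments are excluded from
#' all downstream counting so that each sequenced template contributes one
#' record. Unmapped reads are kept: they are candidate intratelomeric reads.
#'
#' @param path Path to an indexed or fully streamable BAM file.
#' @param exclude_duplicates Drop records with the PCR/optical duplicate
#'   flag (default `FALSE`).
#' @return A data.frame with one row per read: `qname`, `flag`, `seq`,
#'   `qual` (Phred+33), `is_mapped`, `chrom`, `pos` (1-based leftmost),
#'   `mapq`, `is_paired`, `is_proper`, `mate_mapped`, `mate_chrom`,
#'   `mate_pos`, `is_duplicate`. The counts of skipped secondary /
#'   supplementary / duplicate records and the header sequence lengths are
#'   attached as attributes `skipped` and `targets`.
#' @export
stream_reads <- function(path, exclude_duplicates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "mrnm", "mpos",
            "seq", "qual")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  duplicate <- bitwAnd(flag, 1024L) != 0L
  keep <- !secondary & !supplementary
  if (exclude_duplicates) keep <- keep & !duplicate
  skipped <- c(secondary = sum(secondary), supplementary = sum(supplementary),
               duplicate = if (exclude_duplicates) sum(duplicate & !secondary & !supplementary) else 0L)
  flag <- flag[keep]
  df <- data.frame(
    qname = res$qname[keep],
    flag = flag,
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep],
    is_mapped = bitwAnd(flag, 4L) == 0L,
    chrom = as.character(res$rname)[keep],
    pos = res$pos[keep],
    mapq = res$mapq[keep],
    is_paired = bitwAnd(flag, 1L) != 0L,
    is_proper = bitwAnd(flag, 2L) != 0L,
    mate_mapped = bitwAnd(flag, 1L) != 0L & bitwAnd(flag, 8L) == 0L,
    mate_chrom = as.character(res$mrnm)[keep],
    mate_pos = res$mpos[keep],
    is_duplicate = bitwAnd(flag, 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  targets <- tryCatch(Rsamtools::scanBamHeader(path)[[1]]$targets,
                      error = function(e) NULL)
  attr(df, "skipped") <- skipped
  attr(df, "targets") <- targets
  df
}

# Compose a minimal SAM representation of a read frame. Mapped reads get a
# full-length match CIGAR (alignment details beyond position are not used
# downstream); mate fields are emitted when present.
.reads_to_sam <- function(reads, targets) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(targets), "\tLN:", unname(targets)))
  if (nrow(reads) == 0) return(header)
  rname <- ifelse(reads$is_mapped | (!is.na(reads$chrom) & nzchar(reads$chrom)),
                  reads$chrom, "*")
  rname[is.na(rname)] <- "*"
  pos <- ifelse(is.na(reads$pos), ifelse(is.na(reads$mate_pos), 0L, reads$mate_pos),
                reads$pos)
  cigar <- ifelse(reads$is_mapped, paste0(nchar(reads$seq), "M"), "*")
  rnext <- ifelse(is.na(reads$mate_chrom), "*", reads$mate_chrom)
  pnext <- ifelse(is.na(reads$mate_pos), 0L, reads$mate_pos)
  mapq <- ifelse(is.na(reads$mapq), 0L, reads$mapq)
  body <- paste(reads$qname, reads$flag, rname, pos, mapq, cigar,
                rnext, pnext, 0L, reads$seq, reads$qual, sep = "\t")
  c(header, body)
}

#' Write one category of classified reads to a BAM file
#'
#' Emits the given reads as `<category>.bam` (coordinate-sorted, indexed)
#' under `out_dir`, with a header carrying the sequence dictionary of the
#' source file. An empty category yields a valid header-only file.
#'
#' @param reads A read frame (subset of [stream_reads()] output).
#' @param category One of `intratelomeric`, `junction_spanning`,
#'   `subtelomeric`, `intrachromosomal`.
#' @param out_dir Output directory (created if missing).
#' @param targets Named integer vector of reference sequence lengths; taken
#'   from the `targets` attribute of `reads` when omitted.
#' @return Path of the written BAM file, invisibly.
#' @export
write_category_reads <- function(reads, category, out_dir, targets = NULL) {
  category <- match.arg(category, c("intratelomeric", "junction_spanning",
                                    "subtelomeric", "intrachromosomal"))
  if (is.null(targets)) targets <- attr(reads, "targets")
  if (is.null(targets)) stop("no reference sequence dictionary available",
                             call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  sam <- file.path(out_dir, paste0(category, ".sam"))
  writeLines(.reads_to_sam(reads, targets), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, category),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}

#' Write result tables as tab-separated text
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_result_tables <- function(tables, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
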