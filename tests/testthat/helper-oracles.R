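# Independent brute-force oracles for the sequence scanners. These are kept
# deliberately different in mechanism from the package implementation: the
# repeat counter rides on the PCRE regex engine, the hexamer/singleton
# oracles precompute every window and walk logical vectors.

rc <- function(x) reverse_complement(x)

TT3 <- strrep("TTAGGG", 3)
CC3 <- strrep("CCCTAA", 3)

# Non-overlapping leftmost matching of an alternation == greedy scan.
oracle_count_hits <- function(seq, patterns, consecutive = FALSE) {
  if (!consecutive) {
    m <- gregexpr(paste(patterns, collapse = "|"), seq)[[1]]
    return(if (m[1] == -1L) 0L else length(m))
  }
  # longest run of adjacent hits: a greedy (p1|p2|...)+ match consumes a
  # maximal run; count pattern units from the total match length
  m <- gregexpr(paste0("(?:", paste(patterns, collapse = "|"), ")+"), seq)[[1]]
  if (m[1] == -1L) return(0L)
  lens <- attr(m, "match.length")
  # pattern units: all patterns are hexamers in oracle use
  stopifnot(all(nchar(patterns) == 6L))
  max(lens %/% 6L)
}

# Phred+33 quality string -> integer vector
qvec <- function(qual) as.integer(charToRaw(qual)) - 33L

# window-walk oracle for the hexamer scan
oracle_scan_hexamers <- function(seq, qual = NULL, min_qual = 20L) {
  n <- nchar(seq)
  if (n < 6L) return(character(0))
  starts <- seq_len(n - 5L)
  w <- substring(seq, starts, starts + 5L)
  fwd <- grepl("^[ACGT]{3}GGG$", w)
  rev <- !fwd & grepl("^CCC[ACGT]{3}$", w)
  q <- if (is.null(qual)) NULL else qvec(qual)
  hits <- character(0)
  i <- 1L
  while (i <= length(starts)) {
    if (fwd[i] || rev[i]) {
      ok <- is.null(q) || all(q[i:(i + 5L)] >= min_qual)
      if (ok) hits <- c(hits, if (fwd[i]) w[i] else rc(w[i]))
      i <- i + 6L
    } else {
      i <- i + 1L
    }
  }
  hits
}

# every-42-mer oracle for singleton detection
oracle_singletons <- function(seq, qual = NULL, min_qual = 20L) {
  n <- nchar(seq)
  if (n < 42L) return(character(0))
  starts <- seq_len(n - 41L)
  left <- substring(seq, starts, starts + 17L)
  centre <- substring(seq, starts + 18L, starts + 23L)
  right <- substring(seq, starts + 24L, starts + 41L)
  fwd <- left == TT3 & right == TT3 & centre != "TTAGGG" &
    grepl("^[ACGT]{3}GGG$", centre)
  rev <- left == CC3 & right == CC3 & centre != "CCCTAA" &
    grepl("^CCC[ACGT]{3}$", centre)
  if (!is.null(qual)) {
    q <- qvec(qual)
    cq <- vapply(starts, function(s) min(q[(s + 18L):(s + 23L)]), integer(1))
    fwd <- fwd & cq >= min_qual
    rev <- rev & cq >= min_qual
  }
  c(centre[fwd], rc(centre[rev]))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_qual <- function(len, lo = 2L, hi = 40L) {
  rawToChar(as.raw(sample(lo:hi, len, replace = TRUE) + 33L))
}

# a batch of scanner test sequences: uniform random, telomere-like tilings
# with point mutations, and reverse-complemented tilings
random_scanner_sequences <- function(n, max_len = 300L) {
  hex <- c("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG", "TTCGGG", "GGGGGG",
           "ATAGGG", "CCCTAA", "CCCTCA")
  vapply(seq_len(n), function(i) {
    kind <- i %% 3L
    if (kind == 0L) {
      random_dna(sample(6:max_len, 1))
    } else {
      s <- paste(sample(hex, sample(2:(max_len %/% 6L), 1), replace = TRUE),
                 collapse = "")
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        sv <- strsplit(s, "")[[1]]
        pos <- sample(length(sv), min(nmut, length(sv)))
        sv[pos] <- sample(c("A", "C", "G", "T", "N"), length(pos), replace = TRUE)
        s <- paste(sv, collapse = "")
      }
      if (kind == 2L) rc(s) else s
    }
  }, character(1))
}
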