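# Degenerate (IUPAC) consensus scanning, used for CooA-box discovery.
# Implemented as vectorised bitmask matching so that a 1-Mb chromosome scans
# in well under a second: each base is a 5-bit code (A,C,G,T plus a separate
# bit for subject N) and a pattern position matches where the bitwise AND of
# pattern and subject codes is non-zero.  A subject N therefore matches only
# the pattern letter N, never a fixed or partially degenerate letter.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 31L)

# subject alphabet: real bases plus N (own bit, included only in pattern N)
.SUBJ_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

.encode_subject <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- unname(.SUBJ_BITS[ch])
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("invalid subject character '", ch[bad], "' at position ", bad)
  }
  code
}

.encode_pattern <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  code <- unname(.IUPAC_BITS[ch])
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("invalid IUPAC code '", ch[bad], "' at pattern position ", bad)
  }
  code
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# plus-strand scan of an encoded subject; returns start positions
.scan_plus <- function(scode, pcode) {
  n <- length(scode); m <- length(pcode)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & bitwAnd(scode[j:(n - m + j)], pcode[j]) > 0L
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan a nucleotide sequence for a degenerate IUPAC consensus
#'
#' Reports every window matching the pattern, e.g. the CooA-binding consensus
#' \code{TGTCRNNNNNNYGACR}.  Minus-strand hits are reported at the plus-strand
#' coordinate of the window start, with \code{matched} giving the
#' minus-strand (reverse-complement) sequence that conforms to the pattern.
#'
#' @param seq nucleotide string over A, C, G, T, N (case-insensitive).
#' @param pattern IUPAC consensus string.
#' @param strands \code{"both"} (default), \code{"+"} or \code{"-"}.
#' @param contig contig name recorded in the hits (default \code{"seq"}).
#' @return data.frame of class \code{motif_hits} with columns \code{contig},
#'   \code{start} (1-based, plus-strand), \code{strand}, \code{matched}.
#' @examples
#' scan_iupac("TGTCAAAAAAATGACA", "TGTCRNNNNNNYGACR", strands = "+")
#' @export
scan_iupac <- function(seq, pattern, strands = c("both", "+", "-"),
                       contig = "seq") {
  strands <- match.arg(strands)
  pcode <- .encode_pattern(pattern)
  scode <- .encode_subject(seq)
  n <- length(scode); m <- length(pcode)
  seq <- toupper(seq)
  res <- list()
  if (strands %in% c("both", "+")) {
    st <- .scan_plus(scode, pcode)
    if (length(st))
      res[[length(res) + 1]] <- data.frame(
        contig = contig, start = st, strand = "+",
        matched = substring(seq, st, st + m - 1),
        stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "-")) {
    rc <- .revcomp(seq)
    st_rc <- .scan_plus(.encode_subject(rc), pcode)
    if (length(st_rc)) {
      # position i on the reverse complement covers plus-strand
      # [n - m - i + 2, n - i + 1]; report the plus-strand window start
      st <- n - m - st_rc + 2L
      o <- order(st)
      res[[length(res) + 1]] <- data.frame(
        contig = contig, start = st[o], strand = "-",
        matched = substring(rc, st_rc[o], st_rc[o] + m - 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(contig = character(0), start = integer(0),
               strand = character(0), matched = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Expected random hit density of an IUPAC pattern
#'
#' Probability that a random uniform ACGT window matches the pattern on one
#' strand at one position (the product over positions of set-size/4).  For
#' the CooA consensus this is \eqn{(1/4)^7 (1/2)^3 \approx 1/131072} per
#' strand-position.
#'
#' @param pattern IUPAC consensus string.
#' @return Probability per strand-position.
#' @export
iupac_hit_probability <- function(pattern) {
  pcode <- .encode_pattern(pattern)
  sizes <- vapply(pcode, function(b)
    sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), numeric(1))
  prod(sizes / 4)
}

#' Write motif hits as BED
#'
#' Half-open 0-based BED intervals, one per hit.
#' @param hits a \code{motif_hits} data.frame.
#' @param path output file.
#' @param width pattern width (inferred from \code{matched} when absent).
#' @export
write_hits_bed <- function(hits, path, width = NULL) {
  if (is.null(width))
    width <- if (nrow(hits)) nchar(hits$matched[1]) else 0L
  bed <- data.frame(chrom = hits$contig,
                    start = hits$start - 1L,
                    end = hits$start - 1L + width,
                    name = hits$matched,
                    score = 0L,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
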