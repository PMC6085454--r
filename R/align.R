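# Global protein alignment, active-site conservation mapping and
# reciprocal-best-hit strain comparison.  Alignment itself is delegated to
# Biostrings::pairwiseAlignment (Needleman-Wunsch with affine gaps); this
# module adds the identity/coverage conventions and the orthology logic.

.default_scoring <- function() {
  list(substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch with affine gap penalties.  Percent identity is
#' matches / alignment columns after excluding terminal gap runs (end gaps
#' are not penalised as mismatches); coverage is the fraction of each
#' sequence inside the end-gap-trimmed core.
#'
#' @param a,b amino-acid strings.
#' @param scoring list with \code{substitutionMatrix} (name of a matrix
#'   shipped with \pkg{Biostrings}, an actual matrix, or NULL to use
#'   \code{match}/\code{mismatch} unit scores), \code{gapOpening},
#'   \code{gapExtension}, and optionally \code{match}, \code{mismatch}.
#' @return List of class \code{pairwise_alignment}: \code{aligned_a},
#'   \code{aligned_b} (full alignment strings), \code{identity} (percent),
#'   \code{coverage_a}, \code{coverage_b} (percent), \code{score},
#'   \code{columns} (core columns), \code{matches}.
#' @examples
#' pairwise_align("ACD", "AD",
#'   scoring = list(substitutionMatrix = NULL, match = 1, mismatch = -1,
#'                  gapOpening = 0, gapExtension = 1))$identity  # 66.7
#' @export
pairwise_align <- function(a, b, scoring = .default_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  scoring <- modifyList(.default_scoring(), scoring %||% list())
  args <- list(pattern = Biostrings::AAString(a),
               subject = Biostrings::AAString(b),
               type = "global",
               gapOpening = scoring$gapOpening,
               gapExtension = scoring$gapExtension)
  if (!is.null(scoring$substitutionMatrix)) {
    args$substitutionMatrix <- scoring$substitutionMatrix
  } else {
    m <- scoring$match %||% 1
    mm <- scoring$mismatch %||% -1
    alpha <- c(.AA20, "X", "*")
    sm <- matrix(mm, length(alpha), length(alpha),
                 dimnames = list(alpha, alpha))
    diag(sm) <- m
    args$substitutionMatrix <- sm
  }
  al <- do.call(Biostrings::pairwiseAlignment, args)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # core = columns between the last terminal-gap run at each end: from where
  # both sequences have started to where neither has ended yet
  lo <- max(which(pa != "-")[1], which(pb != "-")[1])
  hi <- min(tail(which(pa != "-"), 1), tail(which(pb != "-"), 1))
  if (!is.finite(lo) || !is.finite(hi) || hi < lo)
    stop("degenerate alignment with no aligned columns")
  idx <- lo:hi
  matches <- sum(pa[idx] == pb[idx] & pa[idx] != "-")
  cols <- length(idx)
  list_out <- list(
    aligned_a = paste(pa, collapse = ""),
    aligned_b = paste(pb, collapse = ""),
    identity = 100 * matches / cols,
    coverage_a = 100 * sum(pa[idx] != "-") / nchar(a),
    coverage_b = 100 * sum(pb[idx] != "-") / nchar(b),
    score = Biostrings::score(al),
    columns = cols,
    matches = matches)
  class(list_out) <- "pairwise_alignment"
  list_out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("global alignment: %.1f%% identity over %d columns (cov %.0f%% / %.0f%%)\n",
              x$identity, x$columns, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Check conservation of active-site residues
#'
#' Aligns the query to the reference and maps reference positions through the
#' alignment; a position is conserved iff the aligned query residue equals
#' the expected residue.  Positions falling opposite a query gap are reported
#' as deletions.
#'
#' @param query,reference amino-acid strings.
#' @param reference_positions 1-based positions in the reference.
#' @param expected_residues expected residues (single letters), recycled.
#' @param scoring passed to \code{\link{pairwise_align}}.
#' @param min_identity percent identity floor below which the mapping is
#'   flagged unreliable (default 20, the usual multiheme-cytochrome floor).
#' @return data.frame with \code{position}, \code{expected},
#'   \code{reference_residue}, \code{query_residue} (\code{"-"} for a
#'   deletion), \code{conserved}; attribute \code{reliable} and
#'   \code{identity}.
#' @export
check_active_site <- function(query, reference, reference_positions,
                              expected_residues, scoring = .default_scoring(),
                              min_identity = 20) {
  if (any(reference_positions < 1 | reference_positions > nchar(reference)))
    stop("reference positions outside the reference sequence")
  expected_residues <- rep_len(toupper(expected_residues),
                               length(reference_positions))
  al <- pairwise_align(query, reference, scoring)
  qa <- strsplit(al$aligned_a, "")[[1]]
  ra <- strsplit(al$aligned_b, "")[[1]]
  ref_pos_per_col <- cumsum(ra != "-")
  out <- data.frame(position = reference_positions,
                    expected = expected_residues,
                    reference_residue = NA_character_,
                    query_residue = NA_character_,
                    conserved = NA, stringsAsFactors = FALSE)
  for (k in seq_along(reference_positions)) {
    col <- which(ref_pos_per_col == reference_positions[k] & ra != "-")[1]
    out$reference_residue[k] <- ra[col]
    out$query_residue[k] <- qa[col]
    out$conserved[k] <- identical(qa[col], expected_residues[k])
  }
  attr(out, "identity") <- al$identity
  attr(out, "reliable") <- al$identity >= min_identity
  if (al$identity < min_identity)
    warning("alignment identity ", round(al$identity, 1),
            "% below the reliability floor; mapping flagged unreliable")
  out
}

# cheap shared-k-mer prescreen used to shortlist alignment candidates
.kmer_sets <- function(seqs, k = 5) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Reciprocal-best-hit comparison of two proteomes
#'
#' Best hits are found by global alignment identity (with a shared-k-mer
#' prescreen to shortlist candidates); a pair is accepted when it is the best
#' hit in both directions and passes the identity and coverage thresholds.
#' Everything else is unique to its strain.
#'
#' @param proteome_a,proteome_b named character vectors (or AAStringSets).
#' @param min_identity minimal percent identity (default 40).
#' @param min_coverage minimal percent coverage of both sequences (default 70).
#' @param scoring passed to \code{\link{pairwise_align}}.
#' @param n_candidates alignment shortlist size per protein (default 3).
#' @return List of class \code{strain_comparison}: \code{pairs} (data.frame
#'   \code{id_a}, \code{id_b}, \code{identity}, \code{coverage}),
#'   \code{unique_to_a}, \code{unique_to_b} (character vectors).
#' @export
reciprocal_unique <- function(proteome_a, proteome_b, min_identity = 40,
                              min_coverage = 70, scoring = .default_scoring(),
                              n_candidates = 3) {
  pa <- .as_protein_vector(proteome_a)
  pb <- .as_protein_vector(proteome_b)
  if (!length(pa) || !length(pb)) stop("both proteomes must be non-empty")
  ka <- .kmer_sets(pa); kb <- .kmer_sets(pb)

  best_hit <- function(i, from_k, to_k, from_seqs, to_seqs) {
    shared <- vapply(to_k, function(s) sum(from_k[[i]] %in% s), numeric(1))
    cand <- order(shared, decreasing = TRUE)[seq_len(min(n_candidates,
                                                         length(to_k)))]
    cand <- cand[shared[cand] > 0]
    if (!length(cand)) return(list(j = NA_integer_, identity = 0, coverage = 0))
    best <- list(j = NA_integer_, identity = -1, coverage = 0)
    for (j in cand) {
      al <- pairwise_align(from_seqs[i], to_seqs[j], scoring)
      cov <- min(al$coverage_a, al$coverage_b)
      if (al$identity > best$identity)
        best <- list(j = j, identity = al$identity, coverage = cov)
    }
    best
  }

  fwd <- lapply(seq_along(pa), best_hit, ka, kb, pa, pb)
  rev <- lapply(seq_along(pb), best_hit, kb, ka, pb, pa)

  pairs <- list()
  matched_a <- logical(length(pa)); matched_b <- logical(length(pb))
  for (i in seq_along(pa)) {
    j <- fwd[[i]]$j
    if (is.na(j)) next
    if (!is.na(rev[[j]]$j) && rev[[j]]$j == i &&
        fwd[[i]]$identity >= min_identity &&
        fwd[[i]]$coverage >= min_coverage) {
      pairs[[length(pairs) + 1]] <- data.frame(
        id_a = names(pa)[i], id_b = names(pb)[j],
        identity = fwd[[i]]$identity, coverage = fwd[[i]]$coverage,
        stringsAsFactors = FALSE)
      matched_a[i] <- TRUE; matched_b[j] <- TRUE
    }
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(id_a = character(0), id_b = character(0),
                 identity = numeric(0), coverage = numeric(0)),
    unique_to_a = names(pa)[!matched_a],
    unique_to_b = names(pb)[!matched_b]), class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("strain comparison: %d reciprocal pairs, %d unique to A, %d unique to B\n",
              nrow(x$pairs), length(x$unique_to_a), length(x$unique_to_b)))
  invisible(x)
}
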