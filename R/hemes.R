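# CXXCH heme-binding motif census of c-type cytochromes.
#
# Canonical heme attachment in c-type cytochromes is the CXXCH motif
# (C-x(2)-C-H); rarer variants widen the spacer to 3 or 4 residues.  Counting
# is non-overlapping left to right; at a given start the shortest spacer is
# preferred.  The unknown residue X never matches any motif position.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Count heme-binding motifs in one protein
#'
#' @param protein amino-acid string (20-letter alphabet; X tolerated but
#'   never matches a motif position).
#' @param spacer_policy \code{"strict"} counts only C-x(2)-C-H;
#'   \code{"extended"} additionally allows C-x(3)-C-H and C-x(4)-C-H.
#' @return List of class \code{heme_census_entry}: \code{count},
#'   \code{positions} (motif start positions, strictly increasing,
#'   non-overlapping), \code{length}, \code{policy}.
#' @examples
#' count_heme_motifs("CAACHGGCAACH")$count  # 2
#' @export
count_heme_motifs <- function(protein, spacer_policy = c("strict", "extended")) {
  spacer_policy <- match.arg(spacer_policy)
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(aa)
  spacers <- if (spacer_policy == "strict") 2L else c(2L, 3L, 4L)
  is_res <- aa %in% .AA20          # X (or any junk) never matches
  positions <- integer(0)
  i <- 1L
  while (i <= n - 4L) {
    matched_len <- 0L
    if (aa[i] == "C") {
      for (sp in spacers) {
        j <- i + sp + 1L            # position of the second C
        if (j + 1L > n) next
        if (aa[j] == "C" && aa[j + 1L] == "H" &&
            all(is_res[(i + 1L):(j - 1L)])) {
          matched_len <- sp + 3L
          break                     # shortest spacer wins at this start
        }
      }
    }
    if (matched_len > 0L) {
      positions <- c(positions, i)
      i <- i + matched_len          # non-overlapping: jump past the H
    } else {
      i <- i + 1L
    }
  }
  structure(list(count = length(positions), positions = positions,
                 length = n, policy = spacer_policy),
            class = "heme_census_entry")
}

#' Census of multiheme proteins in a proteome
#'
#' Applies \code{\link{count_heme_motifs}} to every protein and keeps those
#' with at least \code{min_hemes} motifs, sorted by descending count then id.
#'
#' @param proteome named character vector of amino-acid sequences, or a
#'   \code{Biostrings::AAStringSet}.
#' @param min_hemes minimal motif count to report (default 3, the usual
#'   multiheme threshold).
#' @param spacer_policy passed to \code{\link{count_heme_motifs}}.
#' @return data.frame with columns \code{id}, \code{hemes}, \code{length}.
#' @export
find_multihemes <- function(proteome, min_hemes = 3,
                            spacer_policy = c("strict", "extended")) {
  spacer_policy <- match.arg(spacer_policy)
  seqs <- .as_protein_vector(proteome)
  counts <- vapply(seqs, function(s)
    count_heme_motifs(s, spacer_policy)$count, integer(1))
  lens <- nchar(seqs)
  df <- data.frame(id = names(seqs), hemes = counts, length = lens,
                   stringsAsFactors = FALSE)
  df <- df[df$hemes >= min_hemes, , drop = FALSE]
  df <- df[order(-df$hemes, df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.as_protein_vector <- function(proteome) {
  if (methods::is(proteome, "AAStringSet")) {
    seqs <- as.character(proteome)
  } else {
    seqs <- as.character(proteome)
    names(seqs) <- names(proteome)
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("protein_", seq_along(seqs))
  seqs
}

#' Write a heme census as TSV
#' @param census data.frame from \code{\link{find_multihemes}}.
#' @param path output file.
#' @export
write_census_tsv <- function(census, path) {
  write.table(census, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
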