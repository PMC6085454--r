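# Operon inference from intergenic distance and assignment of regulatory
# sites (e.g. CooA boxes) to the operons they plausibly control.

#' Construct a gene feature table
#'
#' @param id locus tags (unique).
#' @param contig contig ids.
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param type feature type, default \code{"CDS"}.
#' @param product free-text product description.
#' @return data.frame of class \code{gene_features}.
#' @export
gene_features <- function(id, contig, start, end, strand,
                          type = "CDS", product = "") {
  if (anyDuplicated(id)) stop("duplicate feature ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(start < 1) || any(end < start))
    stop("coordinates must satisfy 1 <= start <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(id = id, contig = contig, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   type = type, product = product, stringsAsFactors = FALSE)
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Group genes into operons by intergenic distance
#'
#' Maximal runs of same-strand, same-contig genes whose successive intergenic
#' gaps do not exceed \code{max_gap} are called one operon; genes separated by
#' larger gaps (the 70-100 bp spaces typical of genes that sit alone in their
#' operons) or by a strand flip are split.  Singletons form one-gene operons.
#'
#' @param features a \code{gene_features} data.frame (CDS rows are used).
#' @param max_gap maximal intergenic gap in bp for co-membership (default
#'   60, just below the 70-100 bp "alone in its operon" band).
#' @return data.frame with one row per operon: \code{operon}, \code{contig},
#'   \code{strand}, \code{start}, \code{end}, \code{n_genes}, \code{genes}
#'   (comma-separated ids in coordinate order).
#' @export
infer_operons <- function(features, max_gap = 60) {
  f <- as.data.frame(features)
  f <- f[f$type == "CDS", , drop = FALSE]
  if (anyDuplicated(f$id)) stop("duplicate feature ids")
  f <- f[order(f$contig, f$start, f$end), , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(operon = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  new_block <- c(TRUE, f$contig[-1] != f$contig[-nrow(f)] |
                       f$strand[-1] != f$strand[-nrow(f)] |
                       (f$start[-1] - f$end[-nrow(f)] - 1L) > max_gap)
  block <- cumsum(new_block)
  out <- do.call(rbind, lapply(split(seq_len(nrow(f)), block), function(i) {
    data.frame(contig = f$contig[i[1]], strand = f$strand[i[1]],
               start = min(f$start[i]), end = max(f$end[i]),
               n_genes = length(i),
               genes = paste(f$id[i], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$operon <- sprintf("operon_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("operon", "contig", "strand", "start", "end", "n_genes", "genes")]
}

#' Assign motif hits to the operons they lie upstream of
#'
#' A hit maps to an operon when its window lies fully in the intergenic
#' region within \code{upstream_window} bp upstream of the operon's 5' gene
#' start (on the operon's strand).  Hits overlapping any coding feature are
#' left unmapped.  A hit maps to at most one operon: the nearest wins, ties
#' broken by strand agreement with the hit, then by operon coordinate.
#'
#' @param hits \code{motif_hits} data.frame (from \code{\link{scan_iupac}}).
#' @param operons operon table from \code{\link{infer_operons}}.
#' @param features the \code{gene_features} used to build the operons (for
#'   the coding-region exclusion); optional.
#' @param upstream_window bp upstream of the operon start considered
#'   promoter-proximal (default 300).
#' @param width motif width; inferred from \code{matched} when NULL.
#' @return The \code{hits} data.frame with added columns \code{operon}
#'   (NA when unmapped) and \code{distance} (bp from hit to operon 5' start).
#' @export
assign_sites_to_operons <- function(hits, operons, features = NULL,
                                    upstream_window = 300, width = NULL) {
  hits <- as.data.frame(hits)
  if (is.null(width))
    width <- if (nrow(hits)) nchar(hits$matched[1]) else 0L
  hits$operon <- NA_character_
  hits$distance <- NA_integer_
  if (!nrow(hits)) return(hits)
  feats <- if (!is.null(features)) as.data.frame(features) else NULL
  for (i in seq_len(nrow(hits))) {
    h0 <- hits$start[i]; h1 <- h0 + width - 1L
    if (!is.null(feats)) {
      cover <- feats$contig == hits$contig[i] &
               feats$start <= h1 & feats$end >= h0
      if (any(cover)) next   # inside a coding region
    }
    cand <- operons[operons$contig == hits$contig[i], , drop = FALSE]
    if (!nrow(cand)) next
    # distance from the hit to the operon's 5' start, on the operon strand
    d <- ifelse(cand$strand == "+", cand$start - h1, h0 - cand$end)
    keep <- d > 0 & d <= upstream_window
    cand <- cand[keep, , drop = FALSE]; d <- d[keep]
    if (!nrow(cand)) next
    pref <- order(d, cand$strand != hits$strand[i], cand$start)
    hits$operon[i] <- cand$operon[pref[1]]
    hits$distance[i] <- d[pref[1]]
  }
  hits
}
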