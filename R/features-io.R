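# Readers and writers for the genome-screening surface: FASTA (via
# Biostrings), GFF3 and a minimal tab-separated feature table.

#' Read a nucleotide FASTA as plain strings
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a protein FASTA as plain strings
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param type \code{"dna"} or \code{"protein"}.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3 or a tab-separated feature table
#'
#' The TSV layout is \code{id, contig, start, end, strand, type, product}
#' with a header line.  For GFF3, CDS/RNA records are taken, the id from the
#' \code{ID} or \code{locus_tag} attribute and the product from
#' \code{product}.
#'
#' @param path input file; format guessed from the extension (\code{.gff},
#'   \code{.gff3} vs anything else) unless given.
#' @param format \code{"auto"}, \code{"gff3"} or \code{"tsv"}.
#' @return A \code{\link{gene_features}} data.frame.
#' @export
read_features <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
    return(gene_features(df$id, df$contig, df$start, df$end, df$strand,
                         df$type, df$product))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9]
  kind <- vapply(f, `[[`, character(1), 3)
  keep <- kind %in% c("CDS", "rRNA", "tRNA", "ncRNA", "RNA")
  f <- f[keep]; kind <- kind[keep]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) >= 3) m[3] else NA_character_
  }
  ids <- vapply(f, function(x) {
    v <- attr_get(x[9], "locus_tag")
    if (is.na(v)) v <- attr_get(x[9], "ID")
    v %||% NA_character_
  }, character(1))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  gene_features(
    id = ids,
    contig = vapply(f, `[[`, character(1), 1),
    start = as.integer(vapply(f, `[[`, character(1), 4)),
    end = as.integer(vapply(f, `[[`, character(1), 5)),
    strand = vapply(f, `[[`, character(1), 7),
    type = ifelse(kind == "CDS", "CDS", "RNA"),
    product = vapply(f, function(x) {
      p <- attr_get(x[9], "product")
      if (is.na(p)) "" else p
    }, character(1)))
}

#' Write gene features
#'
#' @param features a \code{gene_features} data.frame.
#' @param path output file.
#' @param format \code{"tsv"} (default) or \code{"gff3"}.
#' @param source GFF3 source column (default \code{"ferroco"}).
#' @export
write_features <- function(features, path, format = c("tsv", "gff3"),
                           source = "ferroco") {
  format <- match.arg(format)
  f <- as.data.frame(features)
  if (format == "tsv") {
    write.table(f[, c("id", "contig", "start", "end", "strand", "type",
                      "product")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s;product=%s",
                       f$contig, source, f$type, f$start, f$end, f$strand,
                       f$id, f$id, f$product))
    writeLines(lines, path)
  }
  invisible(path)
}
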