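# Synthetic annotated strain pair with planted determinants: a coo gene
# cluster (cooA | cooSC | cooMKLXUHhypAcooFSC) with CooA boxes upstream of
# the two CODH-containing operons, a set of shared multiheme c-type
# cytochromes, and one extra 17-heme cytochrome present only in strain B.
# The generator's bookkeeping (returned in $truth) is the ground truth that
# the screening functions are expected to recover.

.COO_CLUSTER <- list(
  # operon 1: the regulator, alone
  list(genes = c(cooA = "CO-sensing transcriptional regulator CooA"),
       gaps = integer(0)),
  # operon 2: the 'enigmatic' upstream CODH operon
  list(genes = c(cooS1 = "anaerobic CO dehydrogenase CooS",
                 cooC1 = "CODH nickel-insertion accessory protein CooC"),
       gaps = 20L),
  # operon 3: the CODH-ECH energy-converting cluster
  list(genes = c(cooM = "energy-converting hydrogenase subunit CooM",
                 cooK = "energy-converting hydrogenase subunit CooK",
                 cooL = "energy-converting hydrogenase subunit CooL",
                 cooX = "energy-converting hydrogenase subunit CooX",
                 cooU = "energy-converting hydrogenase subunit CooU",
                 cooH = "energy-converting hydrogenase catalytic subunit CooH",
                 hypA = "hydrogenase maturation protein HypA",
                 cooF = "ferredoxin-like electron transfer protein CooF",
                 cooS2 = "anaerobic CO dehydrogenase CooS",
                 cooC2 = "CODH nickel-insertion accessory protein CooC"),
       gaps = c(15L, 25L, 18L, 30L, 22L, 35L, 20L, 28L, 24L)))

.CODONS <- local({
  # standard genetic code, stop codons excluded
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"),
    "")[[1]]
  split(codons[aa != "*"], aa[aa != "*"])
})

.random_protein <- function(n, rng_exclude = character(0)) {
  pool <- setdiff(.AA20, rng_exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# remove accidental heme motifs so planted counts are exact ground truth
.strip_heme_motifs <- function(protein, keep_positions = integer(0)) {
  repeat {
    cen <- count_heme_motifs(protein, "extended")
    stray <- setdiff(cen$positions, keep_positions)
    if (!length(stray)) return(protein)
    substr(protein, stray[1], stray[1]) <- "A"
  }
}

# a multiheme cytochrome with exactly `hemes` CXXCH motifs
.multiheme_protein <- function(hemes, spacer = 25) {
  parts <- character(0)
  positions <- integer(0)
  pos <- 0L
  lead <- .random_protein(30, rng_exclude = c("C"))
  parts <- lead; pos <- nchar(lead)
  for (k in seq_len(hemes)) {
    motif <- paste0("C", .random_protein(2, rng_exclude = c("C", "H")), "CH")
    positions <- c(positions, pos + 1L)
    gap <- .random_protein(spacer, rng_exclude = c("C"))
    parts <- c(parts, motif, gap)
    pos <- pos + 5L + spacer
  }
  seq <- paste(parts, collapse = "")
  seq <- .strip_heme_motifs(seq, keep_positions = positions)
  list(seq = seq, positions = positions)
}

.back_translate <- function(protein, gc_weight = 1) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) {
    cods <- .CODONS[[a]]
    w <- gc_weight^vapply(cods, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
    sample(cods, 1, prob = w)
  }, character(1)), collapse = "")
}

.random_dna <- function(n, gc = 0.49) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# intergenic spacer guaranteed free of consensus matches on both strands
.clean_spacer <- function(n, consensus, gc = 0.49) {
  repeat {
    s <- .random_dna(n, gc)
    if (!nrow(scan_iupac(s, consensus)) ) return(s)
  }
}

# one concrete instance of the degenerate consensus
.sample_site <- function(consensus) {
  bits <- .encode_pattern(consensus)
  bases <- c("A", "C", "G", "T")
  paste(vapply(bits, function(b) {
    sample(bases[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L], 1)
  }, character(1)), collapse = "")
}

#' Specification for a synthetic strain pair
#'
#' @param n_background number of background CDS per strain (default 40).
#' @param gc target GC fraction (default 0.49).
#' @param shared_multiheme_hemes heme counts of the multiheme cytochromes
#'   present in both strains (default thirty proteins with 3-15 hemes,
#'   including one 15-heme and one 6-heme protein).
#' @param unique_multiheme_hemes heme count of the strain-B-exclusive
#'   cytochrome (default 17); set to 0 to disable it.
#' @param mutation_rate per-residue substitution rate applied to strain B
#'   proteins (default 0.005, keeping pairs at ~99-100\% identity).
#' @param consensus regulator-box consensus planted upstream of the two CODH
#'   operons (default the CooA box \code{TGTCRNNNNNNYGACR}).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return List of class \code{strain_pair_spec}.
#' @export
strain_pair_spec <- function(n_background = 40, gc = 0.49,
                             shared_multiheme_hemes = c(15, 6, 3:15,
                                                        rep(4:8, 3)),
                             unique_multiheme_hemes = 17,
                             mutation_rate = 0.005,
                             consensus = "TGTCRNNNNNNYGACR",
                             seed = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  structure(list(n_background = n_background, gc = gc,
                 shared_multiheme_hemes = shared_multiheme_hemes,
                 unique_multiheme_hemes = unique_multiheme_hemes,
                 mutation_rate = mutation_rate, consensus = consensus,
                 seed = as.integer(seed)),
            class = "strain_pair_spec")
}

# substitute non-C/H residues so planted motifs and counts are untouched
.mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  ok <- !(aa %in% c("C", "H"))
  idx <- which(ok & runif(length(aa)) < rate)
  if (length(idx)) {
    pool <- setdiff(.AA20, c("C", "H"))
    aa[idx] <- sample(pool, length(idx), replace = TRUE)
  }
  paste(aa, collapse = "")
}

#' Generate a synthetic annotated strain pair
#'
#' Builds two strains of one in-silico species: identical planted coo cluster
#' and regulator boxes, near-identical shared proteomes (strain B proteins
#' carry a low substitution load), and one extra multiheme cytochrome in
#' strain B only.  Every planted feature is recoverable with the package's
#' screening defaults.
#'
#' @param spec a \code{\link{strain_pair_spec}}.
#' @return List of class \code{strain_pair} with elements \code{strain_a},
#'   \code{strain_b} (each: \code{genome} string, \code{features}
#'   data.frame, \code{proteome} named vector) and \code{truth}
#'   (planted-site coordinates, coo operon gene ids, multiheme ids and heme
#'   counts, id of the strain-B-exclusive cytochrome).
#' @export
generate_strain_pair <- function(spec = strain_pair_spec()) {
  set.seed(spec$seed)
  consensus <- spec$consensus

  # --- proteins ------------------------------------------------------------
  coo_names <- unlist(lapply(.COO_CLUSTER, function(o) names(o$genes)))
  coo_prods <- unlist(lapply(.COO_CLUSTER, function(o) unname(o$genes)))
  coo_prot <- setNames(vapply(coo_names, function(nm)
    .strip_heme_motifs(.random_protein(sample(180:420, 1))), character(1)),
    coo_names)
  mh <- lapply(spec$shared_multiheme_hemes, .multiheme_protein)
  bg <- vapply(seq_len(spec$n_background), function(i)
    .strip_heme_motifs(.random_protein(sample(120:350, 1))), character(1))
  uniq <- if (spec$unique_multiheme_hemes > 0)
    .multiheme_protein(spec$unique_multiheme_hemes) else NULL

  # --- assemble strain A ---------------------------------------------------
  genes <- list()   # list of (name, product, protein, class)
  add_gene <- function(genes, name, product, protein, class)
    c(genes, list(list(name = name, product = product, protein = protein,
                       class = class)))
  nbg1 <- floor(spec$n_background / 2)
  for (i in seq_len(nbg1))
    genes <- add_gene(genes, paste0("bg_", i), "hypothetical protein",
                      bg[i], "background")
  for (i in seq_along(coo_names))
    genes <- add_gene(genes, coo_names[i], coo_prods[i], coo_prot[i], "coo")
  for (i in seq_along(mh))
    genes <- add_gene(genes, paste0("mhc_", i),
                      sprintf("multiheme c-type cytochrome (%d hemes)",
                              spec$shared_multiheme_hemes[i]),
                      mh[[i]]$seq, "multiheme")
  for (i in (nbg1 + 1):spec$n_background)
    genes <- add_gene(genes, paste0("bg_", i), "hypothetical protein",
                      bg[i], "background")

  build_strain <- function(genes, prefix, contig, extra = NULL,
                           mutate = FALSE) {
    # strain B: mutate shared proteins (motif-preserving), insert extra gene
    glist <- genes
    if (mutate && spec$mutation_rate > 0)
      glist <- lapply(glist, function(g) {
        g$protein <- .mutate_protein(g$protein, spec$mutation_rate)
        g
      })
    if (!is.null(extra)) {
      at <- length(glist) - 3L   # among the trailing background genes
      glist <- append(glist, list(extra), after = at)
    }
    segs <- character(0)
    pos <- 0L
    rows <- list()
    sites <- integer(0)
    idx <- 0L
    for (g in glist) {
      idx <- idx + 1L
      # spacer ahead of this gene
      gap_len <- 150L
      in_operon_gap <- NA_integer_
      # determine structured gaps inside the coo cluster
      if (g$name %in% c("cooC1")) in_operon_gap <- 20L
      if (g$name %in% c("cooK", "cooL", "cooX", "cooU", "cooH", "hypA",
                        "cooF", "cooS2", "cooC2")) {
        op3 <- .COO_CLUSTER[[3]]
        k <- match(g$name, names(op3$genes))
        in_operon_gap <- op3$gaps[k - 1]
      }
      if (!is.na(in_operon_gap)) {
        segs <- c(segs, .clean_spacer(in_operon_gap, consensus, spec$gc))
        pos <- pos + in_operon_gap
      } else if (g$name %in% c("cooS1", "cooM")) {
        # promoter region with a planted regulator box ~60 bp upstream
        up <- .clean_spacer(74, consensus, spec$gc)
        site <- .sample_site(consensus)
        down <- .clean_spacer(60, consensus, spec$gc)
        sites <- c(sites, pos + nchar(up) + 1L)
        segs <- c(segs, up, site, down)
        pos <- pos + nchar(up) + nchar(site) + nchar(down)
      } else {
        segs <- c(segs, .clean_spacer(gap_len, consensus, spec$gc))
        pos <- pos + gap_len
      }
      cds <- paste0("ATG", .back_translate(g$protein,
                                           gc_weight = spec$gc / (1 - spec$gc) * 1.04),
                    "TAA")
      start <- pos + 1L
      pos <- pos + nchar(cds)
      segs <- c(segs, cds)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%s_%04d", prefix, idx), name = g$name,
        start = start, end = pos, product = g$product, class = g$class,
        stringsAsFactors = FALSE)
    }
    segs <- c(segs, .clean_spacer(200, consensus, spec$gc))
    genome <- paste(segs, collapse = "")
    rows <- do.call(rbind, rows)
    feats <- gene_features(rows$id, contig, rows$start, rows$end,
                           strand = "+", type = "CDS", product = rows$product)
    proteome <- setNames(vapply(glist, `[[`, character(1), "protein"),
                         rows$id)
    list(genome = genome, features = feats, proteome = proteome,
         map = rows, sites = sites)
  }

  a <- build_strain(genes, "SYA", "chrA")
  extra <- if (!is.null(uniq))
    list(name = "mhcX", protein = uniq$seq,
         product = sprintf("multiheme c-type cytochrome (%d hemes)",
                           spec$unique_multiheme_hemes),
         class = "unique_multiheme") else NULL
  b <- build_strain(genes, "SYB", "chrB", extra = extra, mutate = TRUE)

  truth <- list(
    consensus = consensus,
    sites_a = a$sites, sites_b = b$sites,
    coo_genes_a = a$map$id[a$map$class == "coo"],
    coo_genes_b = b$map$id[b$map$class == "coo"],
    coo_operons = list(c("cooA"), c("cooS1", "cooC1"),
                       names(.COO_CLUSTER[[3]]$genes)),
    multiheme_a = setNames(spec$shared_multiheme_hemes,
                           a$map$id[a$map$class == "multiheme"]),
    multiheme_b = setNames(spec$shared_multiheme_hemes,
                           b$map$id[b$map$class == "multiheme"]),
    unique_b = if (!is.null(extra)) b$map$id[b$map$class == "unique_multiheme"]
               else character(0),
    unique_hemes = spec$unique_multiheme_hemes)

  structure(list(
    strain_a = list(genome = a$genome, features = a$features,
                    proteome = a$proteome),
    strain_b = list(genome = b$genome, features = b$features,
                    proteome = b$proteome),
    truth = truth), class = "strain_pair")
}

#' Write a strain pair to disk
#'
#' Writes, per strain, \code{<prefix>_genome.fasta},
#' \code{<prefix>_features.tsv} and \code{<prefix>_proteome.fasta}.
#'
#' @param pair a \code{strain_pair}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_strain_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("strain_a", "strain_b")) {
    s <- pair[[nm]]
    contig <- s$features$contig[1]
    p1 <- file.path(dir, paste0(nm, "_genome.fasta"))
    write_fasta(setNames(s$genome, contig), p1, "dna")
    p2 <- file.path(dir, paste0(nm, "_features.tsv"))
    write_features(s$features, p2, "tsv")
    p3 <- file.path(dir, paste0(nm, "_proteome.fasta"))
    write_fasta(s$proteome, p3, "protein")
    paths <- c(paths, p1, p2, p3)
  }
  invisible(paths)
}
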