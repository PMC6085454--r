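Package: ferroco
Title: Electron Balance, Moessbauer Doublet Fitting and Genome Screening for
    Carboxydotrophic Iron(III) Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing anaerobic cultures that couple hydrogenogenic
    carbon monoxide oxidation to dissimilatory Fe(III)-mineral reduction.
    Composes balanced overall (brutto) catabolic equations from phase-wise
    metabolite changes and partitions consumed CO between Fe(III) reduction
    and H2 production; simulates and fits room-temperature paramagnetic
    Moessbauer spectra as superpositions of symmetric quadrupole doublets and
    quantifies Fe site fractions from subspectrum areas; screens annotated
    genomes for carboxydotrophy and iron-reduction determinants (degenerate
    CooA-box consensus sites, CXXCH heme-motif census of multiheme c-type
    cytochromes, intergenic-distance operon inference, reciprocal-best-hit
    strain comparison, fragment-based average nucleotide identity); and
    generates fully synthetic culture time series, annotated strain pairs and
    spectral presets so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
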