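Package: rgenevol
Title: Comparative and Population Genomics of NBS Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying the evolution of
    nucleotide-binding-site (NBS) plant disease-resistance (R) genes across
    related genomes and within a resequenced population. Classifies R genes
    from protein domain annotations and labels domain-order subgroups,
    detects tandem-duplication arrays under a gene-gap rule, finds syntenic
    orthologs by flanking-gene best-hit ratios and groups them into
    cross-genome families, computes Nei-Gojobori Ka/Ks on codon alignments,
    builds neighbor-joining trees with bootstrap support from concatenated
    synonymous loci, and derives per-gene nucleotide diversity (pi),
    Tajima's D and functional-variant burdens from VCF population data.
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    igraph,
    ape,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
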