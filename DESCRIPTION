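Package: autozygy
Title: Runs of Homozygosity, Pedigree Gene-Dropping and Recessive Variant
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify inbreeding from a single diploid genome and to
    infer the pedigree behind it. Computes windowed heterozygosity densities
    with segmental-duplication masking, calls runs of homozygosity (ROH) from
    the window track and derives the F_ROH inbreeding coefficient, simulates
    identity-by-descent segments by gene dropping through ten inbred pedigree
    models with sex-specific recombination rates, ranks pedigree models by a
    multinomial likelihood on binned segment lengths, and prioritizes
    homozygous non-synonymous candidate-gene variants that are private with
    respect to a comparison panel. Includes a synthetic-data generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
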