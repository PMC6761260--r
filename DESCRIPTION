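Package: mircomp
Title: Comparative miRNA Genomics: Families, Conservation, Clusters,
    Targets and Expression Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of microRNA repertoires across a
    species phylogeny: grouping mature miRNAs into families and isomiR genes
    by sequence similarity and shared 2-8 seed, classifying phylogenetic
    conservation and inferring gain/loss histories by Dollo parsimony,
    detecting physical pre-miRNA clusters in genomic coordinates, predicting
    canonical seed-match target sites (6mer, 7mer-A1, 7mer-m8, 8mer) on
    aligned 3' UTRs with site-conservation calls and spatial-distribution
    statistics, correlating miRNA and mRNA expression across individuals and
    across species via phylogenetically independent contrasts, and scoring
    species-specific target "emergence rates" with GO enrichment. Includes a
    synthetic-study generator with planted ground truth so every stage of the
    workflow can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
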