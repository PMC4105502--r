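Package: gbskit
Title: Genotyping-by-Sequencing Discovery Workflow for Inbred Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable genotyping-by-sequencing (GBS) discovery
    workflow for inbred (largely selfing) crop species, including polyploids
    such as cultivated oat. Provides reference-free SNP calling from tag
    presence/absence with a population-level Fisher exact filter, per-locus
    completeness/MAF/heterozygosity filtering, parental phase assignment with
    recursive correction, consensus-map saturation by recombination-fraction
    interpolation, structure- and kinship-corrected linkage disequilibrium
    with Sved and Hill-Weir decay-model fitting, LD-corrected principal
    component analysis, germplasm-identity diagnostics based on allele-matching
    dissimilarity and UPGMA clustering, and a synthetic-data generator that
    emulates recombinant inbred line populations, diversity panels and the
    per-sample sequencing-depth model so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
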