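Package: islandmouse
Title: Molecular Dating, Introgression and Morphometrics for Island House
    Mouse Colonizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses for characterizing recently colonized island house
    mouse (Mus musculus) populations: calling new mitochondrial mutations
    against a cohort consensus and dating the colonization with a
    mutation-frequency molecular clock, collapsing D-loop haplotypes and
    building median-joining networks, segmenting local-ancestry
    probability tracks into introgressed blocks with copy-number profiles
    and genome fractions, microsatellite diversity summaries (observed and
    expected heterozygosity, mean alleles per locus), and landmark-based
    geometric morphometrics (centroid size, generalized Procrustes
    superimposition, shape PCA). A synthetic-data module generates every
    input type with known ground truth so each stage can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
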