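Package: apomixkit
Title: Population-Genomic Analyses of Apomixis in Citrinae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the population-genomic and simulation
    analyses used to study the evolution of apomixis (nucellar embryony) in
    Citrinae: site-pattern introgression statistics (Patterson's D, f_d,
    f4-ratio, f-branch) with block-jackknife significance, window divergence
    (Dxy), per-individual deleterious SNP/SV load under additive and
    recessive models, hemizygous-gene fractions, hypothetical-cross exposure
    of recessive load, bulked-segregant QTL mapping (delta SNP-index, G'),
    a forward Wright-Fisher simulator of deleterious-load dynamics under
    sexual, apomictic and facultative reproduction, and MITE
    promoter-insertion genotyping with TSD-aware haplotype decomposition.
    A synthetic-data generator with recorded ground truth produces every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    vcfR,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
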