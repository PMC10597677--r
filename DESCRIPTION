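Package: pufascreen
Title: Screening Assemblies for Bdelloid Rotifer LC-PUFA Biosynthesis Genes
    and Genetic Contamination
Version: 0.9.0
Authors@R:
    person("Pollon", "Screenworks", email = "maintainer@pufascreen.dev",
           role = c("aut", "cre"))
Description: Tools to detect bdelloid-rotifer genetic material in crustacean
    transcriptome assemblies and to characterize the rotifer long-chain
    polyunsaturated fatty acid (LC-PUFA) biosynthesis gene complement.
    Includes diagnostic-motif classification of desaturase and elongase open
    reading frames (histidine boxes, HPGG heme-binding motif, elongase
    domains), cox1 DNA-barcode contamination calling against a reference
    panel with a percent-identity positivity rule, global pairwise identity
    matrices for homologous gene sets, exon-intron structure analysis with
    introner-like element classification (canonical splice sites,
    polypyrimidine tracts), yeast-assay conversion arithmetic from GC-FID
    peak areas, and a desaturation-elongation reaction-network model with
    reachability inference for enzyme activity sets. A seeded synthetic-data
    generator produces truth-annotated host and contaminated samples and
    annotated genomic scaffolds for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
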