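Package: mouth2gut
Title: Strain-Resolved Tracking of Oral-to-Gut Microbial Transmission from
    Multi-Omic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and follows microbial strain-variants from the oral
    cavity to the gut by integrating metagenomic (MG), metatranscriptomic (MT)
    and metaproteomic (MP) data. Calls substitution variants on gut contigs
    from strand-resolved pileups, applies cross-site and cross-omic support
    criteria (positive allelic depths on both strands in oral and gut DNA;
    alternative-allele genotypes in oral DNA and gut RNA), annotates variant
    effects against gene models, builds variant-augmented protein search
    databases with tryptic variant-peptide matching for MP support, aggregates
    transfer per taxon, and provides the accompanying count-matrix statistics
    (prevalence filtering with per-individual visit medians, richness and
    Simpson diversity, Bray-Curtis dissimilarity, Mann-Whitney tests, Spearman
    correlation networks with Benjamini-Hochberg correction). A synthetic
    family-structured cohort generator with planted, partially transmitted
    variants makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'io.R'
    'pileup.R'
    'proteogenomics.R'
    'tracking.R'
    'stats.R'
    'synthetic.R'
    'pipeline.R'
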