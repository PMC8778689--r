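Package: viromeScreen
Title: Strand-Ratio Virome Triage for Yeast RNA-Seq Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects replicating viral RNAs (including ORFan segments) among
    assembled RNA-seq contigs of wine yeasts via a strand-specific
    replication-intermediate signature, annotates viral ORFs under standard and
    mold-mitochondrial genetic codes (RdRp motifs, -1 ribosomal slippage
    overlaps, killer preprotoxin features, premature stops), computes
    p-distance percent-identity matrices from global alignments, and classifies
    candidate viruses against ICTV demarcation thresholds. Includes a seeded
    synthetic virome generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Virome, Metagenomics, SequenceMatching, Alignment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
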