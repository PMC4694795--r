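Package: trfspace
Title: Deduction and Profiling of tRNA-Derived Fragments by Exact
    Exclusive Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deducing transfer-RNA-derived fragments (tRFs) from
    short RNA-seq data. Builds a CCA-aware reference tRNA space from a
    genome and a gtRNAdb-style annotation (nuclear and mitochondrial tRNAs
    plus exact nuclear lookalikes of mitochondrial tRNAs), enumerates every
    candidate fragment of a mature tRNA and keeps only sequences whose
    exact genomic occurrences all fall inside tRNA space, classifies
    fragments into 5'-tRFs, internal i-tRFs and CCA-ending 3'-tRFs, and
    emits augmented provenance labels. Profiles collapsed read sets into
    per-fragment count tables with single counting of multi-locus
    sequences, assembles cohort expression matrices with read-support
    filtering, depth, laboratory and rank normalization, and produces
    length distributions, nuclear/mitochondrial decompositions,
    per-anticodon Pearson correlation matrices and Mann-Whitney group
    comparisons. A synthetic-data module generates genomes with planted
    tRNA loci, decoys and reads with a full ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
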