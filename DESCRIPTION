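Package: ppomir
Title: Gene Family Evolution and Target-Directed miRNA Discovery for Plant
    Polyphenol Oxidases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a duplicated plant gene family (exemplified by the
    Salvia miltiorrhiza polyphenol oxidases) and discovers small RNAs that
    target it. Provides sequence cataloguing (ORF translation, molecular
    weight, isoelectric point, conserved-motif scanning, intron phases),
    CIP/CALP paralog grouping, Nei-Gojobori (1986) Ka/Ks with domain slices,
    neighbor-joining trees with bootstrap support, RPKM filtering with
    Fisher-exact differential expression and 2^-ddCt quantification, and a
    target-driven miRNA discovery stage: expectation-scored complementarity
    scanning, genome matching, hairpin extraction and annotation against
    structural miRNA criteria, and degradome cleavage validation. Seeded
    generators produce synthetic inputs with the statistical structure each
    stage assumes, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    ape,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
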