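Package: agdsx
Title: Splice-Site SNP Screening of the Anopheles gambiae doublesex Gene
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens the dual-isoform, reverse-strand doublesex (dsx) gene of
    Anopheles gambiae (AGAP004050) for single-nucleotide polymorphisms in
    donor and acceptor splice-site windows. Represents multi-isoform gene
    models, derives introns, classifies splice junctions as shared or
    isoform-specific, detects cassette exons, builds 22-nt donor/acceptor
    windows (6 exonic + 16 intronic bases), extracts strand-corrected site
    sequences, validates canonical GT-AG motifs, and scores acceptor
    polypyrimidine tracts. Intersects splice windows with biallelic PASS
    SNPs from a population VCF, stratifies minor allele frequencies by
    population and sex, applies a configurable splice-relevance rule, and
    computes windowed nucleotide diversity per stratum. A seeded synthetic
    cohort simulator (reference contig with embedded splice-site sequences,
    Hardy-Weinberg diploid genotypes with stratum-specific allele
    frequencies) makes the whole pipeline runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    vcfR,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
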