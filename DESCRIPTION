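Package: variantkit
Title: SNP Calling, Variant QC, Consequence Annotation and Linkage
    Disequilibrium Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A standalone re-implementation of the computational core of a
    genome-browser variation pipeline. Provides neighbourhood-quality-standard
    (NQS) SNP calling from quality-scored read alignments, SARA (same as
    reference assembly) computational genotyping at known loci, read-coverage
    summaries, variant merging with strand normalization and failed-variant
    quality control, transcript consequence annotation over a ranked
    consequence vocabulary (splice sites, coding changes, UTRs, regulatory
    regions), and population-genetic post-processing: minor allele
    frequencies, EM-based two-locus haplotype estimation with r-squared and
    D-prime, windowed pairwise LD, and greedy MAF-ordered tag-SNP selection.
    Includes a deterministic synthetic-data generator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
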