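Package: duplexumi
Title: Duplex UMI Consensus Calling of Very-Low-Fraction SNVs from
    Single-End Duplex-UMI Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted amplicon sequencing libraries that
    carry a single-end duplex unique molecular identifier (UMI) adapter: a
    synthetic library simulator with known truth (spiked SNVs at 0.1-0.4%
    allele fraction, strand-specific base damage and end-repair artifact
    copying), UMI and strand-barcode decoding from read 1, UMI family
    grouping and error-tolerant family merging, duplex pairing via shared
    UMI plus opposite strand barcodes, per-site family and duplex consensus
    with 80/80 majority rules, panel-wise background substitution error
    rates with Wilson confidence intervals, a Beta-Binomial model of the
    site-to-site error rate distribution, and a duplex-aware log-likelihood
    ratio caller for single-nucleotide variants at allele fractions near
    0.1%.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
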