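Package: exonCGH
Title: Exon-Centric Array-CGH Panel Design, Simulation, CNV Calling and
    qPCR Dosage Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted exon-centric array comparative genomic
    hybridization (aCGH). Designs isothermal ~60-mer oligonucleotide probe
    panels over exon targets with a genomic-tiling fallback, accounts for
    design coverage, simulates per-probe log2-ratio signals and qPCR Ct
    tables with the statistical structure the callers assume, detects copy
    number variants with a two-tier interval-score search (a global-noise
    variant and a probe-error-weighted variant) and integrates both call
    sets, flags single-probe exon-level imbalances clustered by disease
    panel, and validates dosage by the delta-delta-Ct method with
    three-way loss/normal/gain classification and concordance accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
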