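Package: mutaccum
Title: Mutation-Accumulation and Experimental-Evolution Mutational Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and hypothesis testing for bacterial
    mutation-accumulation (MA) and serial-transfer experimental-evolution
    studies. Implements per-site per-division mutation-rate estimates with
    exact chi-square (Garwood) Poisson confidence intervals, six-class
    base-substitution spectrum summaries and contingency tests,
    Nei-Gojobori-style fractional synonymous/nonsynonymous site counting
    (including 4-fold degenerate sites), gene-level mutation hotspot tests
    with Bonferroni correction, population allele-frequency and Ka/Ks
    selection scans with a through-origin regression calibration for genes
    lacking synonymous hits, effective-population-size arithmetic for
    single-cell colony bottlenecks, and plating phenotypes (efficiency of
    plating, MIC, log-linear growth rates). Ships simulators (neutral MA
    lines and a serial-bottleneck Wright-Fisher model with selection) that
    generate every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
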