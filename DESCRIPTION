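Package: poolrap
Title: Drift Simulation and Differentiation Testing for Reconstituted
    Ancestral Populations from Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolve-and-resequence studies that reconstitute
    ancestral populations (RAPs) from panels of isofemale lines and compare
    them to the original ancestral populations (APs) with pooled sequencing
    (Pool-Seq).  Provides a neutral simulator of allele-frequency change in
    isofemale-line panels (exponential parental allele-frequency spectrum,
    Hardy-Weinberg founder sampling, within-line fixation, binomial Pool-Seq
    resampling at empirical coverage), readers and writers for
    PoPoolation-style synchronized ("sync") allele-count files, SNP-calling
    filters with hypergeometric coverage subsampling, replicate-stratified
    Cochran-Mantel-Haenszel tests with dual-mapper intersection and
    Benjamini-Hochberg FDR control, and a fully synthetic four-population
    experiment generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
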