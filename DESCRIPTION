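Package: telarch
Title: Three-Dimensional Nuclear Telomere Architecture Profiling for CML Phase Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and quantifies 3D quantitative FISH (Q-FISH) image stacks of
    interphase nuclei to derive per-nucleus telomere architecture profiles
    (signal counts, integrated intensities, telomere aggregates, a/c ratio,
    nuclear volume, radial positions), compares chronic against
    accelerated/blast phase cohorts of chronic myeloid leukemia with nested
    factorial analysis of variance and chi-square distribution tests,
    quantifies AURKA/AURKB expression with the comparative-Ct (2^-ddCt)
    method, and parses simplified ISCN karyotype strings to count
    Philadelphia-chromosome status and clonal evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
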