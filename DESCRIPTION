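Package: mitoscan
Title: Genome-Wide Scans for Mitonuclear Incompatibilities in Hybrid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting mitonuclear genetic incompatibilities in
    admixed populations from local-ancestry posterior matrices. Computes
    mitonuclear linkage disequilibrium (D, D', r-squared) between nuclear
    ancestry-informative markers and the mitochondrial haplotype, aggregates
    statistics per gene, and tests whether gene classes defined by
    mitochondrial interaction (interacting n-mt, non-interacting n-mt,
    non-n-mt) differ via one-way ANOVA, permutation tests, top-fraction
    enrichment, and Z-score outlier scans. Includes a forward-in-time
    simulator of admixed diploid populations with recombination, maternal
    mitochondrial inheritance and viability selection against mismatched
    mitonuclear genotypes, which emits ancestry posterior matrices with
    configurable noise so the full analysis pipeline can be exercised and
    power studies run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
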