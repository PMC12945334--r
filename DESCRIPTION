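Package: diffgwas
Title: Differential Genome-Wide Association Analysis with Sample-Overlap
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contrasts two genome-wide association studies (GWAS) at the
    summary-statistic level to find variants with significantly different
    -- in particular, opposite-direction -- effects on two traits.
    Harmonizes effect alleles across studies, estimates the cross-study
    correlation of z-scores from quasi-independent (LD-pruned) SNPs to
    correct the variance of the effect-size difference for sample overlap,
    standardizes differential z-scores genome-wide before assigning
    two-sided p-values, selects candidate loci by a composite
    significance-and-opposite-direction rule with distance-based clumping,
    and triages candidates against a replication GWAS. Includes a
    synthetic summary-statistics generator with known sample overlap and
    known causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
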