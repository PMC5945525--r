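Package: lynchmmr
Title: Paired Tumor-Normal Analysis for Lynch Syndrome Mismatch-Repair Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for paired tumor/normal targeted-panel analysis in the
    work-up of suspected Lynch syndrome. Differentiates somatic from germline
    small variants with a threshold cascade on paired allele counts, classifies
    microsatellite instability from homopolymer read-length histograms,
    detects loss of heterozygosity in the five Lynch genes from allelic
    imbalance at intronic heterozygous SNPs, interprets methylation-specific
    MLPA ratios for the MLH1 promoter, and combines all evidence into a
    two-hit molecular scenario call. Ships a seeded paired-cohort simulator
    with full truth labels, validation-cohort fixtures, and the concordance
    arithmetic (sensitivity, specificity, discordance rates, binomial
    confidence intervals) used to validate such assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
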