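Package: scase
Title: Genotype-Free Allele-Specific Expression Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying allelic gene expression in single-cell RNA-seq
    when genotypes are unavailable. Heterozygous SNPs are discovered by pooling
    allelic read depths across the cells of an individual, with positive
    predictive value calibration of the read-depth cutoff against truth
    genotypes. Per-cell allelic status at each heterozygous site is classified
    as monoallelic, biallelic, or unknown using an exact binomial test with
    Benjamini-Hochberg false discovery rate control and an allelic-ratio rule;
    calls are lifted to gene level and to cell-type level with expression
    percentile and multi-cell consistency filters. Additional analyses cover
    pseudo-bulk allelic ratios, expression of functionally disrupted alleles,
    and permutation tests for cell-type specificity of monoallelic gene sets.
    A synthetic data generator with allelic dropout, transcriptional bursting,
    sequencing error, and reference mapping bias drives the test suite.
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
    rtracklayer,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
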