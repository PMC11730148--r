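Package: larvascan
Title: Selection-Scan Contrast on Individually Genotyped Coral Larva Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed nucleotide diversity (pi) and Tajima's D selection scans
    on two-condition cohorts of diploid genotypes, as used to contrast control
    and heat-stressed coral larvae. Provides a site-frequency-spectrum
    simulator with neutral, sweep-like and balancing regimes that emits VCF
    plus matching CDS/GO/proteome annotations and a truth table; PLINK-style
    site filtering (Hardy-Weinberg exact test, minor allele frequency,
    calling rate); per-window pi and Tajima's D with missing-genotype
    handling; percentile-tail outlier classification and cross-condition set
    contrast with flank-to-CDS mapping; mixed-model likelihood-ratio group
    inference with subsampling robustness and a survival comparison utility;
    and rank-based (Mann-Whitney U) GO enrichment with Benjamini-Hochberg
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    lme4,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
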