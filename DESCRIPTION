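Package: tsdscan
Title: Genome Scans and Marker Assays for Temperature-Dependent Sex Reversal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genome scans for temperature-dependent sex reversal in
    fish with XX/XY sex determination, modelled on reduced-representation
    (ddRAD-style) SNP data from Nile tilapia. Implements a sample-size-weighted
    per-site fixation index (FST) between temperature-masculinized pseudomales
    and non-masculinized females, Gaussian kernel smoothing along linkage
    groups, empirical-quantile outlier detection, and per-linkage-group
    summaries; a PLINK-style case-control allelic association test (1-df
    chi-square, odds ratios with Woolf confidence intervals, Bonferroni
    correction); in-silico restriction (RFLP) genotyping of amh/amh-deltaY
    amplicons and LG1 SNP sex-genotype calls; Stacks-style site and genotype
    filters (depth, call rate, minor allele frequency, blacklist); and a
    Mendelian full-sib family simulator with a causal masculinization locus
    under genotype-dependent penetrance, used to generate complete synthetic
    studies (VCF, population map, truth table) on which the whole pipeline is
    exercised.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
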