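Package: flockscan
Title: Genomic Characterization and Climate-Resilience Genetics for SNP-Array
    Data from Dairy Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genome-wide characterization and climate-resilience
    analysis of diploid SNP-array genotypes in livestock populations.
    Implements runs-of-homozygosity (sliding-window) and heterozygosity-rich
    region (consecutive) detection, genomic inbreeding (F_ROH) overall and by
    run-length class, homozygosity/heterozygosity island calling at a high
    quantile of per-SNP run frequencies, VanRaden genomic relationship
    matrices with principal component analysis, restricted maximum likelihood
    (REML) estimation of variance components for one and two traits, genomic
    breeding values with prediction-error-variance accuracies, single-SNP
    mixed-model association scans with Bonferroni and suggestive thresholds
    and genomic-control inflation correction, and regional heritability
    mapping with likelihood-ratio tests over sliding SNP windows. Per-animal
    resilience phenotypes are derived as slopes of reaction-norm curves
    fitted to longitudinal test-day milk yields against daily air
    temperature. A synthetic-data generator emulates the statistical
    structure of a medium-density ovine dataset so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
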