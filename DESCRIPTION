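Package: snpselga
Title: Two-Stage SNP Selection for Continuous Phenotypes with
    Support Vector Regression and Genetic Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects single nucleotide polymorphism (SNP) markers that
    explain a continuous phenotype in two stages. Stage one ranks markers
    by the p-value of their Spearman correlation with the phenotype,
    builds an increasing sequence of nested marker groups from p-value
    thresholds, and evaluates each group with epsilon support vector
    regression (linear, radial basis function and Pearson VII universal
    kernels) under repeated 10-fold cross-validation. Stage two prunes
    the best group with a binary genetic algorithm whose fitness is the
    cross-validated mean squared error of the support vector regression.
    Includes genotype quality-control filters (call rate, minor allele
    frequency, Hardy-Weinberg equilibrium), pairwise r^2 linkage
    disequilibrium diagnostics, readers for dosage CSV, PLINK raw and
    VCF genotypes, and seeded genotype/phenotype simulators with
    additive and epistatic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    kernlab,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
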