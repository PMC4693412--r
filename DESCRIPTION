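Package: senet
Title: Statistical Epistasis Networks from SNP-Pair Information Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens all pairs of single-nucleotide polymorphisms (SNPs) for
    epistatic association with a dichotomous phenotype using information gain,
    assembles pairs exceeding a percolation threshold into a statistical
    epistasis network, and assesses significance with phenotype-shuffling
    permutation tests. Per-gene dyadicity and heterophilicity quantify whether
    interactions concentrate within or between genes, and degree, betweenness
    and closeness centrality rank key SNPs in the largest connected component.
    Includes data preparation (BMI dichotomization, covariate adjustment with
    deviance-residual classification, minor-allele-frequency filtering, LD
    pruning, mode imputation, SNP-to-gene window mapping) and a synthetic
    genotype/phenotype simulator for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
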