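Package: cryptohyb
Title: Admixture Clustering, Hybrid Detection and Population Genetics for
    Sympatric Cryptic Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the genetic analysis of pairs of
    sympatric cryptic species typed at co-dominant microsatellite loci, with
    a mitochondrial barcode and simple phenotypes. Implements Bayesian
    admixture clustering under the correlated-allele-frequency (F-model)
    prior with multi-run consensus and Evanno delta-K model selection; a
    simulation-calibrated hybrid classifier (gamete-level simulation of F1,
    F2 and backcross classes, q-value thresholds, conservative and relaxed
    rules, and a replicated parental-misclassification study); Weir-Cockerham
    F-statistics with bootstrap confidence intervals and permutation tests
    (Hardy-Weinberg, linkage disequilibrium, exact G differentiation,
    sex-biased dispersal); null-allele screening; raw-distance haplogrouping
    of mitochondrial barcodes with cyto-nuclear discordance accounting; and
    nested two-way ANOVA phenotype comparisons. A synthetic-data generator
    with known ground truth emulates the statistical structure of a
    two-species microsatellite study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
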