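Package: pileupLR
Title: Population Likelihood Ratios from Low-Coverage Read Pileups at
    Disease-Associated Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probabilistic inference of the population origin of
    low-coverage sequencing data at a panel of disease-associated
    biallelic loci. Implements a symmetric per-read error model, exact
    genotype-marginalized multinomial likelihoods under Hardy-Weinberg
    genotype priors, Dirichlet allele-frequency uncertainty from
    population allele counts, per-locus and cohort likelihood ratios
    between two candidate populations, a Monte-Carlo null distribution
    for a disease-allele read-count statistic with empirical tail
    probabilities, and a synthetic-cohort generator with known ground
    truth for parameter-recovery, power and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
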