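Package: phenomem
Title: Fixation of Phenotypically Plastic Alleles with Heritable Phenotypic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of a phenotypically plastic
    allele whose expressed phenotype is partially heritable between parent
    and offspring ("phenotypic memory"), in constant or periodically
    fluctuating environments. Provides the single-generation update and
    run-to-absorption simulator, closed-form approximations for the fixation
    probability of the plastic allele in a constant environment
    (phenotype-switching balance, effective selection coefficient, Kimura
    diffusion formula), Monte Carlo drivers for fixation and
    counter-fixation probabilities, stationary geometric mean fitness, and
    spline-based location of the optimal phenotypic memory, plus JSON/YAML
    scenario configuration and CSV result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
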