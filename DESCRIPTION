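Package: gpgan
Title: Genetically Guided Weakly-Supervised GAN Subtyping of Disease Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers disease subtypes that are jointly supported by
    phenotypic features (for example regional brain volumes from MRI) and
    genetic features (minor-allele counts of pre-selected SNPs).  A
    generative adversarial network learns one-to-many transformations from a
    healthy reference population to a patient population, with a categorical
    latent variable encoding subtype membership; a variational-inference
    step with a binomial genotype likelihood ties that latent variable to
    the genetic data.  The package also provides the semi-synthetic
    validation cohort generator, hold-out cross-validation with an
    association-count model-selection metric, consensus (ensemble)
    subtyping, interpretation operators for subtype-specific phenotype
    change maps and inferred allele frequencies, and multinomial-logistic
    likelihood-ratio SNP-subtype association tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
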