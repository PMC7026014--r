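Package: tsmc
Title: Sequential Monte Carlo Samplers with Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential Monte Carlo (SMC) samplers that move a weighted
    particle population through a sequence of posterior distributions of
    changing dimension. Deterministic transformations carry particles
    between models, geometric annealing with conditional-ESS-adaptive
    placement of intermediate distributions bridges neighbouring targets,
    and proposals built from several alternative transformations ("routes")
    can be used either conditionally or with the route marginalised out.
    The generic engine returns unbiased marginal-likelihood (evidence)
    estimates. Two applications are provided: Bayesian comparison of
    univariate Gaussian mixture models with birth and moment-matching
    split transformations, and online inference of coalescent genealogies
    and the mutation rate from DNA sequence alignments, adding sequences
    one at a time with SNP-guided lineage proposals and Laplace-type
    attachment-height proposals under the Jukes-Cantor model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
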