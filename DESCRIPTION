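Package: socped
Title: Pedigree Kinship, Infidelity, and Inbreeding Depression in Social Breeders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pedigree-based analysis of inbreeding and extra-pair
    paternity in cooperatively breeding birds. Provides exact pedigree kinship
    and inbreeding coefficients (Malecot recursion and the tabular additive
    relationship matrix), a Monte Carlo gene-dropping oracle, relationship-path
    classification, and pedigree completeness restriction; an agent-based
    simulator of a fairy-wren-like social system (helper queues, territory
    inheritance, mother-son social pairs, obligate female dispersal, high
    extra-pair paternity) with recorded generative truth; brood-level binomial
    mixed models of infidelity; animal-model and survival analyses of
    inbreeding depression in nestlings; and a counterfactual "faithful
    pedigree" contrast with Fisher's exact tests and a two-stage hurdle model
    of offspring inbreeding status and magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    lme4,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
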