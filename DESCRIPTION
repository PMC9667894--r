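Package: symptomnet
Title: Ising Network Analysis of Binary Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and stability analysis of symptom networks from
    ordinal questionnaire data (e.g. PHQ-9 depression and GAD-7 anxiety
    items). Implements item screening and binarization, Ising network
    estimation by nodewise l1-penalized logistic regression with extended-BIC
    model selection (eLasso), expected-influence and bridge-expected-influence
    centrality with percentile-based bridge selection, node predictability,
    non-parametric and case-dropping bootstrap diagnostics with the
    correlation-stability coefficient, and synthetic-data generators (exact
    and Gibbs Ising samplers, a latent-Gaussian ordinal questionnaire
    generator) for validation without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
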