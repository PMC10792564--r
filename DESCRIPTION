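Package: mtxtraj
Title: Multivariate Trajectory Clustering of Methotrexate Response in
    Juvenile Idiopathic Arthritis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying clusters of treatment response in
    juvenile idiopathic arthritis (JIA) from longitudinal disease-activity
    data collected after methotrexate (MTX) initiation.  Implements
    multivariate group-based trajectory models with censored-normal (Tobit)
    outcome components fitted by multi-start EM, admissibility-filtered BIC
    model selection, ACR Pediatric 30/90 composite response scoring, and
    cluster characterization via multinomial logistic regression, one-vs-rest
    ROC analysis and Kaplan-Meier comparison of time to biologic therapy.
    Includes a seeded synthetic-cohort generator emulating the latent
    six-cluster longitudinal structure of UK JIA methotrexate cohorts, so
    that the whole pipeline can be exercised and validated without access to
    the (access-controlled) registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
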