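Package: sdohtopics
Title: Topic Modeling of Clinical Social Work Notes for Social Determinants of Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for discovering and labeling social
    determinants of health (SDoH) themes in clinical social work notes.
    Provides note filtering (metadata "social" selection, length and
    duplicate removal), tokenization and document-term matrix
    construction, latent Dirichlet allocation fitted by batch mean-field
    variational Bayes, selection of the topic number by sliding-window
    NPMI coherence and mean pairwise Jaccard topic similarity with a
    rank-sum rule, automatic topic labeling against a packaged SDoH
    keyword dictionary via intersection-over-union, stratified
    topic-proportion analysis by note type and ICD-10 disease chapter,
    and chi-squared word-frequency comparison across note categories.
    Includes a synthetic-corpus generator with planted topic structure
    so the full pipeline can be exercised without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
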