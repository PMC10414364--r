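Package: shakespeare
Title: Unsupervised Surveillance of Potential Adverse Events in Clinical Note Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds potential adverse events in unstructured electronic health
    record notes without prespecified event definitions. Notes are concatenated
    chronologically per admission, replicate sentences and list items are
    removed, documents are vectorized as n-gram counts, terms statistically
    significant for a target group (or a recent time period) are selected with
    a naive Bayes / logistic regression ensemble plus frequency rules, latent
    Dirichlet allocation is fitted to the term-filtered target documents, and
    documents plus term time trends are surfaced for manual review. Includes a
    synthetic note generator with recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
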