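Package: paqa
Title: Partial-Area Taxonomy Summarization and Outlier-Concept Quality
    Assurance for Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives area and partial-area taxonomy summarization networks
    from biomedical ontology hierarchies with lateral (attribute/role)
    relationships, flags concepts in small partial-areas as audit targets,
    and implements the blinded stratified audit-sampling design with
    Fisher exact analysis of stratum error rates. Also provides the
    exact-binomial (Clopper-Pearson) family-applicability criterion used
    to argue that a quality-assurance technique demonstrated on six of six
    family members applies to at least half of a structural family of
    ontologies, plus a synthetic ontology generator with planted modeling
    errors for end-to-end calibration of the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
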