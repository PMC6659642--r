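Package: gwasminer
Title: Machine Curation of Genetic Associations from Full-Text GWAS Publications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An information-extraction pipeline that reads genome-wide
    association study (GWAS) publications in JATS/PMC-style XML and compiles a
    structured database of (publication, variant rsid, phenotype, p-value)
    associations. Candidate mentions are generated with regular expressions and
    ontology dictionaries, scored by hand-written labeling functions, and
    classified with a generative Naive Bayes label model trained without
    ground-truth labels (data programming). Includes an evaluation harness for
    comparison against human-curated reference catalogs, a linkage
    disequilibrium based novelty filter, and a synthetic-corpus generator with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
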