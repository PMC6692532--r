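Package: pgxminer
Title: Semiautomated Pharmacogenomic Relationship Mining from Literature Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semiautomated text-mining pipeline that extracts
    disease-drug-gene-polymorphism relationships from MEDLINE-style abstract
    corpora. Provides a publication-level filter cascade with auditable
    per-stage counts, dictionary-based named-entity recognition of disease,
    drug, gene and population mentions with orthographic-variant matching,
    pattern-based recognition of genetic variants (dbSNP rsIDs and simple
    HGVS substitutions), normalization of mentions to canonical identifiers
    (HGNC-style gene symbols, ICD-10-style parent disease chapters, DrugBank
    style drug identifiers, rsIDs) with explicit failure codes, abstract-level
    co-occurrence relation extraction with binary projections, ranking of
    extracted relationships against PharmGKB-, OMIM- and CTD-style reference
    datasets with a frequency threshold for unsupported relationships, and
    confusion-matrix evaluation against a gold standard including
    error-percentage bookkeeping. A deterministic synthetic-fixtures
    generator produces toy lexica, corpora, reference datasets and gold
    standards with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
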