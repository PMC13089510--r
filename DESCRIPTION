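Package: pprlaudit
Title: Evaluating Privacy-Preserving Record Linkage Against Rule-Based Patient Matching
Version: 1.0.0
Authors@R:
    person("pprlaudit", "developers", email = "pprlaudit@example.org", role = c("aut", "cre"))
Description: Tools to evaluate hashed-token privacy-preserving record linkage
    (PPRL) against rule-based deterministic patient matching between two
    health-system registries. Provides a synthetic two-site patient registry
    generator with ground-truth linkage and realistic PII error processes,
    an HMAC-based feature-combination tokenizer, a weighted rule-based
    matcher and a calibrated token-overlap matcher with nested score
    thresholds, partitioning of a query cohort into the eight exclusive
    agreement categories, stratified audit sampling with simulated
    adjudication, and estimation of false-match rates with exact binomial
    confidence intervals, population projections, and per-algorithm
    precision and recall against a union proxy gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    openssl,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
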