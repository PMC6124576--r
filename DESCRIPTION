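Package: orthoDE
Title: Conserved Differential Expression Across Species in Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-species comparison of pluripotent embryonic stages over a
    1:1:1 orthologue universe: negative-binomial count simulation with planted
    conserved, species-specific and state-specific effects; orthologue table
    validation and matrix re-keying; counts-per-million normalisation,
    expressed-gene calling and three-set Venn decomposition; per-transition
    differential expression with Benjamini-Hochberg false discovery control
    and fold-change thresholds; conservation-of-differential-expression
    overlap enrichment against hypergeometric and Monte-Carlo independence
    nulls; sample-level correlation clustering, principal component analysis
    and replicate quality control; and derivation and scoring of naive and
    primed pluripotency predictor gene panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
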