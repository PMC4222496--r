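Package: rcr
Title: Reverse Causal Reasoning for Gene Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers upstream molecular mechanisms that explain observed
    differential gene expression. A signed causal knowledge graph (optionally
    parsed from simple Biological Expression Language statements) is collapsed
    into hypothesis networks (HYPs), each linking one upstream controller to
    its measured downstream RNA abundances. Trinary differential-expression
    states are mapped onto each HYP, a direction is inferred by majority vote,
    and each mechanism is scored with an ambiguity-corrected binomial
    concordance p-value and a hypergeometric richness p-value. Matched random
    data sets calibrate significance thresholds, diagnose size bias, and
    optionally adjust concordance with a LOESS fit. A synthetic-fixture
    generator with planted active mechanisms supports end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
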