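Package: evmirpanel
Title: Consensus Differential Expression and Cross-Biofluid Panel Selection
    for Extracellular-Vesicle miRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tiered extracellular-vesicle miRNA marker panels for
    ovarian cancer from small-RNA count matrices. Implements three-engine
    consensus differential expression (negative-binomial likelihood-ratio,
    precision-weighted moderated linear model, negative-binomial Wald) with
    two-tier FDR selection, direction-aware differential co-expression set
    algebra across biofluids (uterine aspirate, ascitic fluid, ascites-cell
    conditioned medium), and a negative-binomial count simulator with planted,
    optionally monotone, co-directional effects for end-to-end validation.
    Ships machine-readable transcriptions of the published result tables and
    reproduces the published panel counts from them by pure set logic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    DESeq2,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
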