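Package: fanoreg
Title: Intrinsic Noise in Autoregulated Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intrinsic noise in the standard on/off-gene, mRNA,
    protein model of gene expression with transcriptional autoregulation
    (negative or positive feedback). Provides an exact stochastic simulator
    of the jump process, the deterministic quasi-steady-state limit of the
    protein concentration, an Ornstein-Uhlenbeck fluctuation theory with
    closed-form equilibrium Fano factors and their additive decomposition
    into protein, mRNA and gene-switching noise, matched-model comparisons
    of feedback variants, and classical reference formulas (Paulsson's
    exact neutral Fano factor, the Thattai-van Oudenaarden linearization,
    and the birth-death stationary law of the low-abundance limit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
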