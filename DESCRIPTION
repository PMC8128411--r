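Package: hybridGP
Title: Genomic Prediction of Single-Cross Hybrids with Origin-Specific
    Additive, Dominance and Epistatic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic evaluation of single-cross hybrids between
    two heterotic groups of inbred lines (e.g. Dent x Flint maize).
    Implements origin-specific incidence codings for marker effects,
    the derived additive, dominance and additive-by-additive epistatic
    genomic relationship matrices for the GCA-model, the NOIA hybrid-level
    codings and matrices for the G-model, Bayesian variance-component
    estimation by Gibbs sampling on eigendecomposed covariance structures
    (with "residual genetic" line effects), hybrid prediction, and a
    T2/T1/T0 cross-validation protocol.  Includes an exact single- and
    two-locus enumeration oracle for the underlying quantitative-genetic
    theory and a synthetic-data generator with analytically known
    variance components.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
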