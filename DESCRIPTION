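Package: mrnadecay
Title: Modeling Transcript Properties That Predict mRNA Degradation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for modeling genome-wide variation in mRNA
    degradation rates in budding yeast from transcript properties.
    Computes sequence-derived codon features (positional GC content,
    codon adaptation index, normalized translational efficiency,
    poly-proline runs), converts between half-lives and first-order
    degradation rate constants with growth-dilution correction,
    assembles a gene-by-predictor table with per-column log
    transformations and Tukey-fence outlier filtering of the response,
    builds multiple regression models by univariate screening followed
    by backward or forward stepwise selection and AIC reduction with
    variance decomposition over continuous and categorical predictors,
    and estimates decay constants from transcriptional-shutoff qRT-PCR
    time courses with bootstrap confidence intervals. A synthetic-data
    generator produces coding sequences, predictor tables, categorical
    annotations, and Ct time courses with known ground truth so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
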