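Package: hosnmr
Title: Quantitative NMR Similarity Assessment of Protein Drug Products
Version: 0.1.0
Authors@R:
    person("HOS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric similarity assessment of protein higher order structure
    (HOS) in formulated drug products from solution NMR data. Implements the 1D
    1H spectral pipeline of excipient-region exclusion, fixed-width binning, sum
    normalization, Pareto scaling and principal component analysis, yielding a
    pooled-covariance Mahalanobis distance between two brands of a drug product
    compared against the 3.3 similarity threshold, with 90% confidence ellipses
    in score space. Also implements 2D methyl peak-profile comparison: cross-lot
    peak matching, chemical shift difference metrics (4 ppb 1H / 15 ppb 13C),
    relative peak heights against a reference peak, Welch t-tests and an
    equivalence summary; amide peak counting from protein sequences for
    1H-15N correlation spectra; and a synthetic spectrum/peak-list generator
    providing ground-truth inputs for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
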