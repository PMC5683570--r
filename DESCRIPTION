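Package: mirmint
Title: Integrative miRNA-mRNA Expression Analysis with Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating small-RNA and mRNA sequencing count data
    from two-group (tumour versus normal) designs. Provides counts-per-million
    filtering, TMM normalization, a negative-binomial likelihood-ratio test
    for differential expression with moment-based shrunken dispersions and
    optional residual-SVD latent factors, Benjamini-Hochberg adjustment and
    fold-change classification; a random-walk-with-restart network-propagation
    screen that scores each miRNA's perturbation against the ranked
    differential-expression profile (NPES) with gene-set-permutation
    normalization; inverse-correlation miRNA-mRNA pair discovery over
    validated-target edges with a joint sample-shuffling permutation test;
    a coupled negative-binomial count simulator with planted regulatory
    structure and machine-readable ground truth; and a deterministic
    end-to-end pipeline with a summary report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
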