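Package: rodomics
Title: Quantitative Myopathology and Multi-Omic Comparison of Nemaline Myopathies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing inherited and sporadic late-onset
    nemaline myopathy at the tissue and molecular level: stereological muscle
    morphometry with systematic uniform random sampling (counting frames,
    minimum Feret fiber diameters, rod-distribution classification, two-group
    statistics), label-free proteomics differential abundance (lower-tail
    imputation of left-censored intensities, log2 quantile normalization,
    per-protein Gaussian linear models with Benjamini-Hochberg correction),
    signed-rank preranked gene-set enrichment with a gene-permutation FDR,
    immunoglobulin spectral-count testing on Poisson and quasi-Poisson tracks,
    and proteome-transcriptome overlap of differential targets. Includes
    synthetic-data generators with planted ground truth (fiber maps with rod
    spatial patterns, log-normal intensity matrices with intensity-dependent
    missingness, overdispersed count tables) so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
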