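Package: structkit
Title: Haplotype-Sharing Statistics for Fine-Scale Population Structure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics layered on top of haplotype painting and
    identity-by-descent (IBD) detection for fine-scale population structure
    studies: total variation distance (TVD) between cluster copying vectors
    with permutation tests and a TVD merge tree; non-negative least squares
    (NNLS) ancestry profiles with prune-and-refit, country aggregation,
    gradient-axis scans, Moran's I and Mantel tests; length-binned IBD
    sharing matrices with closed-form segment dating, PCA and Gaussian
    mixture clustering, and within/between-group mean sharing; Nagelkerke
    pseudo-R2 of structure covariates against a binary phenotype; plus a
    synthetic structured-cohort generator (coancestry matrices, IBD segment
    files, geography, ancestry gradients, stratified phenotypes) so the whole
    pipeline can be exercised and validated without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    mclust,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
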