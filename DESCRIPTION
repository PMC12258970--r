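Package: sigstratum
Title: Stratified Mutational Signature Extraction, Decomposition, and
    Clonal Timing for Somatic Substitution Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building single base substitution (SBS) mutational
    catalogs under the SBS-96, SBS-288 and SBS-1536 classification schemas,
    extracting de novo mutational signatures by bootstrapped nonnegative
    matrix factorization with consensus clustering and stability-based rank
    selection, decomposing de novo signatures into reference catalogs with
    subgroup exclusion and novelty calling, attributing per-sample signature
    activities with sparsity pruning, timing mutations as early or late
    clonal from cancer cell fraction and copy-number annotations, applying
    cohort stratification filters for hypermutated samples, and testing
    burden associations. Includes a synthetic-cohort generator with known
    ground-truth exposures, hypermutator spike-ins, clonal-timing structure
    and correlated indel burdens for validating the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
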