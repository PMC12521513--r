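Package: panelfrag
Title: Fragmentomics Metrics and Phenotype Classification for Targeted
    cfDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes fragmentomics feature classes (normalized read depth,
    fragment-length Shannon entropy, fragment-size bin proportions, small
    fragment fraction, 4-mer end-motif diversity score, and fragment-length
    entropy over transcription factor binding sites and open-chromatin
    region sets) from cell-free DNA fragment intervals over targeted exon
    panels; subsets panels to commercial gene lists; builds in silico
    low-tumor-fraction samples by down-sampling and mixing fragment sets;
    and evaluates phenotype predictability with repeated stratified
    cross-validation of elastic-net multinomial classifiers tuned by Latin
    hypercube search in a nested inner loop, summarized by one-vs-rest
    AUROC. Includes a synthetic cohort generator so the full pipeline is
    testable without access to patient data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    graphics,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
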