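Package: tcms
Title: Clinico-Molecular Subtyping of Lung Adenocarcinoma from Tumor and
    Microenvironment Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a 20-feature signature system combining radiological and
    pathological expression signatures with consensus-voted tumor
    microenvironment marker sets, scores bulk transcriptomes by single-sample
    gene-set enrichment (ssGSEA), derives four lung-adenocarcinoma subtypes
    (LPI, IMD, IME, HPI) by resampled PAM consensus clustering, and provides
    the downstream genomic and survival machinery: NCCN hotspot calling,
    pairwise co-occurrence and mutual-exclusivity testing, a 32-category
    structural-variant taxonomy with NMF signature extraction and NNLS
    catalog refitting, and Kaplan-Meier / log-rank / Cox comparisons. A
    synthetic-cohort generator with planted subtype structure makes the whole
    pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    pracma,
    stats,
    survival,
    utils,
    withr
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
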