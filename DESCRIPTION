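Package: pairconcord
Title: Paired Tumour-Metastasis Somatic Variant Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing somatic mutation profiles between paired
    primary tumours and synchronous metastases sequenced together with a
    matched normal sample. Implements a germline-subtraction and
    evidence-filtering cascade for variant call tables, shared/private
    classification of variants across the two tumour sites with explicit
    coverage guards and low-frequency rescue, clonality-shift detection from
    variant allele frequency changes, per-patient and cohort concordance
    statistics (shared fraction, mutational burden, transition/transversion
    ratio, SIFT composition, gene-by-patient recurrence, rank-based group
    contrasts), and paired copy-number aberration analysis on binned log2
    copy-ratio profiles (binary segmentation, numerical versus segmental
    event taxonomy, pair comparison, mutation-CNA co-occurrence). A
    synthetic cohort generator simulates matched trios and copy-number
    profiles under a branched clonal-evolution model with known ground
    truth so every stage can be validated without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    vcfR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
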