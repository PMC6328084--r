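Package: pdxconcord
Title: Genomic Concordance Scoring Between Tumours and Patient-Derived Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genomic agreement between a patient tumour and its
    matched patient-derived xenograft (PDX) or organoid (PDO) across three
    levels of genomic complexity: simple somatic mutations (per-category and
    overall Jaccard indices on variant identity sets), structural variants
    (size-weighted per-chromosome and per-category Jaccard indices, weighted
    event counts with clustered-rearrangement flags, and an overall
    chromosome-level concordance score), and ploidy-rescaled copy-number
    states (base-weighted agreement over co-defined genomic loci). Includes
    readers for somatic VCF, BEDPE and copy-number segment files, a
    manifest-driven orchestrator for pairs and trios, and a seeded synthetic
    matched-callset generator that emits data with known ground-truth
    concordance for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
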