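Package: cnvcurate
Title: Ensemble Merging, Filtering and ACMG/ClinGen Interpretation of Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-calling curation of germline copy number variant (CNV) call
    sets. Applies caller-specific confidence filters to per-caller VCF/BED
    call sets, merges concordant calls across callers with a size- and
    type-aware single-linkage strategy, removes calls in blacklist and
    assembly-gap regions by reciprocal overlap, and scores each surviving CNV
    under the ACMG/ClinGen semiquantitative framework (dosage sensitivity,
    gene content with family collapsing, loss-of-function assessment,
    population frequency) to produce per-CNV evidence reports and a
    five-tier classification. Ships a synthetic-fixture generator so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
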