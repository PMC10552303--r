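Package: fetomics
Title: Metabolite-Gene Association Screening and Prioritization for
    Germ-Free vs SPF Fetal Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates per-fetus gene expression counts and LC-MS
    metabolite intensities from germ-free (GF) versus specific-pathogen-free
    (SPF) mouse litters into a ranked list of microbially modulated
    metabolites most strongly associated with gene expression programs, per
    tissue. Implements gene prefiltering, median-of-ratios normalization, a
    documented differential-expression stand-in, metabolite differential
    status classification, litter averaging with twin-similarity QC, three
    association routes on SPF dam-level means (direct Spearman screening,
    complete-linkage cluster linking, plaid-model biclustering with
    permutation-based layer acceptance), hypergeometric over-representation
    analysis against GMT collections, and rank-sum score aggregation. A
    synthetic twin-litter study generator with known planted structure makes
    every stage testable without external data.
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
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
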