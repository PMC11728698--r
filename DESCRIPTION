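Package: taxeval
Title: Evaluation of Taxonomic Profilers in a Common Feature Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Standardized evaluation of metagenomic taxonomic profilers
    against a ground truth in a shared (common) feature space. Projects
    relative-abundance tables between feature spaces through weighted
    feature mappings with explicit loss accounting, computes a per-sample
    metric suite (richness and Shannon diversity error, Bray-Curtis,
    weighted UniFrac and Aitchison distances, sensitivity, precision,
    false-positive and false-negative relative abundance), compares
    community structure via Jensen-Shannon divergence between pairwise
    distance matrices, detects systematically confused species pairs by
    cross-correlating false negatives with false positives, and ships a
    profile-level community and profiler-error simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
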