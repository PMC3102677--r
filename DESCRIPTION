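Package: silacquant
Title: SILAC Pair Quantification and Differential Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for stable-isotope-labeling (SILAC)
    quantitative proteomics: builds persistent chromatographic features
    from per-scan deisotoped detections, matches light/heavy isotope
    pairs by exact mass-shift class, computes relative isotope abundance
    (RIA), assembles an accurate-mass-and-time peptide database with
    presence and retention-time filters, rolls peptide ratios up to
    proteins with outlier trimming and ratio-space normalization, calls
    differential expression by one-way ANOVA with a control-distribution
    fold cutoff, and performs hierarchical clustering and hypergeometric
    term enrichment. Includes a ground-truthed synthetic-data generator
    emulating a forward/reverse mixed plus double-control study design
    in biological triplicate and technical duplicate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
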