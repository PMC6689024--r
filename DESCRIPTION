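Package: bescope
Title: Quantification and Characterization of Cytosine Base Editing from
    Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies CRISPR cytosine base-editing outcomes from targeted
    amplicon deep-sequencing reads: demultiplexing, 3' quality trimming,
    seed-based read placement, and per-position base-conversion frequencies
    in protospacer coordinates over a 43-bp quantification window. Builds on
    the frequency tables to compute editing-window statistics (per-sgRNA
    editing scope, per-editor comprehensive editing window), classify editors
    as forward-shifted, backward-shifted or broad-range, test dinucleotide
    substrate preference by one-way ANOVA, and score on/off-target
    specificity. Includes a seeded amplicon read simulator with closed-form
    ground truth so every stage can be validated against known editing
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
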