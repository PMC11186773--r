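Package: beshield
Title: Amplicon Sequencing Analysis for Base-Edited, Epitope-Shielded Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying base-editing outcomes from targeted
    amplicon deep sequencing in epitope-shielding experiments: protospacer
    and quantification-window geometry on reference amplicons, global
    alignment of merged reads and window-restricted allele counting,
    translation of alleles into named amino-acid substitution genotypes,
    codon-level enumeration of adenine/cytosine base-editor outcomes
    (intended and bystander edits) with a screening score, off-target
    editing validation against matched controls (2x2 chi-squared test,
    Benjamini-Hochberg false discovery rate, dual significance criterion),
    alanine-scan antibody epitope calling, and donor chimerism estimation
    from informative indel markers. A synthetic-data module generates
    every input with known ground truth so the whole pipeline runs and is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
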