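Package: smorfscreen
Title: Screening Cancer-Specific lincRNAs for Micropeptide-Encoding Small ORFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering micropeptide candidates among
    tumor-specific long intergenic noncoding RNAs (lincRNAs). Stages cover
    tissue-exclusive expression filtering on FPKM matrices, promoter
    chromatin-accessibility annotation against DNase/cCRE/CAGE interval
    tracks, small open-reading-frame discovery with Kozak-context scoring and
    peptide mass prediction, nuclear/cytoplasmic export classification, and
    polysome-gradient translation evidence computed from qPCR CT values.
    Includes a truth-labelled synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
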