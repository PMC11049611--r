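Package: triplescore
Title: Triple p16-CD8-Ki67 Immunohistochemical Score for CDKN2A Deletion
    Status in Melanoma
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-quantitative triple immunohistochemical scoring algorithm
    (p16 tumor-cell positivity, CD8-positive peritumoral tumor-infiltrating
    lymphocytes, Ki67 proliferation index) that predicts CDKN2A homozygous
    deletion in multiple-primary and familial melanoma, together with the
    diagnostic-evaluation harness needed to assess it: confusion matrices,
    sensitivity and specificity, threshold sweeps, bootstrap confidence
    intervals, genotype-wise group statistics with Welch t-tests, and a
    genotype-conditional synthetic cohort generator.  A 23-patient reference
    cohort with fluorescence in situ hybridization (FISH) copy-number calls
    is bundled, and a command-line interface exposes scoring, evaluation and
    simulation as reproducible commands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
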