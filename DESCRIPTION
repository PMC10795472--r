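Package: porePTM
Title: Nanopore Signal Analysis for Peptide Post-Translational Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-channel nanopore current recordings for
    discriminating peptide post-translational modifications. Provides a
    ground-truth synthetic trace simulator parameterized by measured
    per-peptide blockade statistics, open-pore baseline fitting and
    threshold event extraction, per-event features and local-extrema
    sequences, a jointly trained recurrent classifier and assessment
    network with a 3-part loss and confidence-based event selection,
    evaluation protocols (normalized confusion matrices, accuracy versus
    selection percentage, mixture assignment), and capture-rate
    quantification of analyte concentration from blockade frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    mclust,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
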