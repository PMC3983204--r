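Package: pdzsnp
Title: Screening Protein Variants That Disrupt or Create C-Terminal
    PDZ-Binding Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Position weight matrix (PWM) models of PDZ domain binding
    specificity built from C-terminally aligned peptide sets, log-odds
    scoring of protein C-termini, and a two-threshold rule classifying
    missense and stop-gain variants as disrupting, creating, or not
    affecting PDZ-binding motifs. Includes exact binomial and Fisher
    enrichment statistics for C-terminal variant density and
    gold-standard interaction overlap, threshold-sweep and
    randomization-null summaries, a synthetic-data generator with
    planted ground truth, and an end-to-end screening pipeline with
    reproducible tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
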