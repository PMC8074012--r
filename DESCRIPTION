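Package: dirlists
Title: Directional Gene-List Algebra for Treatment-by-Insult Transcriptome Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for factorial treatment-by-insult microarray
    designs in which a candidate neuroprotectant (e.g. magnesium sulfate) is
    given alone and before an insult (e.g. neonatal hypoxia-ischemia).
    Implements probe-level quality control and multi-probe resolution,
    per-timepoint differential calls from two-color log-ratios and one-color
    intensities with Benjamini-Hochberg correction, a directional set algebra
    that classifies genes into proper-treatment, de novo, reversed, amplified
    and insult-insensitive categories, self-contained over-representation
    statistics (Fisher exact, EASE score, fold enrichment), a signed-network
    regulator activation z-score, ontogeny concordance, and a seeded synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
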