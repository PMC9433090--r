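Package: olfstate
Title: State-Dependent Chemoreceptor Expression and Neural Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of feeding-state-dependent olfactory
    receptor expression in C. elegans. Selects fasting-regulated gene sets from
    two-condition abundance tables by fold change, tests chemoreceptor-family
    enrichment globally (Fisher exact test) and per neuron against a binary
    neuron-by-gene expression atlas (Bonferroni-corrected chi-squared test),
    quantifies fluorescent reporters from confocal z-stacks by percentile
    scoring, processes GCaMP calcium traces for freely-moving
    (percentile-baseline dF/F0, peak detection, distance-to-lawn binning) and
    microfluidic (epoch maxima) paradigms, and computes behavioral endpoints
    (chemotaxis index, food-choice index, exploration grid coverage). Includes
    synthetic-data generators with known ground truth for every input class so
    the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
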