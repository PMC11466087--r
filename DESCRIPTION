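Package: radtol
Title: Radiation Tolerance Classification of Bacterial Genomes from Pfam Domain Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial genomes and metagenome-assembled genomes
    (MAGs) as ionizing-radiation tolerant or radiosensitive (D10 below 200 Gy)
    from the relative frequencies of Pfam domains in their annotated
    proteomes. Provides parsers for per-protein Pfam annotation tables and
    EggNOG-Mapper output, the full predictor-selection funnel (universality
    and abundance filters, Boruta shadow-feature selection, stepwise pruning
    by permutation importance), a random-forest classifier with
    missing-predictor accounting, incomplete-MAG robustness simulation by
    annotation subsampling, a D10 estimator for CFU dose-survival assays, and
    a synthetic-cohort generator with planted class-informative domains so
    the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
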