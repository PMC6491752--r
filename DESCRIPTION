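Package: sdindex
Title: Stroke Dysbiosis Index Construction and Evaluation for Gut
    Microbiome Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a case-control dysbiosis signature from genus-level 16S
    abundance tables and condenses it into a single per-sample score, the
    Stroke Dysbiosis Index (SDI): the difference between the mean percent
    relative abundance of stroke-enriched and control-enriched genera,
    scaled by 100. Implements the full analysis pipeline around the index:
    low-abundance filtering, rarefaction, genus collapse, Wilcoxon rank-sum
    differential abundance with Benjamini-Hochberg control, median
    stratification of patients into high- and low-index groups, unweighted
    UniFrac / PCoA / PERMANOVA community comparisons, ROC discrimination,
    Spearman correlation with stroke severity scales, univariate screening
    plus multivariable logistic regression for clinical outcomes, and the
    edema-corrected infarct volume formula used in the companion mouse
    experiments. A Dirichlet-multinomial synthetic cohort generator with a
    planted signature and linked clinical scores makes every stage testable
    without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    picante,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
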