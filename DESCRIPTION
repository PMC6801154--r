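Package: microtrait
Title: Two-Part Microbiome-Phenotype Association, Co-Abundance Networks and
    Microbiome-Explained Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for associating 16S rRNA gene OTU profiles with a continuous
    host phenotype such as weaning weight. Implements rarefaction and
    abundance/prevalence filtering of OTU count tables, covariate
    residualization of the phenotype, the two-part (binary + quantitative +
    unweighted-Z meta-analysis, min-P) association model with permutation-based
    FDR, SparCC compositional correlation with bootstrap pseudo-p-values,
    co-abundance group construction by Ward clustering validated by PERMANOVA,
    Spearman screening of predicted functional features, and estimation of the
    phenotypic variance explained by the microbiome via repeated 80/20
    cross-validation of an additive prediction model. Includes a synthetic-data
    generator with known ground truth for calibration and recovery testing.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    biomformat,
    igraph,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
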