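Package: dsfprog
Title: Joint Structure-Function Prediction of Glaucoma Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring glaucoma progression by jointly modelling a
    structural measurement (neuroretinal rim area or retinal nerve fiber layer
    thickness) and a functional measurement (perimetric mean sensitivity or
    mean deviation) on a common percent-of-mean-normal scale. Implements the
    dynamic structure-function (DSF) predictor, which extrapolates a centroid
    along a velocity vector in the two-dimensional structure-function space,
    together with a per-component ordinary least squares comparator; static
    automated perimetry 30-2/24-2 grid geometry with Garway-Heath sector
    summaries in linear (1/Lambert) units; reliability-based cohort quality
    control; a visits-4-to-7 prediction-error evaluation protocol with paired
    Wilcoxon comparisons and Bland-Altman agreement; and a synthetic
    longitudinal cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
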