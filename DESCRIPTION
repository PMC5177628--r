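Package: nafkit
Title: Non-Aqueous Fractionation Gradient Planning and Subcellular
    Metabolite Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for benchtop non-aqueous fractionation
    (NAF) of plant tissue. Plans heptane-tetrachlorethylene density
    gradients from the binary mixture-density formula, and assigns
    relative and absolute subcellular (plastid/cytosol/vacuole)
    metabolite distributions from marker-enzyme activity profiles and
    metabolite abundance profiles across gradient fractions using a
    pairwise-slope, multi-bound hit-counting algorithm. Includes
    condition comparison (ANOVA with Tukey post-hoc and significance
    marks), z-score scaling with Euclidean hierarchical clustering, and
    a synthetic-experiment generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
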