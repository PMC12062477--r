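Package: mscds
Title: Probabilistic Design Spaces for Mesenchymal Stem Cell Cultivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based determination and validation of probabilistic design
    spaces for adherent mesenchymal stem cell (MSC) cultivation. Implements a
    logistic growth model with seeding-heterogeneity and contact-inhibition
    penalties, per-sample least-squares estimation of the maximum specific
    growth rate, Student-t prediction intervals on that rate, Monte-Carlo
    simulation of upper and lower growth limits over empirical parameter
    pools, probability maps over a seeding-density by harvest-time grid,
    thresholding at a minimum acceptable risk, and precision/recall-style
    validation metrics against experimental feasibility. A synthetic-data
    generator emulating tiled image-based cell counting supports end-to-end
    testing without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
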