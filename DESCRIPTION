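Package: parkshift
Title: Projecting Climate-Driven Change in Protected-Area Bird Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting climate-driven change in the species
    assemblages of protected areas from species distribution model output.
    Classifies per-cell environmental-suitability change between a baseline
    and a warming scenario into five categories (potential extirpation,
    worsening, stable, improving, potential colonisation), summarizes
    projections per park by majority cell count, applies expert-review
    filters, and derives current and future presence sets. Computes
    assemblage metrics (Sorensen and Jaccard turnover, species richness,
    colonisation/extirpation counts, quartile-based trend groups, regional
    summaries), builds a mixed-trait functional space (Gower distance,
    principal coordinates, convex-hull functional richness, scaled
    functional dispersion, taxon restrictedness), and compares current
    versus future index values with model II major-axis regression,
    confidence intervals and permutation tests. Includes a synthetic
    landscape generator with known ground truth for end-to-end testing,
    and a pipeline driver with text-based input/output formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    ape,
    vegan
Config/testthat/edition: 3
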