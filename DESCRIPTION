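Package: migrquant
Title: Quantification of Confined Amoeboid Cell Migration and Vesicle Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of confined amoeboid migration of
    leukemic B cells imaged under agarose. Parses tracking-export spot tables,
    computes per-track migration statistics (total and maximum distance traveled,
    median speed, confinement ratio and its decay, mean square displacement),
    performs replicate-aware SuperPlot statistics (one-way ANOVA with Tukey
    post hoc tests on replicate medians) and transwell normalization (percent of
    input, migration index), and provides a self-contained nucleus detector
    (Laplacian-of-Gaussian) with gap-closing particle linking so movies can be
    analyzed end to end. Two scoring procedures quantify the dispersion of
    punctate endocytic-vesicle signal in single cells: a grid of square regions
    thresholded at twice the minimum median intensity, and prominence-filtered
    local maxima; both end in the per-cell median of all mutual locus distances.
    Synthetic trajectory and image generators with known ground truth make every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    yaml,
    minpack.lm,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
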