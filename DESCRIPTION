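Package: dendrisig
Title: Passive Cable Models and Dendritic Signalling Descriptors for
    Pyramidal Neuron Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds passive compartmental cable models from SWC neuron
    morphologies, folds dendritic spine membrane into per-compartment
    specific parameters, fits specific membrane resistance and capacitance
    to somatic input-resistance and time-constant targets, and computes
    per-site descriptors of subthreshold dendritic signalling (steady-state,
    50-Hz and current transfers, centroid delays, somatic EPSP shape,
    electrotonic distances).  Includes a seeded generator of pyramidal-like
    test morphologies, binned group-comparison graphs with two-way ANOVA,
    Bonferroni post hoc, Kolmogorov-Smirnov and Mann-Whitney statistics, and
    a reproducible end-to-end pipeline for comparing two populations of
    neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
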