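Package: photolim
Title: Partitioning Photosynthetic Limitations in C3 and C4 Cereals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying diffusive and biochemical limitations to
    leaf photosynthesis in C3 (rice, wheat) and C4 (maize) cereals under
    water deficit and high growth temperature. Computes PSII operating
    efficiency and linear electron transport from chlorophyll fluorescence,
    estimates mesophyll conductance and chloroplast CO2 via the variable-J
    method, inverts a von Caemmerer-type C4 model for bundle-sheath CO2,
    reconstructs maximum Rubisco carboxylation rates from 14C assay and
    densitometry data, and partitions photosynthetic inhibition relative to
    a control treatment into stomatal, mesophyll and biochemical components
    following the Grassi-Magnani approach. Includes factorial ANOVA with
    Duncan's multiple range test, a self-consistent synthetic-experiment
    generator for pipeline validation, and a reproducible end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
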