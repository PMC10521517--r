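Package: holotherm
Title: Holobiont Thermal-Stress Assay Analysis for Coral-Symbiodiniaceae
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-holobiont coral thermal-stress
    experiments contrasting Cladocopium- and Durusdinium-dominated
    Pocillopora damicornis. Converts raw assay tables (PAM quantum yields,
    buoyant weights, hemocytometer counts, fate-tracked bleaching census,
    genus-specific qPCR threshold cycles, 13C tracer isotope ratios, ITS2
    clone counts) into derived physiology and symbiont-community metrics:
    maximum excitation pressure over PSII (Qm) and its thermal adjustment
    (dQm), areal calcification rates from buoyant weight, areal symbiont
    densities and bleaching rates, tracer uptake and photosynthate
    translocation fractions, Durusdinium-to-Cladocopium ratios and a
    symbiont shuffling index, zero-adjusted Bray-Curtis ordination with
    complete-linkage grouping, and a consolidated statistical report.
    Includes a seeded synthetic-data generator emulating the crossed
    two-holobiont by two-temperature design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    vegan,
    car,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
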