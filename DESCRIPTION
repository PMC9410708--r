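Package: osmoscale
Title: Colloid Osmotic Models of Nuclear and Cell Size Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying nuclear-to-cell volume ratio
    (N/C ratio) control by colloid osmotic pressure in walled eukaryotic
    cells such as fission yeast. Provides a steady-state nested-osmometer
    model of the cell and its nucleus, Boyle-Van't Hoff analysis of
    osmotic-shift volume measurements, post-tracking nanorheology of 40-nm
    genetically encoded multimeric nanoparticles (MSD, effective
    diffusivity, anomalous exponent, Phillies concentration model), an
    exponential-growth N/C-ratio homeostasis model with its regression
    estimators, perturbation scenarios for nuclear-export block and
    translation inhibition, and seeded synthetic-data generators for every
    input format the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
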