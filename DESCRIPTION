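Package: cardiomd
Title: Microdomain Remodeling and Arrhythmogenic Triggers in Human
    Ventricular Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A family of human ventricular heart-failure myocyte models
    built on the O'Hara-Rudy endocardial action-potential formulation,
    extended with graded transverse-tubule loss, six L-type calcium channel
    subpopulations defined by membrane location and beta-2
    adrenergic/phosphodiesterase association, binary PKA/CaMKII
    phosphorylation populations, a sub-sarcolemmal calcium compartment, and
    redistribution of sodium-calcium exchangers and ryanodine receptors.
    Includes the voltage-clamp and steady-state pacing protocols, decay
    time-constant fitting, APD90 computation, early-afterdepolarization and
    oscillation classification, and parameter-sweep heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
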