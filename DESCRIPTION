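Package: rygbcat
Title: Compartmental Absorption and Transit Modeling of Oral Drug
    Absorption after Roux-en-Y Gastric Bypass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A nine-compartment gut absorption-transit (CAT/ACAT-style)
    simulator with one-compartment disposition for predicting oral drug
    pharmacokinetics before and after Roux-en-Y gastric bypass (RYGB).
    Includes single-pass intestinal perfusion (SPIP) effective-permeability
    estimation with gravimetric water-flux correction, rat-to-human
    permeability scaling, a Renkin hindered-diffusion paracellular pore
    model, an RYGB physiology transform that bypasses the duodenum and
    proximal jejunum, scenario calibration of a single permeability
    multiplier against an AUC anchor, noncompartmental PK metric
    extraction, and synthetic-data generators for perfusion series and
    noisy plasma profiles. Ships a metformin parameterization of healthy,
    obese-control and post-RYGB subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
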