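# Shared fixtures. The calibrated pipeline is deterministic and cheap
# (~1 s) but several files inspect it, so it is computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

get_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- run_rygb_pipeline()
  }
  .fixture_env$pipeline
}

# A perfusion record row with sensible protocol defaults.
make_record <- function(outlet_conc_uM, inlet_conc_uM = 50,
                        inlet_mass_g = 2, outlet_mass_g = 2,
                        flow_mL_min = 0.2, segment = "jejunum",
                        pH = 6.5, time_min = 70) {
  data.frame(flow_mL_min = flow_mL_min, inlet_conc_uM = inlet_conc_uM,
             outlet_conc_uM = outlet_conc_uM, inlet_mass_g = inlet_mass_g,
             outlet_mass_g = outlet_mass_g, interval_min = 10,
             segment = segment, pH = pH, time_min = time_min,
             stringsAsFactors = FALSE)
}

# Direct evaluation of the SPIP formula, independent of estimate_peff().
peff_formula <- function(q_mL_min, ratio, radius_cm, length_cm) {
  -(q_mL_min / 60) * log(ratio) / (2 * pi * radius_cm * length_cm)
}
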