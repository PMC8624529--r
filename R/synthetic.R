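# Synthetic-data generators. Every estimator in the package can be exercised
# without any external data: the perfusion generator inverts the SPIP
# log-loss model and the plasma generator samples the simulator's own output.
# Noise is multiplicative lognormal (concentrations are positive and assay
# error is relative); net water flux is constant per run (steady state).

#' Specification of a synthetic SPIP perfusion series
#'
#' @param true_peff_cm_s True effective permeability, cm/s.
#' @param flow_mL_min Perfusate flow Q, mL/min (protocol default 0.2).
#' @param inlet_conc_uM Inlet drug concentration, uM (protocol default 50).
#' @param radius_cm Segment radius, cm (protocol default 0.2).
#' @param length_cm Segment length, cm (protocol default 10).
#' @param n_samples Number of steady-state sampling intervals (protocol: 6
#'   samples every 10 min over the post-equilibration hour).
#' @param noise_cv Relative assay noise (lognormal CV) on the outlet
#'   concentration.
#' @param net_water_flux Fraction of the inlet mass absorbed as water per
#'   interval (negative = net secretion); |flux| < 1. Water absorption
#'   concentrates the outlet stream by 1/(1 - flux), which the gravimetric
#'   correction exactly undoes.
#' @param segment Segment label.
#' @param pH Perfusate pH.
#' @param seed Integer seed; the series is reproducible under a fixed seed.
#' @return A `spip_sim_spec` list.
#' @export
spip_sim_spec <- function(true_peff_cm_s, flow_mL_min = 0.2,
                          inlet_conc_uM = 50, radius_cm = 0.2,
                          length_cm = 10, n_samples = 6L, noise_cv = 0.05,
                          net_water_flux = 0, segment = "jejunum",
                          pH = 6.5, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (abs(net_water_flux) >= 1) stop("|net_water_flux| must be < 1")
  if (true_peff_cm_s < 0) stop("true_peff_cm_s must be >= 0")
  structure(
    list(true_peff_cm_s = true_peff_cm_s, flow_mL_min = flow_mL_min,
         inlet_conc_uM = inlet_conc_uM, radius_cm = radius_cm,
         length_cm = length_cm, n_samples = as.integer(n_samples),
         noise_cv = noise_cv, net_water_flux = net_water_flux,
         segment = segment, pH = pH, seed = as.integer(seed)),
    class = "spip_sim_spec"
  )
}

#' Generate a synthetic SPIP perfusion series
#'
#' Forward model of the steady-state perfusion: the noiseless outlet/inlet
#' ratio is exp(-2 pi R L Peff / Q) (Q in cm^3/s), multiplied by
#' 1/(1 - net_water_flux) for the concentrating effect of water absorption,
#' then perturbed by multiplicative lognormal noise with the requested CV.
#' Collected masses follow the water flux: outlet_mass =
#' inlet_mass x (1 - flux). Samples are placed at 10-min intervals starting
#' at t = 70 min (the first post-equilibration collection).
#'
#' @param spec A [spip_sim_spec()].
#' @return A `perfusion_records` data frame with `spec$n_samples` rows.
#' @export
synth_spip <- function(spec) {
  stopifnot(inherits(spec, "spip_sim_spec"))
  q_cm3_s <- spec$flow_mL_min / 60
  ratio_true <- exp(-2 * pi * spec$radius_cm * spec$length_cm *
                      spec$true_peff_cm_s / q_cm3_s)
  inlet_mass <- spec$flow_mL_min * 10  # 10-min collection, density 1 g/mL
  outlet_mass <- inlet_mass * (1 - spec$net_water_flux)

  noise <- withr_seed(spec$seed, {
    if (spec$noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      exp(stats::rnorm(spec$n_samples, -sdlog^2 / 2, sdlog))
    } else rep(1, spec$n_samples)
  })
  cout <- spec$inlet_conc_uM * ratio_true / (1 - spec$net_water_flux) * noise

  perfusion_records(data.frame(
    flow_mL_min = spec$flow_mL_min,
    inlet_conc_uM = spec$inlet_conc_uM,
    outlet_conc_uM = cout,
    inlet_mass_g = inlet_mass,
    outlet_mass_g = outlet_mass,
    interval_min = 10,
    segment = spec$segment,
    pH = spec$pH,
    time_min = 70 + 10 * (seq_len(spec$n_samples) - 1),
    stringsAsFactors = FALSE
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a noisy synthetic plasma profile from a scenario
#'
#' Simulates the named scenario and samples its plasma profile at the
#' requested times with multiplicative lognormal noise — a stand-in for
#' observed concentration-time data with the one-compartment disposition
#' structure the analysis assumes.
#'
#' @param scenario_name One of the packaged scenario names.
#' @param times_h Sampling times, h (within the simulation horizon).
#' @param noise_cv Relative noise CV (0 returns the simulator output
#'   exactly).
#' @param seed Integer seed.
#' @param multiplier Permeability multiplier for the underlying scenario.
#' @param settings [simulation_settings()].
#' @return A data frame `time_h`, `conc_ng_mL` with attribute `scenario`.
#' @export
synth_plasma <- function(scenario_name, times_h = seq(0.5, 24, by = 0.5),
                         noise_cv = 0.1, seed = 1L, multiplier = 1,
                         settings = simulation_settings()) {
  if (any(times_h < 0) || any(times_h > settings$t_end_h)) {
    stop("sampling times must lie within the simulation horizon")
  }
  sc <- build_scenario(scenario_name, multiplier = multiplier)
  res <- simulate_scenario(sc, settings)
  conc <- stats::approx(res$time_h, res$plasma_conc_ng_mL, xout = times_h)$y
  noise <- withr_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      exp(stats::rnorm(length(times_h), -sdlog^2 / 2, sdlog))
    } else rep(1, length(times_h))
  })
  out <- data.frame(time_h = times_h, conc_ng_mL = conc * noise)
  attr(out, "scenario") <- scenario_name
  out
}
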