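# Configuration loading/validation and result writers. Scenario configs are
# YAML; tabular outputs are plain CSV with unit-suffixed column names; a JSON
# manifest records the inputs hash, package version and tolerances so a run
# can be reproduced byte-for-byte.

SCENARIO_CONFIG_KEYS <- c("scenario", "multiplier", "base_peff_cm_s",
                          "segment_ratios", "duodenal_ratio", "colon_factor",
                          "settings")
SETTINGS_KEYS <- c("t_end_h", "output_step_h", "rtol", "atol", "colonic_asf")

#' Load and validate a scenario configuration file
#'
#' A scenario config is a YAML mapping with a required `scenario` key (one
#' of the packaged scenario names) and optional keys `multiplier`,
#' `base_peff_cm_s`, `segment_ratios` (mapping with `jejunum`, `mid_SI`,
#' `ileum`), `duodenal_ratio`, `colon_factor`, and `settings` (mapping with
#' any of `t_end_h`, `output_step_h`, `rtol`, `atol`, `colonic_asf`).
#' Unknown keys are rejected; every schema violation is reported at once;
#' defaults are injected for omitted optional keys.
#'
#' @param path Path to a YAML file.
#' @return A list with `scenario` (a validated `scenario` object) and
#'   `settings` (a `simulation_settings`).
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0) {
    stop("config schema error: file '", path, "' is empty")
  }
  if (!is.list(raw)) stop("config schema error: top level must be a mapping")

  problems <- character(0)
  unknown <- setdiff(names(raw), SCENARIO_CONFIG_KEYS)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$scenario)) {
    problems <- c(problems, "missing required key: scenario")
  } else if (!raw$scenario %in% SCENARIO_NAMES) {
    problems <- c(problems, paste0("scenario must be one of: ",
                                   paste(SCENARIO_NAMES, collapse = ", ")))
  }
  num_keys <- c("multiplier", "base_peff_cm_s", "duodenal_ratio", "colon_factor")
  for (k in num_keys) {
    v <- raw[[k]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1 || v < 0)) {
      problems <- c(problems, paste0(k, " must be a single non-negative number"))
    }
  }
  if (!is.null(raw$multiplier) && is.numeric(raw$multiplier) && raw$multiplier <= 0) {
    problems <- c(problems, "multiplier must be > 0")
  }
  if (!is.null(raw$segment_ratios)) {
    sr <- raw$segment_ratios
    if (!is.list(sr) || !all(c("jejunum", "mid_SI", "ileum") %in% names(sr))) {
      problems <- c(problems,
                    "segment_ratios must provide jejunum, mid_SI and ileum")
    } else if (any(unlist(sr) < 0)) {
      problems <- c(problems, "segment_ratios must be >= 0")
    }
  }
  settings_raw <- raw$settings
  if (!is.null(settings_raw)) {
    bad <- setdiff(names(settings_raw), SETTINGS_KEYS)
    if (length(bad) > 0) {
      problems <- c(problems,
                    paste0("unknown settings key(s): ", paste(bad, collapse = ", ")))
    }
    for (k in intersect(names(settings_raw), SETTINGS_KEYS)) {
      v <- settings_raw[[k]]
      if (!is.numeric(v) || length(v) != 1 || v <= 0) {
        problems <- c(problems, paste0("settings$", k, " must be a positive number"))
      }
    }
  }
  if (length(problems) > 0) {
    stop("config schema error in '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "))
  }

  settings_args <- settings_raw[intersect(names(settings_raw), SETTINGS_KEYS)]
  settings <- do.call(simulation_settings, as.list(settings_args))

  build_args <- list(name = raw$scenario)
  if (!is.null(raw$multiplier)) build_args$multiplier <- raw$multiplier
  if (!is.null(raw$base_peff_cm_s)) build_args$base_peff_cm_s <- raw$base_peff_cm_s
  if (!is.null(raw$segment_ratios)) {
    build_args$segment_ratios <- unlist(raw$segment_ratios)[c("jejunum", "mid_SI", "ileum")]
  }
  if (!is.null(raw$duodenal_ratio)) build_args$duodenal_ratio <- raw$duodenal_ratio
  if (!is.null(raw$colon_factor)) build_args$colon_factor <- raw$colon_factor
  scenario <- do.call(build_scenario, build_args)

  list(scenario = scenario, settings = settings, config_path = path)
}

#' Write a scenario configuration file
#'
#' Inverse of [load_scenario_config()]: any shipped or loaded configuration
#' round-trips load -> dump -> load to an identical scenario.
#'
#' @param scenario A `scenario`.
#' @param settings A `simulation_settings`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, settings, path) {
  cfg <- list(
    scenario = scenario$name,
    multiplier = scenario$multiplier,
    base_peff_cm_s = scenario$base_peff_cm_s,
    segment_ratios = as.list(scenario$segment_ratios),
    duodenal_ratio = scenario$duodenal_ratio,
    colon_factor = scenario$colon_factor,
    settings = list(t_end_h = settings$t_end_h,
                    output_step_h = settings$output_step_h,
                    rtol = settings$rtol, atol = settings$atol,
                    colonic_asf = settings$colonic_asf)
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Write the standard output file set of a run
#'
#' Writes four files into `outdir`: `plasma_profile.csv` (`time_h`,
#' `conc_ng_per_mL`), `regional_absorption.csv` (compartment, fraction of
#' dose), `metrics.json` (the five PK metrics), and `manifest.json`
#' (package version, MD5 of the config file if given, integration
#' tolerances, mass-balance residual). Reruns with an identical config
#' produce byte-identical CSVs.
#'
#' @param result A `simulation_result`.
#' @param metrics A `pk_metrics`.
#' @param outdir Output directory (created if needed).
#' @param config_path Optional path of the config that produced the run;
#'   its MD5 hash goes into the manifest.
#' @return Character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(result, metrics, outdir, config_path = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  profile_path <- file.path(outdir, "plasma_profile.csv")
  regional_path <- file.path(outdir, "regional_absorption.csv")
  metrics_path <- file.path(outdir, "metrics.json")
  manifest_path <- file.path(outdir, "manifest.json")

  utils::write.csv(
    data.frame(time_h = result$time_h,
               conc_ng_per_mL = result$plasma_conc_ng_mL),
    profile_path, row.names = FALSE)

  frac <- regional_absorption(result)
  utils::write.csv(
    data.frame(compartment = names(frac), fraction_of_dose = as.numeric(frac)),
    regional_path, row.names = FALSE)

  jsonlite::write_json(unclass(metrics), metrics_path,
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "rygbcat",
    version = as.character(utils::packageVersion("rygbcat")),
    config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path))
                 else NA,
    dose_mg = result$dose_mg,
    t_end_h = max(result$time_h),
    rtol = result$settings$rtol,
    atol = result$settings$atol,
    mass_balance_residual_mg = result$mass_balance_residual_mg
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(c(profile_path, regional_path, metrics_path, manifest_path))
}
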