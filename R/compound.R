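# Compound physicochemistry and disposition parameters. The packaged default
# is metformin: MW 129.17, a strong monobase (pKa 11.5), very hydrophilic
# (LogD -3.37 at pH 4), low cell-monolayer permeability (Papp 0.05e-5 cm/s),
# immediate-release tablets of 500 or 1000 mg.

#' Compound profile
#'
#' Physicochemical and dosing parameters of the simulated drug.
#'
#' @param name Compound name.
#' @param molecular_weight MW, g/mol (> 0).
#' @param pKa Basic-center pKa.
#' @param logD_pH4 Distribution coefficient at pH 4.
#' @param solubility_mg_mL Reference solubility, mg/mL.
#' @param solubility_pH pH at which the reference solubility was determined.
#' @param papp_cm_s Cell-monolayer apparent permeability, cm/s (>= 0).
#' @param dose_mg Oral dose, mg (> 0).
#' @param dosage_form Only `immediate_release` is supported.
#' @param water_mL Volume of water co-administered with the dose, mL.
#' @return A `compound_profile` list.
#' @export
compound_profile <- function(name, molecular_weight, pKa, logD_pH4,
                             solubility_mg_mL, solubility_pH, papp_cm_s,
                             dose_mg, dosage_form = "immediate_release",
                             water_mL = 250) {
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (dose_mg <= 0) stop("dose_mg must be > 0")
  if (papp_cm_s < 0) stop("papp_cm_s must be >= 0")
  dosage_form <- match.arg(dosage_form, "immediate_release")
  structure(
    list(name = name, molecular_weight = molecular_weight, pKa = pKa,
         logD_pH4 = logD_pH4, solubility_mg_mL = solubility_mg_mL,
         solubility_pH = solubility_pH, papp_cm_s = papp_cm_s,
         dose_mg = dose_mg, dosage_form = dosage_form, water_mL = water_mL),
    class = "compound_profile"
  )
}

#' Packaged metformin profile
#'
#' @param dose_mg Oral dose, mg (500 for the healthy-subject study, 1000 for
#'   the obese-control / post-RYGB study).
#' @param water_mL Co-administered water, mL (200 in the healthy-subject
#'   study, 250 standard otherwise).
#' @return A `compound_profile` for metformin.
#' @export
metformin_profile <- function(dose_mg = 1000, water_mL = 250) {
  compound_profile(
    name = "metformin", molecular_weight = 129.17, pKa = 11.5,
    logD_pH4 = -3.37, solubility_mg_mL = 100.05, solubility_pH = 12.24,
    papp_cm_s = 0.05e-5, dose_mg = dose_mg, water_mL = water_mL
  )
}

#' One-compartment disposition parameters
#'
#' @param body_weight_kg Body weight, kg.
#' @param clearance_L_h_kg Renal clearance, L/h/kg.
#' @param vd_L_kg Volume of distribution, L/kg.
#' @return A `pk_parameters` list. All values must be > 0.
#' @export
pk_parameters <- function(body_weight_kg, clearance_L_h_kg, vd_L_kg) {
  if (body_weight_kg <= 0 || clearance_L_h_kg <= 0 || vd_L_kg <= 0) {
    stop("all PK parameters must be > 0")
  }
  structure(
    list(body_weight_kg = body_weight_kg,
         clearance_L_h_kg = clearance_L_h_kg,
         vd_L_kg = vd_L_kg),
    class = "pk_parameters"
  )
}

#' Cationic (protonated) fraction of a monobase
#'
#' Henderson-Hasselbalch for a single basic center:
#' f = 1 / (1 + 10^(pH - pKa)). Metformin (pKa 11.5) is essentially fully
#' protonated at every gut pH, which motivates excluding gastric absorption
#' and treating dissolution as pH-independent.
#'
#' @param pKa Basic pKa.
#' @param pH Ambient pH (vectorized).
#' @return Protonated fraction in \[0, 1\].
#' @examples
#' cationic_fraction(11.5, 6.5)
#' @export
cationic_fraction <- function(pKa, pH) {
  1 / (1 + 10^(pH - pKa))
}

#' Dose number
#'
#' Dose / (solubility x administered fluid volume). Values well below 1 mean
#' the full dose dissolves in the co-administered fluid, so dissolution is
#' not rate-limiting and the simulator may treat the dose as entering the
#' stomach in solution.
#'
#' @param dose_mg Dose, mg.
#' @param solubility_mg_mL Solubility, mg/mL (> 0).
#' @param volume_mL Administered fluid volume, mL (> 0).
#' @return Dimensionless dose number.
#' @examples
#' dose_number(500, 100.05, 200)
#' @export
dose_number <- function(dose_mg, solubility_mg_mL, volume_mL) {
  if (volume_mL <= 0) stop("volume_mL must be > 0")
  if (solubility_mg_mL <= 0) stop("solubility_mg_mL must be > 0")
  dose_mg / (solubility_mg_mL * volume_mL)
}
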