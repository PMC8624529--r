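# Permeability conversions: rat -> human scaling, the paracellular pore
# (Renkin hindered-diffusion) model, and assignment of segmental values to
# the gut compartments.

#' Scale rat effective permeability to human
#'
#' Human jejunal effective permeability correlates linearly with rat SPIP
#' permeability: Peff,human = 3.6 x Peff,rat + 0.03e-4 (cm/s).
#'
#' @param peff_rat Rat Peff, cm/s (vectorized, >= 0).
#' @return Human Peff, cm/s.
#' @examples
#' rat_to_human(2.795e-5)
#' @export
rat_to_human <- function(peff_rat) {
  if (any(peff_rat < 0)) stop("rat Peff must be >= 0")
  3.6 * peff_rat + 0.03e-4
}

#' Renkin hindered-diffusion sieving factor
#'
#' Fractional reduction of diffusion through a cylindrical water-filled pore
#' for a solute of radius lambda x pore radius:
#' (1 - lambda)^2 (1 - 2.104 lambda + 2.09 lambda^3 - 0.95 lambda^5),
#' clamped to 0 for lambda >= 1 (size exclusion).
#'
#' @param lambda Ratio molecular radius / pore radius (>= 0, vectorized).
#' @return Sieving factor in \[0, 1\].
#' @export
renkin_factor <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  f <- (1 - lambda)^2 *
    (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
  f[lambda >= 1] <- 0
  pmax(f, 0)
}

#' Paracellular pore model
#'
#' A single-pore description of tight-junction permeability: a capacity
#' prefactor (aggregating porosity, aqueous diffusivity and path length, on
#' the cm/s scale) times the Renkin sieving factor at the solute's
#' molecular radius. Hydrophilic cations like metformin cross the intestinal
#' wall predominantly (about 90%) by this route.
#'
#' @param pore_radius_A Pore radius, Angstrom (> 0).
#' @param capacity_cm_s Capacity prefactor, cm/s (>= 0).
#' @param molecular_radius_A Solute radius, Angstrom (>= 0).
#' @return A `paracellular_model` list.
#' @export
paracellular_model <- function(pore_radius_A, capacity_cm_s, molecular_radius_A = NA_real_) {
  if (pore_radius_A <= 0) stop("pore_radius_A must be > 0")
  if (capacity_cm_s < 0) stop("capacity_cm_s must be >= 0")
  if (!is.na(molecular_radius_A) && molecular_radius_A < 0) {
    stop("molecular_radius_A must be >= 0")
  }
  structure(
    list(pore_radius_A = pore_radius_A, capacity_cm_s = capacity_cm_s,
         molecular_radius_A = molecular_radius_A),
    class = "paracellular_model"
  )
}

#' Paracellular effective permeability
#'
#' @param model A [paracellular_model()] with `molecular_radius_A` set.
#' @return Peff, cm/s: capacity x Renkin factor at lambda =
#'   molecular_radius / pore_radius. Monotone non-increasing in the
#'   molecular radius.
#' @export
paracellular_peff <- function(model) {
  if (is.na(model$molecular_radius_A)) stop("molecular_radius_A is not set")
  model$capacity_cm_s * renkin_factor(model$molecular_radius_A / model$pore_radius_A)
}

#' Fit the molecular radius to a target paracellular fraction
#'
#' The paracellular:transcellular split for a compound (90:10 for metformin)
#' is enforced by adjusting the molecular radius until
#' paracellular / (paracellular + transcellular) equals the target. The
#' fraction is strictly decreasing in the radius, so the root is found by
#' bracketing on (0, pore radius).
#'
#' @param target_fraction Target paracellular fraction, in (0, 1).
#' @param trans_peff_cm_s Transcellular Peff, cm/s (> 0).
#' @param model A [paracellular_model()]; its `molecular_radius_A` is ignored.
#' @param tol Convergence tolerance on the fraction (default 1e-6).
#' @return Molecular radius in Angstrom achieving the target fraction.
#' @examples
#' m <- paracellular_model(pore_radius_A = 6, capacity_cm_s = 1e-4)
#' r <- fit_molecular_radius(0.9, trans_peff_cm_s = 1e-6, model = m)
#' @export
fit_molecular_radius <- function(target_fraction, trans_peff_cm_s, model, tol = 1e-6) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0, 1)")
  }
  if (trans_peff_cm_s <= 0) stop("trans_peff_cm_s must be > 0")
  frac_at <- function(r) {
    p <- model$capacity_cm_s * renkin_factor(r / model$pore_radius_A)
    p / (p + trans_peff_cm_s)
  }
  max_frac <- frac_at(0)
  if (max_frac < target_fraction) {
    stop(sprintf(
      "target paracellular fraction %.3f unreachable: maximum %.3f at zero radius (capacity too small)",
      target_fraction, max_frac))
  }
  root <- stats::uniroot(function(r) frac_at(r) - target_fraction,
                         lower = 0, upper = model$pore_radius_A,
                         tol = tol * model$pore_radius_A * 1e-3)
  root$root
}

#' Assign measured segmental permeabilities to the gut compartments
#'
#' Maps the three perfused rat segments onto the eight post-stomach model
#' compartments: jejunal Peff to jejunum1/jejunum2, mid-small-intestine to
#' ileum1, ileal to ileum2/ileum3, and colon (caecum, ascending colon) as
#' `colon_factor` times the ileal value — metformin-like drugs absorb poorly
#' from the colon and no colonic measurement exists. The duodenal value is
#' supplied separately (it comes from the literature, not the perfusion
#' assay). Bypassed compartments keep their assigned value but are ignored
#' by the simulator.
#'
#' @param measured Named numeric: human Peff (cm/s) for `jejunum`, `mid_SI`,
#'   `ileum`.
#' @param duodenal_peff Human duodenal Peff, cm/s.
#' @param physiology A `gut_physiology` (used for compartment identity).
#' @param colon_factor Colonic Peff as a fraction of ileal, in \[0, 1\]
#'   (default 0.1).
#' @param provenance Provenance label: `single_value`, `segmental_measured`
#'   or `calibrated`.
#' @return A `segmental_permeability`: named numeric vector over the eight
#'   intestinal compartments with a `provenance` attribute.
#' @export
assign_segments <- function(measured, duodenal_peff, physiology,
                            colon_factor = 0.1,
                            provenance = "segmental_measured") {
  need <- c("jejunum", "mid_SI", "ileum")
  missing_seg <- setdiff(need, names(measured))
  if (length(missing_seg) > 0) {
    stop("measured permeability map missing segment(s): ",
         paste(missing_seg, collapse = ", "))
  }
  if (any(unlist(measured[need]) < 0) || duodenal_peff < 0) {
    stop("permeabilities must be >= 0")
  }
  if (colon_factor < 0 || colon_factor > 1) stop("colon_factor must be in [0, 1]")
  validate_physiology(physiology)
  perm <- c(
    duodenum  = unname(duodenal_peff),
    jejunum1  = unname(measured[["jejunum"]]),
    jejunum2  = unname(measured[["jejunum"]]),
    ileum1    = unname(measured[["mid_SI"]]),
    ileum2    = unname(measured[["ileum"]]),
    ileum3    = unname(measured[["ileum"]]),
    caecum    = colon_factor * unname(measured[["ileum"]]),
    asc_colon = colon_factor * unname(measured[["ileum"]])
  )
  segmental_permeability(perm, provenance)
}

#' Construct a segmental permeability set
#'
#' @param values Named numeric vector of human Peff (cm/s) covering the
#'   eight post-stomach compartments.
#' @param provenance One of `single_value`, `segmental_measured`, `calibrated`.
#' @return A `segmental_permeability` object.
#' @export
segmental_permeability <- function(values,
                                   provenance = c("single_value",
                                                  "segmental_measured",
                                                  "calibrated")) {
  provenance <- match.arg(provenance)
  missing_cmp <- setdiff(INTESTINAL_COMPARTMENTS, names(values))
  if (length(missing_cmp) > 0) {
    stop("permeability set missing compartment(s): ",
         paste(missing_cmp, collapse = ", "))
  }
  if (any(values < 0)) stop("permeabilities must be >= 0")
  out <- values[INTESTINAL_COMPARTMENTS]
  attr(out, "provenance") <- provenance
  class(out) <- "segmental_permeability"
  out
}

#' @export
print.segmental_permeability <- function(x, ...) {
  cat(sprintf("<segmental_permeability (%s), cm/s>\n", attr(x, "provenance")))
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}
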