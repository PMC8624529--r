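# Canonical anatomical order of the nine gut compartments. The model ends at
# the ascending colon; transverse/descending colon are outside the absorptive
# window considered here.
GUT_COMPARTMENTS <- c(
  "stomach", "duodenum", "jejunum1", "jejunum2",
  "ileum1", "ileum2", "ileum3", "caecum", "asc_colon"
)

# Post-stomach compartments that can carry a permeability value.
INTESTINAL_COMPARTMENTS <- GUT_COMPARTMENTS[-1]

#' Default fasted gut physiology
#'
#' Returns the nine-compartment fasted-state gut physiology (stomach through
#' ascending colon) used as the pre-surgery baseline: compartment pH, mean
#' transit time, resting fluid volume and anatomical length. The absorption
#' scale factor (`asf`) defaults to 1 for every compartment; colonic
#' attenuation is applied separately by the simulator (see
#' [simulation_settings()]).
#'
#' @return A `gut_physiology` object: a data frame with one row per
#'   compartment and columns `name`, `pH`, `transit_h`, `volume_mL`,
#'   `length_cm`, `asf`, `bypassed`.
#' @seealso [apply_rygb()], [compartment_radius()]
#' @examples
#' phys <- default_fasted_physiology()
#' phys[phys$name == "jejunum1", ]
#' @export
default_fasted_physiology <- function() {
  phys <- data.frame(
    name      = GUT_COMPARTMENTS,
    pH        = c(1.3, 6.00, 6.20, 6.40, 6.60, 6.90, 7.40, 6.40, 6.80),
    transit_h = c(0.25, 0.26, 0.95, 0.73, 0.59, 0.43, 0.31, 4.50, 13.50),
    volume_mL = c(50.00, 48.25, 175.3, 139.90, 108.5, 79.48, 56.29, 52.92, 56.98),
    length_cm = c(30, 15.00, 62.00, 62.00, 62.00, 62.00, 62.00, 13.75, 29.02),
    asf       = rep(1, 9),
    bypassed  = rep(FALSE, 9),
    stringsAsFactors = FALSE
  )
  class(phys) <- c("gut_physiology", "data.frame")
  validate_physiology(phys)
  phys
}

#' Validate a gut physiology object
#'
#' Checks the structural invariants of a nine-compartment physiology:
#' compartment identity and order, physical ranges (pH in \[1, 9\],
#' non-negative transit times, volumes, lengths), the bypass flag being
#' consistent with zeroed transit/volume/length, and at least one open
#' (non-bypassed) intestinal compartment downstream of the stomach.
#'
#' @param phys A `gut_physiology` data frame.
#' @return `phys`, invisibly, if valid; otherwise an error naming every
#'   violated field.
#' @export
validate_physiology <- function(phys) {
  problems <- character(0)
  need <- c("name", "pH", "transit_h", "volume_mL", "length_cm", "asf", "bypassed")
  missing_cols <- setdiff(need, names(phys))
  if (length(missing_cols) > 0) {
    stop("physiology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(phys) != 9L) {
    problems <- c(problems, sprintf("expected 9 compartments, got %d", nrow(phys)))
  }
  if (!identical(as.character(phys$name), GUT_COMPARTMENTS[seq_len(nrow(phys))])) {
    problems <- c(problems, "compartment names/order must be stomach..asc_colon")
  }
  if (any(phys$pH < 1 | phys$pH > 9)) problems <- c(problems, "pH outside [1, 9]")
  for (col in c("transit_h", "volume_mL", "length_cm")) {
    if (any(phys[[col]] < 0)) problems <- c(problems, paste0(col, " must be >= 0"))
  }
  if (any(phys$asf < 0)) problems <- c(problems, "asf must be >= 0")
  zeroed <- phys$transit_h == 0 & phys$volume_mL == 0 & phys$length_cm == 0
  if (any(phys$bypassed != zeroed)) {
    problems <- c(problems,
      "bypassed flag must match (transit_h == 0 & volume_mL == 0 & length_cm == 0)")
  }
  if (nrow(phys) == 9L && !any(!phys$bypassed[-1])) {
    problems <- c(problems, "all intestinal compartments are bypassed")
  }
  if (length(problems) > 0) {
    stop("invalid gut physiology:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(phys)
}

#' Apply the Roux-en-Y gastric bypass transform
#'
#' Converts a pre-surgery physiology into the post-RYGB state: the stomach
#' becomes a small, near-neutral pouch (pH 6.4, transit 0.12 h, 30 mL, 18 cm)
#' and the duodenum and proximal jejunum (jejunum1) are bypassed by setting
#' their transit time, volume and length to zero. Bypassed compartments are
#' retained in the table (flagged `bypassed = TRUE`) so that compartment
#' indexing stays stable across scenarios; the simulator routes gastric
#' outflow directly into the first open compartment (jejunum2).
#'
#' @param phys A `gut_physiology` with no bypassed compartments.
#' @return The transformed `gut_physiology`.
#' @examples
#' post <- apply_rygb(default_fasted_physiology())
#' post[post$bypassed, "name"]
#' @export
apply_rygb <- function(phys) {
  validate_physiology(phys)
  if (any(phys$bypassed)) {
    stop("physiology already contains bypassed compartments; ",
         "apply_rygb() expects an intact pre-surgery physiology")
  }
  phys[phys$name == "stomach", c("pH", "transit_h", "volume_mL", "length_cm")] <-
    list(6.4, 0.12, 30, 18)
  gone <- phys$name %in% c("duodenum", "jejunum1")
  phys[gone, c("transit_h", "volume_mL", "length_cm")] <- list(0, 0, 0)
  phys$bypassed[gone] <- TRUE
  validate_physiology(phys)
  phys
}

#' Cylindrical compartment radius from volume and length
#'
#' The gut physiology table stores only compartment volume and length; the
#' radius used for the absorption rate constant (ka = 2 Peff / R) is derived
#' assuming a cylinder: R = sqrt(V / (pi L)), with V in mL (= cm^3) and L in
#' cm.
#'
#' @param volume_mL Compartment fluid volume, mL. Must be > 0.
#' @param length_cm Compartment length, cm. Must be > 0.
#' @return Radius in cm (vectorized).
#' @examples
#' compartment_radius(175.3, 62) # jejunum1, ~0.949 cm
#' @export
compartment_radius <- function(volume_mL, length_cm) {
  if (any(volume_mL <= 0) || any(length_cm <= 0)) {
    stop("compartment_radius() requires volume and length > 0 ",
         "(bypassed compartments have no radius)")
  }
  sqrt(volume_mL / (pi * length_cm))
}

#' Read / write a gut physiology as YAML
#'
#' A physiology serializes to a YAML list with one block per compartment,
#' preserving every field exactly; reading validates the result. `physiology_csv()`
#' writes the same table as a plain CSV for reports.
#'
#' @param path File path.
#' @param phys A `gut_physiology`.
#' @return `read_physiology()` returns a validated `gut_physiology`;
#'   the writers return `path` invisibly.
#' @export
write_physiology <- function(phys, path) {
  validate_physiology(phys)
  blocks <- lapply(seq_len(nrow(phys)), function(i) {
    as.list(phys[i, , drop = FALSE])
  })
  names(blocks) <- phys$name
  yaml::write_yaml(list(compartments = blocks), path, precision = 15L)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$compartments)) stop("physiology file lacks a 'compartments' block")
  rows <- lapply(raw$compartments, function(b) {
    data.frame(
      name = b$name, pH = b$pH, transit_h = b$transit_h,
      volume_mL = b$volume_mL, length_cm = b$length_cm,
      asf = b$asf, bypassed = b$bypassed, stringsAsFactors = FALSE
    )
  })
  phys <- do.call(rbind, rows)
  rownames(phys) <- NULL
  class(phys) <- c("gut_physiology", "data.frame")
  validate_physiology(phys)
  phys
}

#' @rdname write_physiology
#' @export
physiology_csv <- function(phys, path) {
  validate_physiology(phys)
  utils::write.csv(as.data.frame(phys), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.gut_physiology <- function(x, ...) {
  state <- if (any(x$bypassed)) "post-RYGB" else "intact"
  cat(sprintf("<gut_physiology: 9 compartments, %s>\n", state))
  print(as.data.frame(x), ...)
  invisible(x)
}
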