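# Electro-donating/accepting powers and the donor-acceptor map (DAM).
#
# omega_minus = (3I + A)^2 / (16 (I - A))   propensity to donate charge
# omega_plus  = (I + 3A)^2 / (16 (I - A))   propensity to accept charge
# Rd = omega_minus(compound) / omega_minus(Na), Ra = omega_plus(compound) /
# omega_plus(F): both indices are dimensionless ratios against the atomic
# anchors, so the DAM places sodium at Rd = 1 and fluorine at Ra = 1.

check_ia_gap <- function(I, A, compound_id, what) {
  if (any(I <= A)) {
    bad <- rep_len(compound_id, length(I))[I <= A]
    stop("degenerate (I <= A) in ", what, " for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
}

#' Electro-donating power
#'
#' `omega_minus = (3I + A)^2 / (16 (I - A))` in eV. Lower values mean a
#' better electron donor (charge leaves more easily).
#'
#' @param I,A Vertical ionization potential and electron affinity, eV;
#'   vectors recycled. Requires `I > A`.
#' @param compound_id Identifier(s) used in error messages.
#' @return omega_minus in eV.
#' @export
#' @examples
#' donating_power(7.15, 0.07)   # 4.09 (2 dp)
donating_power <- function(I, A, compound_id = "compound") {
  stopifnot(is.numeric(I), is.numeric(A), all(is.finite(I)), all(is.finite(A)))
  check_ia_gap(I, A, compound_id, "donating_power")
  (3 * I + A)^2 / (16 * (I - A))
}

#' Electro-accepting power
#'
#' `omega_plus = (I + 3A)^2 / (16 (I - A))` in eV. Higher values mean a
#' better electron acceptor. The identity
#' `omega_minus - omega_plus == (I + A)/2 == chi` holds algebraically.
#'
#' @inheritParams donating_power
#' @return omega_plus in eV.
#' @export
#' @examples
#' accepting_power(9.74, 3.06)  # 3.35 (2 dp)
accepting_power <- function(I, A, compound_id = "compound") {
  stopifnot(is.numeric(I), is.numeric(A), all(is.finite(I)), all(is.finite(A)))
  check_ia_gap(I, A, compound_id, "accepting_power")
  (I + 3 * A)^2 / (16 * (I - A))
}

#' Donating/accepting power of a reference atom
#'
#' @param atom A [reference_atom()].
#' @param type `"donating"` (omega_minus, for the Na anchor) or
#'   `"accepting"` (omega_plus, for the F anchor).
#' @return Power in eV.
#' @export
#' @examples
#' reference_power(reference_atom("Na", 5.139, 0.548), "donating")  # 3.470
#' reference_power(reference_atom("F", 17.423, 3.401), "accepting") # 3.402
reference_power <- function(atom, type = c("donating", "accepting")) {
  stopifnot(inherits(atom, "reference_atom"))
  type <- match.arg(type)
  f <- if (type == "donating") donating_power else accepting_power
  f(atom$ionization_potential, atom$electron_affinity, compound_id = atom$symbol)
}

#' Electron-donating index Rd
#'
#' `Rd = omega_minus(compound) / omega_minus(donor reference)`. The sodium
#' anchor maps to exactly 1.
#'
#' @param omega_minus Compound electro-donating power(s), eV.
#' @param donor_reference A [reference_atom()] (default sodium,
#'   I = 5.139 eV, A = 0.548 eV).
#' @return Dimensionless Rd.
#' @export
donation_index <- function(omega_minus,
                           donor_reference = reference_atom("Na", 5.139, 0.548)) {
  ref <- reference_power(donor_reference, "donating")
  if (!is.finite(ref) || ref == 0) {
    stop("donor reference power is zero or non-finite; check configuration",
         call. = FALSE)
  }
  omega_minus / ref
}

#' Electron-accepting index Ra
#'
#' `Ra = omega_plus(compound) / omega_plus(acceptor reference)`. The
#' fluorine anchor maps to exactly 1.
#'
#' @param omega_plus Compound electro-accepting power(s), eV.
#' @param acceptor_reference A [reference_atom()] (default fluorine,
#'   I = 17.423 eV, A = 3.401 eV).
#' @return Dimensionless Ra.
#' @export
acceptance_index <- function(omega_plus,
                             acceptor_reference = reference_atom("F", 17.423, 3.401)) {
  ref <- reference_power(acceptor_reference, "accepting")
  if (!is.finite(ref) || ref == 0) {
    stop("acceptor reference power is zero or non-finite; check configuration",
         call. = FALSE)
  }
  omega_plus / ref
}

#' Absolute DAM sector of a point
#'
#' Quadrant classification against the configured boundaries (defaults:
#' Rd = 1, Ra = 1, the reference anchors). Low-Rd/low-Ra is the electron
#' donor (antioxidant) sector, high-Rd/high-Ra the anti-reductant (electron
#' acceptor) sector; values exactly on a boundary classify to the lower
#' side. The exact sector geometry of published maps is not standardized,
#' which is why [build_dam_table()] additionally emits a dataset-relative
#' label.
#'
#' @param Ra,Rd Non-negative index vectors (recycled).
#' @param cfg An [ar_config()] (boundaries and labels).
#' @return Character vector of sector labels.
#' @export
classify_sector <- function(Ra, Rd, cfg = ar_config()) {
  stopifnot(is.numeric(Ra), is.numeric(Rd), all(Ra >= 0), all(Rd >= 0))
  n <- max(length(Ra), length(Rd))
  Ra <- rep_len(Ra, n); Rd <- rep_len(Rd, n)
  rd_high <- Rd > cfg$rd_boundary
  ra_high <- Ra > cfg$ra_boundary
  key <- paste0(ifelse(rd_high, "rd_high", "rd_low"), "_",
                ifelse(ra_high, "ra_high", "ra_low"))
  unlist(cfg$sector_labels[key], use.names = FALSE)
}

# Dataset-relative reading of the map: donor-leaning when Rd does not exceed
# the panel median and Ra is below the acceptor boundary, acceptor-leaning
# otherwise. Captures the qualitative grouping used when all compounds of a
# panel sit on the donor side of the absolute quadrants.
classify_sector_relative <- function(Ra, Rd, cfg = ar_config()) {
  med <- stats::median(Rd)
  ifelse(Rd <= med & Ra < cfg$ra_boundary, "donor-leaning", "acceptor-leaning")
}

#' DAM coordinates for a descriptor table
#'
#' Computes omega_minus, omega_plus, Rd and Ra for every row of a table
#' holding `compound_id`, `phase`, `I_eV`, `A_eV` (e.g. a
#' [descriptor_table()] output). Rows with degenerate I <= A are dropped
#' into the `"failures"` attribute; the rest of the map proceeds.
#'
#' @param ia data.frame with at least `compound_id`, `phase`, `I_eV`, `A_eV`.
#' @param cfg An [ar_config()].
#' @return data.frame of class `dam_points` with columns `compound_id`,
#'   `phase`, `omega_minus_eV`, `omega_plus_eV`, `Rd`, `Ra`.
#' @export
dam_points <- function(ia, cfg = ar_config()) {
  stopifnot(is.data.frame(ia),
            all(c("compound_id", "phase", "I_eV", "A_eV") %in% names(ia)))
  ok <- ia$I_eV > ia$A_eV
  failures <- data.frame(compound_id = ia$compound_id[!ok],
                         error = rep("degenerate (I <= A); excluded from DAM",
                                     sum(!ok)),
                         stringsAsFactors = FALSE)
  ia <- ia[ok, , drop = FALSE]
  wm <- if (nrow(ia)) donating_power(ia$I_eV, ia$A_eV, ia$compound_id) else numeric()
  wp <- if (nrow(ia)) accepting_power(ia$I_eV, ia$A_eV, ia$compound_id) else numeric()
  out <- data.frame(compound_id = ia$compound_id, phase = ia$phase,
                    omega_minus_eV = wm, omega_plus_eV = wp,
                    Rd = donation_index(wm, cfg$donor_reference),
                    Ra = acceptance_index(wp, cfg$acceptor_reference),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dam_points", class(out))
  attr(out, "failures") <- failures
  out
}

#' Build the donor-acceptor map table
#'
#' Assembles plot-ready DAM coordinates: one row per compound/phase with
#' both sector labels (absolute quadrant and dataset-relative reading), plus
#' the two reference anchors — sodium at Rd = 1 and fluorine at Ra = 1, each
#' with its cross-index computed from the configured atomic values. Rows are
#' ordered by compound_id then phase; anchors come last and are marked
#' `is_reference = TRUE`.
#'
#' @param points A [dam_points()] data.frame.
#' @param cfg An [ar_config()].
#' @return data.frame with columns `compound_id`, `phase`,
#'   `omega_minus_eV`, `omega_plus_eV`, `Rd`, `Ra`, `sector_absolute`,
#'   `sector_relative`, `is_reference`.
#' @export
build_dam_table <- function(points, cfg = ar_config()) {
  stopifnot(is.data.frame(points),
            all(c("compound_id", "phase", "Rd", "Ra") %in% names(points)))
  pts <- points[order(points$compound_id, points$phase), , drop = FALSE]
  pts$sector_absolute <- if (nrow(pts)) classify_sector(pts$Ra, pts$Rd, cfg) else character()
  pts$sector_relative <- if (nrow(pts)) classify_sector_relative(pts$Ra, pts$Rd, cfg) else character()
  pts$is_reference <- rep(FALSE, nrow(pts))
  na <- cfg$donor_reference; fl <- cfg$acceptor_reference
  anchor <- function(atom, role) {
    wm <- donating_power(atom$ionization_potential, atom$electron_affinity, atom$symbol)
    wp <- accepting_power(atom$ionization_potential, atom$electron_affinity, atom$symbol)
    data.frame(compound_id = paste0(atom$symbol, " (", role, " reference)"),
               phase = "reference",
               omega_minus_eV = wm, omega_plus_eV = wp,
               Rd = donation_index(wm, cfg$donor_reference),
               Ra = acceptance_index(wp, cfg$acceptor_reference),
               sector_absolute = NA_character_, sector_relative = NA_character_,
               is_reference = TRUE, stringsAsFactors = FALSE)
  }
  cols <- c("compound_id", "phase", "omega_minus_eV", "omega_plus_eV",
            "Rd", "Ra", "sector_absolute", "sector_relative", "is_reference")
  out <- rbind(pts[, cols, drop = FALSE], anchor(na, "donor"), anchor(fl, "acceptor"))
  rownames(out) <- NULL
  attr(out, "dam_config") <- cfg
  out
}

#' Export a DAM table
#'
#' Writes the CSV form (coordinates and both sector labels) and a JSON
#' variant (`<path>.json`) embedding the configuration used, so a map can
#' always be traced back to its anchors and boundaries.
#'
#' @param dam A [build_dam_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dam_table <- function(dam, path) {
  stopifnot(is.data.frame(dam))
  utils::write.csv(dam, path, row.names = FALSE, quote = TRUE)
  cfg <- attr(dam, "dam_config")
  payload <- list(
    config = if (is.null(cfg)) NULL else list(
      hartree_to_ev = cfg$hartree_to_ev,
      donor_reference = unclass(cfg$donor_reference),
      acceptor_reference = unclass(cfg$acceptor_reference),
      rd_boundary = cfg$rd_boundary, ra_boundary = cfg$ra_boundary,
      sector_labels = cfg$sector_labels),
    points = dam)
  jsonlite::write_json(payload, paste0(path, ".json"), dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
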