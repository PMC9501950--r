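# Pipeline configuration: unit factor, DAM reference atoms and sector
# boundaries, assay model and correlation descriptor. A single object is
# threaded through every stage so that no two stages can disagree on a
# convention constant.

#' Atomic reference for the donor-acceptor map
#'
#' An atom whose experimental vertical ionization potential and electron
#' affinity anchor one axis of the DAM: sodium (an excellent electron donor)
#' normalizes the electron-donating index Rd, fluorine (an excellent
#' acceptor) normalizes the electron-accepting index Ra.
#'
#' @param symbol Atom symbol, e.g. `"Na"` or `"F"`.
#' @param ionization_potential Atomic I in eV.
#' @param electron_affinity Atomic A in eV; must be smaller than `I`.
#' @return An object of class `reference_atom`.
#' @export
#' @examples
#' reference_atom("Na", 5.139, 0.548)
reference_atom <- function(symbol, ionization_potential, electron_affinity) {
  stopifnot(is.character(symbol), length(symbol) == 1L,
            is.numeric(ionization_potential), length(ionization_potential) == 1L,
            is.numeric(electron_affinity), length(electron_affinity) == 1L,
            is.finite(ionization_potential), is.finite(electron_affinity))
  if (ionization_potential <= electron_affinity) {
    stop("reference_atom: ionization potential must exceed electron affinity (",
         symbol, ": I = ", ionization_potential, ", A = ", electron_affinity, ")",
         call. = FALSE)
  }
  structure(
    list(symbol = symbol,
         ionization_potential = ionization_potential,
         electron_affinity = electron_affinity),
    class = "reference_atom"
  )
}

#' @export
print.reference_atom <- function(x, ...) {
  cat(sprintf("<reference_atom %s: I = %.3f eV, A = %.3f eV>\n",
              x$symbol, x$ionization_potential, x$electron_affinity))
  invisible(x)
}

default_sector_labels <- function() {
  list(
    rd_low_ra_low   = "electron donor (antioxidant) sector",
    rd_high_ra_high = "anti-reductant (electron acceptor) sector",
    rd_high_ra_low  = "weak donor sector",
    rd_low_ra_high  = "weak acceptor sector"
  )
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis: the hartree-to-eV factor,
#' the DAM reference atoms (experimental atomic values: Na I = 5.139 eV,
#' A = 0.548 eV; F I = 17.423 eV, A = 3.401 eV), the DAM sector boundaries
#' (the reference anchors, Rd = 1 and Ra = 1), the IC50 fit model and the
#' descriptor correlated against IC50.
#'
#' @param hartree_to_ev eV per hartree; default [hartree_ev_factor()].
#' @param donor_reference,acceptor_reference [reference_atom()] objects for
#'   the Rd (sodium) and Ra (fluorine) normalizations.
#' @param rd_boundary,ra_boundary Positive sector boundaries of the DAM
#'   quadrant scheme; points exactly on a boundary classify to the lower side.
#' @param sector_labels Named list of the four quadrant labels
#'   (`rd_low_ra_low`, `rd_high_ra_low`, `rd_low_ra_high`, `rd_high_ra_high`).
#' @param assay_model Default IC50 model, `"loglinear_interpolation"` or
#'   `"four_parameter_logistic"`.
#' @param correlation_descriptor Descriptor column correlated with IC50 by
#'   default (any of `"I_eV"`, `"A_eV"`, `"Rd"`, `"Ra"`, `"omega_minus_eV"`,
#'   `"omega_plus_eV"`, `"homo_eV"`).
#' @param convention Descriptor convention, `"replication"` (atomic-units
#'   evaluation of softness and electrophilicity, matching published tables)
#'   or `"standard"` (see [global_descriptors()]).
#' @param seed Integer seed recorded in run metadata and used by synthetic
#'   stages.
#' @return An object of class `ar_config` (a validated list).
#' @seealso [read_ar_config()] to load one from a key-value file.
#' @export
ar_config <- function(hartree_to_ev = hartree_ev_factor(),
                      donor_reference = reference_atom("Na", 5.139, 0.548),
                      acceptor_reference = reference_atom("F", 17.423, 3.401),
                      rd_boundary = 1.0,
                      ra_boundary = 1.0,
                      sector_labels = default_sector_labels(),
                      assay_model = c("loglinear_interpolation",
                                      "four_parameter_logistic"),
                      correlation_descriptor = "I_eV",
                      convention = c("replication", "standard"),
                      seed = 1L) {
  assay_model <- match.arg(assay_model)
  convention <- match.arg(convention)
  stopifnot(is.numeric(hartree_to_ev), hartree_to_ev > 0,
            inherits(donor_reference, "reference_atom"),
            inherits(acceptor_reference, "reference_atom"),
            is.numeric(rd_boundary), rd_boundary > 0,
            is.numeric(ra_boundary), ra_boundary > 0,
            is.list(sector_labels))
  missing_labels <- setdiff(names(default_sector_labels()), names(sector_labels))
  if (length(missing_labels)) {
    stop("ar_config: sector_labels missing ", paste(missing_labels, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(hartree_to_ev = hartree_to_ev,
         donor_reference = donor_reference,
         acceptor_reference = acceptor_reference,
         rd_boundary = rd_boundary,
         ra_boundary = ra_boundary,
         sector_labels = sector_labels,
         assay_model = assay_model,
         correlation_descriptor = correlation_descriptor,
         convention = convention,
         seed = as.integer(seed)),
    class = "ar_config"
  )
}

#' @export
print.ar_config <- function(x, ...) {
  cat("<ar_config>\n")
  cat(sprintf("  hartree_to_ev: %.6f\n", x$hartree_to_ev))
  cat(sprintf("  donor ref:     %s (I %.3f, A %.3f eV)\n", x$donor_reference$symbol,
              x$donor_reference$ionization_potential, x$donor_reference$electron_affinity))
  cat(sprintf("  acceptor ref:  %s (I %.3f, A %.3f eV)\n", x$acceptor_reference$symbol,
              x$acceptor_reference$ionization_potential, x$acceptor_reference$electron_affinity))
  cat(sprintf("  boundaries:    Rd %.2f, Ra %.2f\n", x$rd_boundary, x$ra_boundary))
  cat(sprintf("  assay model:   %s\n", x$assay_model))
  cat(sprintf("  convention:    %s; correlation vs %s; seed %d\n",
              x$convention, x$correlation_descriptor, x$seed))
  invisible(x)
}

#' Read a configuration file
#'
#' Parses a plain `key = value` file (one pair per line, `#` comments) into
#' an [ar_config()]. Recognized keys: `hartree_to_ev`, `donor_symbol`,
#' `donor_I_eV`, `donor_A_eV`, `acceptor_symbol`, `acceptor_I_eV`,
#' `acceptor_A_eV`, `rd_boundary`, `ra_boundary`, `assay_model`,
#' `correlation_descriptor`, `convention`, `seed`, plus the pipeline input
#' keys `energies_file`, `ia_file`, `fmo_file`, `assay_file`, `ic50_file`
#' and `phases` (comma-separated) consumed by [run_pipeline()].
#'
#' @param path Path to the key-value file.
#' @return An `ar_config` whose extra input keys are attached as the
#'   `"inputs"` attribute.
#' @export
read_ar_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    stop("config line not of the form key = value: ", lines[bad][1L], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  get <- function(key, default = NULL) if (key %in% keys) vals[[match(key, keys)]] else default
  num <- function(key, default) {
    v <- get(key)
    if (is.null(v)) default else as.numeric(v)
  }
  donor <- reference_atom(get("donor_symbol", "Na"),
                          num("donor_I_eV", 5.139), num("donor_A_eV", 0.548))
  acceptor <- reference_atom(get("acceptor_symbol", "F"),
                             num("acceptor_I_eV", 17.423), num("acceptor_A_eV", 3.401))
  cfg <- ar_config(
    hartree_to_ev = num("hartree_to_ev", hartree_ev_factor()),
    donor_reference = donor,
    acceptor_reference = acceptor,
    rd_boundary = num("rd_boundary", 1.0),
    ra_boundary = num("ra_boundary", 1.0),
    assay_model = get("assay_model", "loglinear_interpolation"),
    correlation_descriptor = get("correlation_descriptor", "I_eV"),
    convention = get("convention", "replication"),
    seed = as.integer(num("seed", 1))
  )
  input_keys <- c("energies_file", "ia_file", "fmo_file", "assay_file",
                  "ic50_file", "phases")
  inputs <- list()
  for (k in input_keys) {
    v <- get(k)
    if (!is.null(v)) inputs[[k]] <- v
  }
  if (!is.null(inputs$phases)) {
    inputs$phases <- trimws(strsplit(inputs$phases, ",", fixed = TRUE)[[1L]])
  }
  attr(cfg, "inputs") <- inputs
  cfg
}

#' Stable hash of a configuration
#'
#' MD5 of the deparsed configuration, used to stamp report bundles so two
#' runs are comparable only when their constants agree.
#'
#' @param cfg An [ar_config()].
#' @return Length-one character MD5 digest.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "ar_config"))
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}
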