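# Vertical I/A and the seven global conceptual-DFT reactivity descriptors.
#
# Two conventions are supported and never mixed in one table:
#   standard    — S = 1/(2*eta) in 1/eV, omega = mu^2/(2*eta) in eV (the
#                 literature definitions on the eV scale)
#   replication — S and omega evaluated with energies in atomic units and
#                 the bare number relabelled eV, i.e. S = F^2/(2*eta_eV) and
#                 omega = mu_eV^2/(2*F) with F the hartree-to-eV factor.
#                 This is how many published tables (computed from hartree
#                 totals with omega = mu^2/2) were actually produced.

#' Vertical ionization potential
#'
#' `I = E(cation) - E(neutral)` at the neutral geometry, converted to eV.
#' A negative result is physically suspect (the cation below the neutral)
#' and is flagged with a warning, not an error.
#'
#' @param e_cation,e_neutral Total electronic energies in hartree.
#' @param factor eV-per-hartree conversion factor.
#' @return Ionization potential(s) in eV.
#' @export
#' @examples
#' ionization_potential(-687.700, -687.963)  # 7.1566 eV
ionization_potential <- function(e_cation, e_neutral,
                                 factor = hartree_ev_factor()) {
  stopifnot(all(is.finite(e_cation)), all(is.finite(e_neutral)))
  I <- (e_cation - e_neutral) * factor
  if (any(I < 0)) {
    warning("negative ionization potential computed; check species assignment",
            call. = FALSE)
  }
  I
}

#' Vertical electron affinity
#'
#' `A = E(neutral) - E(anion)` at the neutral geometry, converted to eV.
#' A negative A (vertical attachment to a metastable anion) is legitimate
#' and common for poor acceptors; it is reported with a message, never an
#' error.
#'
#' @param e_neutral,e_anion Total electronic energies in hartree.
#' @param factor eV-per-hartree conversion factor.
#' @return Electron affinity(ies) in eV.
#' @export
#' @examples
#' electron_affinity(-500.000, -500.004)  # 0.1088 eV
electron_affinity <- function(e_neutral, e_anion,
                              factor = hartree_ev_factor()) {
  stopifnot(all(is.finite(e_neutral)), all(is.finite(e_anion)))
  A <- (e_neutral - e_anion) * factor
  if (any(A < 0)) {
    message("note: negative electron affinity (metastable vertical anion)")
  }
  A
}

#' Global conceptual-DFT reactivity descriptors
#'
#' From vertical I and A (eV) computes chemical hardness
#' `eta = (I - A)/2`, electronegativity `chi = (I + A)/2`, chemical
#' potential `mu = -chi`, softness S and electrophilicity index omega.
#' The identities `chi == -mu` and `eta == (I - A)/2` hold to machine
#' precision by construction in both conventions.
#'
#' Under `convention = "standard"`, `S = 1/(2*eta)` (1/eV) and
#' `omega = mu^2/(2*eta)` (eV). Under `"replication"` the two quantities are
#' evaluated in atomic units and the bare numbers relabelled: `S` becomes
#' `F^2/(2*eta)` and `omega` becomes `mu^2/(2*F)` with `F` the
#' hartree-to-eV factor — the convention that reproduces published
#' descriptor tables computed directly from hartree energies with
#' `omega = mu^2/2`. The convention used is carried in the output and table
#' writers refuse to mix conventions.
#'
#' @param I,A Vertical ionization potential(s) and electron affinity(ies),
#'   eV. Vectors are allowed (recycled against `compound_id`/`phase`).
#' @param convention `"replication"` or `"standard"`.
#' @param compound_id,phase Identifiers carried into the output.
#' @param factor eV-per-hartree factor used by the replication convention.
#' @return data.frame of class `global_descriptors` with columns
#'   `compound_id`, `phase`, `I_eV`, `A_eV`, `eta_eV`, `S`, `chi_eV`,
#'   `mu_eV`, `omega_eV`, `convention`.
#' @export
#' @examples
#' global_descriptors(9.74, 3.06, convention = "replication")   # omega 0.75
#' global_descriptors(9.74, 3.06, convention = "standard")      # omega 6.13
global_descriptors <- function(I, A, convention = c("replication", "standard"),
                               compound_id = "compound", phase = "gas",
                               factor = hartree_ev_factor()) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(I), is.numeric(A), all(is.finite(I)), all(is.finite(A)))
  n <- max(length(I), length(A), length(compound_id), length(phase))
  I <- rep_len(I, n); A <- rep_len(A, n)
  compound_id <- rep_len(compound_id, n); phase <- rep_len(phase, n)
  if (any(I <= A)) {
    bad <- compound_id[I <= A]
    stop("degenerate hardness (I <= A) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  eta <- (I - A) / 2
  chi <- (I + A) / 2
  mu <- -chi
  if (convention == "standard") {
    S <- 1 / (2 * eta)
    omega <- mu^2 / (2 * eta)
  } else {
    S <- factor^2 / (2 * eta)
    omega <- mu^2 / (2 * factor)
  }
  out <- data.frame(compound_id = compound_id, phase = phase,
                    I_eV = I, A_eV = A, eta_eV = eta, S = S,
                    chi_eV = chi, mu_eV = mu, omega_eV = omega,
                    convention = convention, stringsAsFactors = FALSE)
  class(out) <- c("global_descriptors", class(out))
  out
}

#' Descriptor table for a set of compound records
#'
#' Resolves each record to (I, A) for the requested phase via [record_ia()]
#' and computes [global_descriptors()]. Records that cannot feed the stage
#' (no I/A source, or degenerate I <= A) are skipped and reported in the
#' `"failures"` attribute instead of aborting the table.
#'
#' @param records List of [compound_record()]s.
#' @param phase Phase label.
#' @param config An [ar_config()]; supplies convention and unit factor.
#' @return A `global_descriptors` data.frame (possibly zero rows) with
#'   attributes `"failures"` (data.frame compound_id/error) and `"notes"`.
#' @export
descriptor_table <- function(records, phase = "gas", config = ar_config()) {
  rows <- list(); failures <- list(); notes <- character()
  for (rec in records) {
    res <- tryCatch({
      ia <- record_ia(rec, phase, config)
      notes <- c(notes, ia$notes)
      global_descriptors(ia$I_eV, ia$A_eV, convention = config$convention,
                         compound_id = rec$compound_id, phase = phase,
                         factor = config$hartree_to_ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(compound_id = rec$compound_id, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    global_descriptors(1, 0, convention = config$convention)[0, ]
  out <- out[order(out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(compound_id = character(), error = character())
  attr(out, "notes") <- notes
  out
}

#' Write a descriptor table
#'
#' CSV with fixed column order and 2-decimal display values, plus a JSON
#' sidecar (`<path>.json`) retaining full precision and the convention tag.
#' Mixing conventions within one table is refused.
#'
#' @param desc A `global_descriptors` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(desc, path) {
  stopifnot(is.data.frame(desc))
  if (nrow(desc) && length(unique(desc$convention)) > 1L) {
    stop("refusing to write a table mixing descriptor conventions", call. = FALSE)
  }
  cols <- c("compound_id", "phase", "I_eV", "A_eV", "eta_eV", "S",
            "chi_eV", "mu_eV", "omega_eV", "convention")
  disp <- desc[, cols, drop = FALSE]
  for (cl in c("I_eV", "A_eV", "eta_eV", "S", "chi_eV", "mu_eV", "omega_eV")) {
    disp[[cl]] <- sprintf("%.2f", desc[[cl]])
  }
  con <- file(path, open = "wb")
  writeLines(c(paste(cols, collapse = ","),
               apply(disp, 1L, paste, collapse = ",")), con, sep = "\n")
  close(con)
  jsonlite::write_json(desc[, cols, drop = FALSE], paste0(path, ".json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}
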