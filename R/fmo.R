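# Frontier-molecular-orbital bookkeeping. The HOMO energy proxies
# electron-donating ability (more positive HOMO donates more readily), so
# descending-HOMO order should mirror ascending vertical-I order; the
# concordance check quantifies how well it does.

#' Frontier-orbital table constructor
#'
#' @param compound_id Identifiers.
#' @param homo HOMO energies, eV.
#' @param lumo Optional LUMO energies, eV (`NA` when unknown; many studies
#'   print HOMO values only).
#' @param phase Phase label(s).
#' @return data.frame with columns `compound_id`, `phase`, `homo_eV`,
#'   `lumo_eV`, `gap_eV` (NA where LUMO is missing).
#' @export
frontier_orbitals <- function(compound_id, homo, lumo = NA_real_, phase = "gas") {
  n <- length(compound_id)
  homo <- rep_len(as.numeric(homo), n)
  lumo <- rep_len(as.numeric(lumo), n)
  gap <- ifelse(is.finite(homo) & is.finite(lumo), lumo - homo, NA_real_)
  data.frame(compound_id = compound_id, phase = rep_len(phase, n),
             homo_eV = homo, lumo_eV = lumo, gap_eV = gap,
             stringsAsFactors = FALSE)
}

#' HOMO-LUMO gap
#'
#' `gap = LUMO - HOMO` in eV. A negative gap means the stated LUMO lies
#' below the HOMO — inconsistent input, flagged with a warning and returned
#' as-is so the caller can inspect it.
#'
#' @param homo,lumo Orbital energies in eV, finite.
#' @return Gap(s) in eV.
#' @export
#' @examples
#' orbital_gap(-5.7590, -1.0)  # 4.759
orbital_gap <- function(homo, lumo) {
  stopifnot(all(is.finite(homo)), all(is.finite(lumo)))
  gap <- lumo - homo
  if (any(gap < 0)) {
    warning("negative HOMO-LUMO gap: inconsistent orbital input", call. = FALSE)
  }
  gap
}

#' Rank compounds by HOMO energy
#'
#' Stable descending order by HOMO (most positive first = best predicted
#' electron donor); ties broken by lexicographic compound_id so ranking is
#' deterministic. Entries without a HOMO are excluded with a message and
#' listed in the `"excluded"` attribute.
#'
#' @param orbitals data.frame with `compound_id` and `homo_eV` columns
#'   (e.g. from [frontier_orbitals()]).
#' @return The ranked data.frame with an added integer `donor_rank` column.
#' @export
rank_by_homo <- function(orbitals) {
  stopifnot(is.data.frame(orbitals),
            all(c("compound_id", "homo_eV") %in% names(orbitals)))
  has <- is.finite(orbitals$homo_eV)
  if (!any(has)) stop("rank_by_homo: no entry has a HOMO energy", call. = FALSE)
  excluded <- orbitals$compound_id[!has]
  if (length(excluded)) {
    message("rank_by_homo: excluding entries without HOMO: ",
            paste(excluded, collapse = ", "))
  }
  out <- orbitals[has, , drop = FALSE]
  out <- out[order(-out$homo_eV, out$compound_id), , drop = FALSE]
  out$donor_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Concordance between HOMO order and ionization-potential order
#'
#' Checks the frontier-orbital prediction against the energy-difference
#' ground truth: over all compound pairs shared by the two tables, a pair is
#' concordant when the compound with the more positive HOMO has the lower
#' (or tied) I. Ties in either quantity are treated as compatible. Reported
#' as a concordance fraction with the discordant pairs listed.
#'
#' @param orbitals data.frame with `compound_id`, `homo_eV`.
#' @param descriptors data.frame with `compound_id`, `I_eV`
#'   (e.g. [descriptor_table()] output).
#' @return List with `concordance` (fraction in \[0, 1\]), `n_pairs`,
#'   `concordant_pairs`, `discordant` (data.frame of offending pairs) and
#'   `compounds` compared.
#' @export
koopmans_consistency <- function(orbitals, descriptors) {
  stopifnot(is.data.frame(orbitals), is.data.frame(descriptors))
  m <- merge(orbitals[, c("compound_id", "homo_eV")],
             descriptors[, c("compound_id", "I_eV")], by = "compound_id")
  m <- m[is.finite(m$homo_eV) & is.finite(m$I_eV), , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) {
    return(list(concordance = 1.0, n_pairs = 0L, concordant_pairs = 0L,
                discordant = data.frame(compound_a = character(),
                                        compound_b = character()),
                compounds = m$compound_id))
  }
  disc <- list(); conc <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + 1L
      dh <- m$homo_eV[i] - m$homo_eV[j]
      di <- m$I_eV[i] - m$I_eV[j]
      # compatible when a tie is present in either quantity, else the
      # higher-HOMO compound must have the lower I
      ok <- dh == 0 || di == 0 || sign(dh) == -sign(di)
      if (ok) conc <- conc + 1L else {
        disc[[length(disc) + 1L]] <- data.frame(
          compound_a = m$compound_id[i], compound_b = m$compound_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(concordance = conc / total, n_pairs = total, concordant_pairs = conc,
       discordant = if (length(disc)) do.call(rbind, disc) else
         data.frame(compound_a = character(), compound_b = character()),
       compounds = m$compound_id)
}

#' Export an FMO table
#'
#' CSV with columns `compound_id`, `phase`, `homo_eV`, `lumo_eV`, `gap_eV`,
#' `donor_rank`.
#'
#' @param ranked A [rank_by_homo()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fmo_table <- function(ranked, path) {
  cols <- intersect(c("compound_id", "phase", "homo_eV", "lumo_eV",
                      "gap_eV", "donor_rank"), names(ranked))
  utils::write.csv(ranked[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
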