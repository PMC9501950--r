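# Data model and tabular I/O for compounds and their charged species.
#
# Two delimited-text dialects are supported and never mixed:
#   energies  — compound_id, charge_state, phase, energy_hartree (+ optional
#               method_tag, homo_eV, lumo_eV, ic50_ppm)
#   ia_values — compound_id, phase, I_eV, A_eV (+ optional homo_eV, lumo_eV,
#               ic50_ppm)
# Energies are accepted in hartree only, I/A in eV only, which keeps unit
# mix-ups structurally impossible.

CHARGE_STATES <- c("neutral", "cation", "anion")

#' Construct a single species-energy record
#'
#' One total electronic energy of one charge state of one compound in one
#' phase. Three of these (neutral, cation, anion, vertical geometries) are
#' what the ionization potential and electron affinity are computed from.
#'
#' @param compound_id Compound identifier (opaque text).
#' @param charge_state One of `"neutral"`, `"cation"`, `"anion"`.
#' @param phase Phase label, e.g. `"gas"` or `"methanol"`.
#' @param energy_hartree Finite total electronic energy in hartree.
#' @param method_tag Free-text level of theory, e.g. `"B3LYP/6-31+G(2d,2p)"`.
#' @return A one-row data.frame with the five columns above.
#' @export
species_energy <- function(compound_id, charge_state, phase, energy_hartree,
                           method_tag = NA_character_) {
  charge_state <- match.arg(charge_state, CHARGE_STATES)
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.character(phase), nzchar(phase),
            is.numeric(energy_hartree), is.finite(energy_hartree))
  data.frame(compound_id = compound_id, charge_state = charge_state,
             phase = phase, energy_hartree = as.numeric(energy_hartree),
             method_tag = method_tag, stringsAsFactors = FALSE)
}

#' Construct a compound record
#'
#' The per-compound container: species energies keyed by (charge state,
#' phase), optional pre-computed I/A overrides per phase, optional frontier
#' orbital energies and optional assay results. For any phase consumed
#' downstream either the full neutral/cation/anion triplet or an `ia_override`
#' row must be present; when both are, the override wins and a notice is
#' recorded in `$notes`.
#'
#' @param compound_id Identifier.
#' @param display_name Human-readable name; defaults to the identifier.
#' @param species data.frame as produced by [species_energy()] (zero or more
#'   rows); duplicate (charge_state, phase) pairs are an error.
#' @param ia_override Optional data.frame with columns `phase`, `I_eV`,
#'   `A_eV` of pre-computed vertical values.
#' @param homo_eV,lumo_eV Optional frontier-orbital energies in eV.
#' @param assay Optional [dose_response_curve()].
#' @param ic50_ppm Optional IC50 in ppm.
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(compound_id, display_name = compound_id,
                            species = NULL, ia_override = NULL,
                            homo_eV = NA_real_, lumo_eV = NA_real_,
                            assay = NULL, ic50_ppm = NA_real_) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L, nzchar(compound_id))
  notes <- character()
  if (is.null(species)) {
    species <- data.frame(compound_id = character(), charge_state = character(),
                          phase = character(), energy_hartree = numeric(),
                          method_tag = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(species))
  if (nrow(species)) {
    stopifnot(all(c("charge_state", "phase", "energy_hartree") %in% names(species)))
    if (!all(species$charge_state %in% CHARGE_STATES)) {
      stop("compound_record(", compound_id, "): unknown charge_state ",
           paste(setdiff(species$charge_state, CHARGE_STATES), collapse = ", "),
           call. = FALSE)
    }
    if (!all(is.finite(species$energy_hartree))) {
      stop("compound_record(", compound_id, "): non-finite energy", call. = FALSE)
    }
    key <- paste(species$charge_state, species$phase)
    if (anyDuplicated(key)) {
      stop("compound_record(", compound_id, "): duplicate species for (",
           key[duplicated(key)][1L], ")", call. = FALSE)
    }
  }
  if (!is.null(ia_override)) {
    stopifnot(is.data.frame(ia_override),
              all(c("phase", "I_eV", "A_eV") %in% names(ia_override)))
    if (anyDuplicated(ia_override$phase)) {
      stop("compound_record(", compound_id, "): duplicate ia_override phase",
           call. = FALSE)
    }
    both <- intersect(ia_override$phase, unique(species$phase))
    for (ph in both) {
      have_triplet <- all(CHARGE_STATES %in% species$charge_state[species$phase == ph])
      if (have_triplet) {
        notes <- c(notes, sprintf(
          "phase '%s': both an energy triplet and an I/A override present; override wins",
          ph))
      }
    }
  }
  structure(
    list(compound_id = compound_id, display_name = display_name,
         species = species, ia_override = ia_override,
         homo_eV = as.numeric(homo_eV), lumo_eV = as.numeric(lumo_eV),
         assay = assay, ic50_ppm = as.numeric(ic50_ppm), notes = notes),
    class = "compound_record"
  )
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record %s ('%s')>\n", x$compound_id, x$display_name))
  cat(sprintf("  species rows: %d; override phases: %s\n", nrow(x$species),
              if (is.null(x$ia_override)) "none" else paste(x$ia_override$phase, collapse = ", ")))
  cat(sprintf("  homo: %s eV; lumo: %s eV; ic50: %s ppm\n",
              format(x$homo_eV), format(x$lumo_eV), format(x$ic50_ppm)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# Reads a delimited file with the separator chosen from the extension
# (.tsv/.tab/.txt -> tab, otherwise comma), all columns as character so that
# "-0.00" survives parsing.
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE)
}

# Numeric parse that flags values printed as "-0", "-0.0", ... : the sign is
# metadata (it usually marks a tiny negative rounded to zero upstream), the
# stored value is exactly 0.
parse_signed <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & nzchar(trimws(x)) & is.na(num)
  if (any(bad)) stop("non-numeric value: '", x[bad][1L], "'", call. = FALSE)
  negzero <- !is.na(num) & num == 0 & grepl("^\\s*-", x)
  num[negzero] <- 0
  list(value = num, negative_zero = negzero)
}

require_columns <- function(df, cols, path, dialect) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("'", path, "' is not a valid ", dialect, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a compound table
#'
#' Reads one of the two tabular dialects into a list of
#' [compound_record()]s. Delimiter is auto-detected from the extension
#' (`.csv` comma; `.tsv`/`.tab`/`.txt` tab).
#'
#' A printed `-0.00` (a tiny negative electron affinity rounded to zero
#' upstream) is stored as `0` and surfaced in the record's `$notes` rather
#' than silently dropped.
#'
#' @param path File path.
#' @param dialect `"energies"` (hartree triplets) or `"ia_values"`
#'   (pre-computed I/A in eV filling `ia_override`).
#' @return A named list of `compound_record`s, ordered by first appearance.
#' @export
read_compound_table <- function(path, dialect = c("energies", "ia_values")) {
  dialect <- match.arg(dialect)
  df <- read_delimited(path)
  opt_num <- function(col, i) {
    if (!col %in% names(df)) return(NA_real_)
    v <- df[[col]][i]
    if (is.na(v) || !nzchar(trimws(v))) NA_real_ else parse_signed(v)$value
  }
  records <- list()
  if (dialect == "energies") {
    require_columns(df, c("compound_id", "charge_state", "phase", "energy_hartree"),
                    path, dialect)
    key <- paste(df$compound_id, df$charge_state, df$phase)
    if (anyDuplicated(key)) {
      stop("duplicate (compound_id, charge_state, phase) in '", path, "': ",
           key[duplicated(key)][1L], call. = FALSE)
    }
    energy <- parse_signed(df$energy_hartree)$value
    for (id in unique(df$compound_id)) {
      idx <- which(df$compound_id == id)
      sp <- data.frame(
        compound_id = id,
        charge_state = df$charge_state[idx],
        phase = df$phase[idx],
        energy_hartree = energy[idx],
        method_tag = if ("method_tag" %in% names(df)) df$method_tag[idx] else NA_character_,
        stringsAsFactors = FALSE)
      records[[id]] <- compound_record(
        id,
        display_name = if ("display_name" %in% names(df)) df$display_name[idx[1L]] else id,
        species = sp,
        homo_eV = opt_num("homo_eV", idx[1L]),
        lumo_eV = opt_num("lumo_eV", idx[1L]),
        ic50_ppm = opt_num("ic50_ppm", idx[1L]))
    }
  } else {
    require_columns(df, c("compound_id", "phase", "I_eV", "A_eV"), path, dialect)
    key <- paste(df$compound_id, df$phase)
    if (anyDuplicated(key)) {
      stop("duplicate (compound_id, phase) in '", path, "': ",
           key[duplicated(key)][1L], call. = FALSE)
    }
    iv <- parse_signed(df$I_eV)
    av <- parse_signed(df$A_eV)
    for (id in unique(df$compound_id)) {
      idx <- which(df$compound_id == id)
      ov <- data.frame(phase = df$phase[idx], I_eV = iv$value[idx],
                       A_eV = av$value[idx], stringsAsFactors = FALSE)
      rec <- compound_record(
        id,
        display_name = if ("display_name" %in% names(df)) df$display_name[idx[1L]] else id,
        ia_override = ov,
        homo_eV = opt_num("homo_eV", idx[1L]),
        lumo_eV = opt_num("lumo_eV", idx[1L]),
        ic50_ppm = opt_num("ic50_ppm", idx[1L]))
      nz <- iv$negative_zero[idx] | av$negative_zero[idx]
      if (any(nz)) {
        rec$notes <- c(rec$notes, sprintf(
          "phase '%s': value printed as -0 parsed as 0 (sign recorded)",
          df$phase[idx][nz]))
      }
      records[[id]] <- rec
    }
  }
  records
}

# Canonical numeric text: shortest representation that round-trips doubles.
format_canonical <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, "")
  out
}

#' Write a compound table in canonical form
#'
#' The canonical writer: fixed column order, shortest round-tripping decimal
#' text, LF line endings. Reading a table and writing it again yields
#' byte-identical text, which makes tables diffable and runs reproducible.
#'
#' @param records List of [compound_record()]s.
#' @param path Output path (`.csv` comma, `.tsv` tab).
#' @param dialect `"energies"` or `"ia_values"`.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path, dialect = c("energies", "ia_values")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  rows <- character()
  if (dialect == "energies") {
    header <- c("compound_id", "charge_state", "phase", "energy_hartree",
                "method_tag", "homo_eV", "lumo_eV", "ic50_ppm")
    for (rec in records) {
      sp <- rec$species
      for (i in seq_len(nrow(sp))) {
        rows <- c(rows, paste(c(
          sp$compound_id[i], sp$charge_state[i], sp$phase[i],
          format_canonical(sp$energy_hartree[i]),
          ifelse(is.na(sp$method_tag[i]), "", sp$method_tag[i]),
          format_canonical(rec$homo_eV), format_canonical(rec$lumo_eV),
          format_canonical(rec$ic50_ppm)), collapse = sep))
      }
    }
  } else {
    header <- c("compound_id", "phase", "I_eV", "A_eV",
                "homo_eV", "lumo_eV", "ic50_ppm")
    for (rec in records) {
      ov <- rec$ia_override
      if (is.null(ov)) next
      for (i in seq_len(nrow(ov))) {
        rows <- c(rows, paste(c(
          rec$compound_id, ov$phase[i],
          format_canonical(ov$I_eV[i]), format_canonical(ov$A_eV[i]),
          format_canonical(rec$homo_eV), format_canonical(rec$lumo_eV),
          format_canonical(rec$ic50_ppm)), collapse = sep))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(paste(header, collapse = sep), rows), con, sep = "\n")
  invisible(path)
}

#' Report which pipeline stages a record can feed
#'
#' Report-only completeness check: for a given phase, lists whether the
#' record can enter the descriptor/DAM stage (needs an I/A override or a
#' full neutral/cation/anion triplet), the FMO stage (needs a HOMO energy)
#' and the assay stage (needs a dose-response curve or an IC50), with a
#' reason when it cannot.
#'
#' @param rec A [compound_record()].
#' @param phase Phase label to check.
#' @return data.frame with columns `stage`, `eligible`, `reason`.
#' @export
validate_record <- function(rec, phase = "gas") {
  stopifnot(inherits(rec, "compound_record"))
  has_override <- !is.null(rec$ia_override) && phase %in% rec$ia_override$phase
  sp <- rec$species[rec$species$phase == phase, , drop = FALSE]
  have_states <- CHARGE_STATES %in% sp$charge_state
  has_triplet <- all(have_states)
  desc_ok <- has_override || has_triplet
  desc_reason <- if (desc_ok) "" else if (nrow(sp) == 0L && !has_override) {
    sprintf("no energies and no I/A override for phase '%s'", phase)
  } else {
    sprintf("incomplete energy triplet for phase '%s': missing %s",
            phase, paste(CHARGE_STATES[!have_states], collapse = ", "))
  }
  fmo_ok <- is.finite(rec$homo_eV)
  assay_ok <- !is.null(rec$assay) || is.finite(rec$ic50_ppm)
  data.frame(
    stage = c("descriptors", "dam", "fmo", "assay"),
    eligible = c(desc_ok, desc_ok, fmo_ok, assay_ok),
    reason = c(desc_reason, desc_reason,
               if (fmo_ok) "" else "no HOMO energy",
               if (assay_ok) "" else "no dose-response curve or IC50"),
    stringsAsFactors = FALSE)
}

#' Extract vertical I/A for one record and phase
#'
#' Resolves a record to an (I, A) pair in eV for the requested phase: the
#' `ia_override` wins when present (with a notice if a full triplet also
#' exists), otherwise I and A are computed from the energy triplet via
#' [ionization_potential()] and [electron_affinity()].
#'
#' @param rec A [compound_record()].
#' @param phase Phase label.
#' @param config An [ar_config()] supplying the unit factor.
#' @return List with `I_eV`, `A_eV`, `source` (`"override"` or
#'   `"energies"`) and `notes` (character vector, possibly empty).
#' @export
record_ia <- function(rec, phase = "gas", config = ar_config()) {
  stopifnot(inherits(rec, "compound_record"))
  notes <- character()
  if (!is.null(rec$ia_override) && phase %in% rec$ia_override$phase) {
    i <- match(phase, rec$ia_override$phase)
    sp <- rec$species[rec$species$phase == phase, , drop = FALSE]
    if (nrow(sp) && all(CHARGE_STATES %in% sp$charge_state)) {
      notes <- c(notes, sprintf(
        "%s/%s: I/A override used in place of the available energy triplet",
        rec$compound_id, phase))
    }
    return(list(I_eV = rec$ia_override$I_eV[i], A_eV = rec$ia_override$A_eV[i],
                source = "override", notes = notes))
  }
  sp <- rec$species[rec$species$phase == phase, , drop = FALSE]
  e <- function(state) sp$energy_hartree[match(state, sp$charge_state)]
  if (!all(CHARGE_STATES %in% sp$charge_state)) {
    stop("record_ia(", rec$compound_id, "): no I/A source for phase '", phase,
         "'", call. = FALSE)
  }
  list(I_eV = ionization_potential(e("cation"), e("neutral"),
                                   factor = config$hartree_to_ev),
       A_eV = electron_affinity(e("neutral"), e("anion"),
                                factor = config$hartree_to_ev),
       source = "energies", notes = notes)
}
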