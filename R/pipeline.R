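# Orchestration: read -> descriptors per phase -> DAM -> phase comparison
# -> FMO -> assay -> correlation -> report bundle. Stage order is fixed so
# logs and bundles are reproducible; per-compound failures are isolated and
# recorded, never fatal to the rest of the run.

#' Gas-versus-solvent descriptor shift
#'
#' Elementwise differences (solvent minus gas) of I, A and the DAM indices
#' for every compound present in both phases, with a qualitative per-row
#' summary ("donor weakened", "acceptor strengthened", ...) reported as
#' text alongside — not enforced as a sign constraint, since Rd in solvent
#' can rise even when donor efficiency is argued to fall.
#'
#' @param gas,solvent `global_descriptors` tables for the two phases.
#' @param gas_dam,solvent_dam Optional matching [dam_points()] tables; when
#'   given, `delta_Rd`/`delta_Ra` are included.
#' @return data.frame with columns `compound_id`, `delta_I_eV`,
#'   `delta_A_eV`, optionally `delta_Rd`, `delta_Ra`, and `summary`.
#'   Compounds missing from either phase are skipped and listed in the
#'   `"skipped"` attribute.
#' @export
#' @examples
#' g <- global_descriptors(7.15, 0.07, compound_id = "lupinifolin", phase = "gas")
#' m <- global_descriptors(5.77, 1.71, compound_id = "lupinifolin", phase = "methanol")
#' compare_phases(g, m)  # delta_I = -1.38, delta_A = +1.64
compare_phases <- function(gas, solvent, gas_dam = NULL, solvent_dam = NULL) {
  stopifnot(is.data.frame(gas), is.data.frame(solvent))
  shared <- intersect(gas$compound_id, solvent$compound_id)
  skipped <- setdiff(union(gas$compound_id, solvent$compound_id), shared)
  g <- gas[match(shared, gas$compound_id), , drop = FALSE]
  s <- solvent[match(shared, solvent$compound_id), , drop = FALSE]
  out <- data.frame(compound_id = shared,
                    delta_I_eV = s$I_eV - g$I_eV,
                    delta_A_eV = s$A_eV - g$A_eV,
                    stringsAsFactors = FALSE)
  if (!is.null(gas_dam) && !is.null(solvent_dam)) {
    gd <- gas_dam[match(shared, gas_dam$compound_id), , drop = FALSE]
    sd_ <- solvent_dam[match(shared, solvent_dam$compound_id), , drop = FALSE]
    out$delta_Rd <- sd_$Rd - gd$Rd
    out$delta_Ra <- sd_$Ra - gd$Ra
  }
  out$summary <- if (!nrow(out)) character() else paste0(
    ifelse(out$delta_I_eV < 0, "I decreased (ionization easier)",
           ifelse(out$delta_I_eV > 0, "I increased", "I unchanged")), "; ",
    ifelse(out$delta_A_eV > 0, "A increased (acceptor strengthened)",
           ifelse(out$delta_A_eV < 0, "A decreased", "A unchanged")))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (length(skipped)) {
    message("compare_phases: skipped (missing in one phase): ",
            paste(skipped, collapse = ", "))
  }
  out
}

merge_record_lists <- function(primary, secondary) {
  # secondary fills compounds absent from primary; for shared ids the
  # primary record wins field-by-field where it has content
  out <- primary
  for (id in names(secondary)) {
    if (!id %in% names(out)) {
      out[[id]] <- secondary[[id]]
    } else {
      a <- out[[id]]; b <- secondary[[id]]
      if (is.null(a$ia_override)) a$ia_override <- b$ia_override
      if (!nrow(a$species)) a$species <- b$species
      if (!is.finite(a$homo_eV)) a$homo_eV <- b$homo_eV
      if (!is.finite(a$lumo_eV)) a$lumo_eV <- b$lumo_eV
      if (!is.finite(a$ic50_ppm)) a$ic50_ppm <- b$ic50_ppm
      out[[id]] <- a
    }
  }
  out
}

#' Run the full profiling pipeline
#'
#' Executes the fixed stage order — descriptors per phase, DAM, phase
#' comparison, FMO ranking and consistency, assay fits, descriptor-IC50
#' correlation — and returns everything as one report bundle stamped with
#' the configuration hash, convention and seed. Any per-compound failure
#' (e.g. a degenerate I <= A) is isolated into the bundle's `failures`
#' table; only unreadable inputs are hard errors.
#'
#' @param config An [ar_config()], or the path to a key-value config file
#'   (see [read_ar_config()]) whose `energies_file`/`ia_file`/`assay_file`
#'   keys name the inputs.
#' @param ia_file,energies_file,assay_file Optional input paths overriding
#'   the config file's keys.
#' @param phases Phases to profile; default: every phase present in the
#'   records.
#' @return Object of class `ar_report`: list of tables (`descriptors`,
#'   `dam`, `phase_shift`, `fmo`, `assay`, `correlation`, `failures`,
#'   `log`) plus `metadata`.
#' @export
run_pipeline <- function(config = ar_config(), ia_file = NULL,
                         energies_file = NULL, assay_file = NULL,
                         phases = NULL) {
  if (is.character(config)) config <- read_ar_config(config)
  stopifnot(inherits(config, "ar_config"))
  inputs <- attr(config, "inputs")
  ia_file <- ia_file %||% inputs$ia_file
  energies_file <- energies_file %||% inputs$energies_file
  assay_file <- assay_file %||% inputs$assay_file
  phases <- phases %||% inputs$phases

  log_lines <- character()
  log_add <- function(level, stage, msg) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf("[%s] %s: %s", level, stage, msg)
  }

  records <- list()
  if (!is.null(ia_file)) {
    records <- read_compound_table(ia_file, "ia_values")
    log_add("info", "read", sprintf("ia_values: %d record(s) from %s",
                                    length(records), ia_file))
  }
  if (!is.null(energies_file)) {
    erecs <- read_compound_table(energies_file, "energies")
    log_add("info", "read", sprintf("energies: %d record(s) from %s",
                                    length(erecs), energies_file))
    records <- merge_record_lists(records, erecs)
  }
  if (!length(records)) {
    log_add("warn", "read", "no compound records; empty bundle")
  }

  if (is.null(phases)) {
    phases <- unique(c(
      unlist(lapply(records, function(r) r$ia_override$phase)),
      unlist(lapply(records, function(r) unique(r$species$phase)))))
  }

  desc_all <- list(); dam_all <- list(); failures <- list()
  for (ph in phases) {
    eligible <- Filter(function(r) {
      v <- validate_record(r, ph)
      v$eligible[v$stage == "descriptors"]
    }, records)
    if (!length(eligible)) next
    desc <- descriptor_table(eligible, phase = ph, config = config)
    fl <- attr(desc, "failures")
    if (nrow(fl)) {
      failures[[length(failures) + 1L]] <- cbind(stage = "descriptors", fl)
      for (k in seq_len(nrow(fl))) log_add("error", "descriptors", fl$error[k])
    }
    log_add("info", "descriptors",
            sprintf("phase %s: %d compound(s)", ph, nrow(desc)))
    pts <- dam_points(desc, config)
    log_add("info", "dam", sprintf("phase %s: %d point(s)", ph, nrow(pts)))
    desc_all[[ph]] <- desc
    dam_all[[ph]] <- pts
  }
  descriptors <- if (length(desc_all)) do.call(rbind, desc_all) else NULL
  if (!is.null(descriptors)) rownames(descriptors) <- NULL

  dam <- NULL
  if (length(dam_all)) {
    pooled <- do.call(rbind, dam_all)
    rownames(pooled) <- NULL
    dam <- build_dam_table(pooled, config)
  }

  phase_shift <- NULL
  if (length(desc_all) >= 2L) {
    ref <- if ("gas" %in% names(desc_all)) "gas" else names(desc_all)[1L]
    for (ph in setdiff(names(desc_all), ref)) {
      ps <- compare_phases(desc_all[[ref]], desc_all[[ph]],
                           dam_all[[ref]], dam_all[[ph]])
      ps$phase_from <- ref; ps$phase_to <- ph
      phase_shift <- rbind(phase_shift, ps)
      log_add("info", "phases", sprintf("%s -> %s: %d compound(s)",
                                        ref, ph, nrow(ps)))
    }
  }

  fmo <- NULL
  homo_df <- do.call(rbind, lapply(records, function(r) {
    if (!is.finite(r$homo_eV)) return(NULL)
    frontier_orbitals(r$compound_id, r$homo_eV, r$lumo_eV)
  }))
  if (!is.null(homo_df) && nrow(homo_df)) {
    ranked <- rank_by_homo(homo_df)
    consistency <- if (!is.null(descriptors)) {
      koopmans_consistency(ranked, descriptors[descriptors$phase == phases[1L], ,
                                               drop = FALSE])
    } else NULL
    fmo <- list(table = ranked, consistency = consistency)
    log_add("info", "fmo", sprintf("%d compound(s) ranked; concordance %s",
                                   nrow(ranked),
                                   if (is.null(consistency)) "n/a" else
                                     sprintf("%.3f", consistency$concordance)))
  }

  assay <- NULL
  ic50_tab <- do.call(rbind, lapply(records, function(r) {
    if (!is.finite(r$ic50_ppm)) return(NULL)
    data.frame(compound_id = r$compound_id, ic50_ppm = r$ic50_ppm,
               source = "reported", stringsAsFactors = FALSE)
  }))
  if (!is.null(assay_file)) {
    curves <- read_assay_table(assay_file)
    fits <- list()
    for (id in names(curves)) {
      fit <- tryCatch(fit_ic50(curves[[id]], model = config$assay_model,
                               allow_extrapolation = TRUE),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          stage = "assay", compound_id = id, error = conditionMessage(fit))
        log_add("error", "assay", conditionMessage(fit))
      } else {
        fits[[id]] <- fit
      }
    }
    if (length(fits)) {
      fitted_tab <- data.frame(
        compound_id = names(fits),
        ic50_ppm = vapply(fits, `[[`, 0, "ic50"),
        source = "fitted", stringsAsFactors = FALSE)
      # fitted values win over reported ones for shared compounds
      if (!is.null(ic50_tab)) {
        ic50_tab <- ic50_tab[!ic50_tab$compound_id %in% fitted_tab$compound_id, ,
                             drop = FALSE]
      }
      ic50_tab <- rbind(fitted_tab, ic50_tab)
      assay <- list(fits = fits, ic50 = ic50_tab)
      log_add("info", "assay", sprintf("%d curve(s) fitted (%s)",
                                       length(fits), config$assay_model))
    }
  } else if (!is.null(ic50_tab)) {
    assay <- list(fits = list(), ic50 = ic50_tab)
    log_add("info", "assay", sprintf("%d reported IC50(s)", nrow(ic50_tab)))
  }
  if (!is.null(assay)) rownames(assay$ic50) <- NULL

  correlation <- NULL
  if (!is.null(assay) && !is.null(descriptors)) {
    ph1 <- if ("gas" %in% descriptors$phase) "gas" else descriptors$phase[1L]
    desc_ph <- descriptors[descriptors$phase == ph1, , drop = FALSE]
    wide <- merge(desc_ph, dam[!dam$is_reference & dam$phase == ph1,
                               c("compound_id", "Rd", "Ra")],
                  by = "compound_id", all.x = TRUE)
    if (!is.null(fmo)) {
      wide <- merge(wide, fmo$table[, c("compound_id", "homo_eV")],
                    by = "compound_id", all.x = TRUE)
    }
    correlation <- tryCatch(correlate_descriptors(wide, assay$ic50),
                            error = function(e) NULL)
    if (!is.null(correlation)) {
      log_add("info", "correlate",
              sprintf("%d descriptor(s) correlated with IC50 (phase %s)",
                      nrow(correlation$summary), ph1))
    }
  }

  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(stage = character(), compound_id = character(),
               error = character())
  rownames(failures) <- NULL
  bundle <- structure(
    list(descriptors = descriptors, dam = dam, phase_shift = phase_shift,
         fmo = fmo, assay = assay, correlation = correlation,
         failures = failures, log = log_lines,
         metadata = list(
           config_hash = config_hash(config),
           convention = config$convention,
           seed = config$seed,
           phases = phases,
           package_version = as.character(utils::packageVersion("antiradical")))),
    class = "ar_report")
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ar_report <- function(x, ...) {
  cat("<ar_report>\n")
  cat(sprintf("  convention %s; seed %d; config %s\n", x$metadata$convention,
              x$metadata$seed, substr(x$metadata$config_hash, 1, 8)))
  cat(sprintf("  descriptors: %s rows; dam: %s rows; failures: %d\n",
              if (is.null(x$descriptors)) 0L else nrow(x$descriptors),
              if (is.null(x$dam)) 0L else nrow(x$dam), nrow(x$failures)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the bundle's tables under `out_dir` as CSV (or JSON), plus a
#' `run_metadata.json` carrying the configuration hash, convention, seed
#' and package version. Machine-readable outputs are byte-stable across
#' reruns of the same config and inputs.
#'
#' @param bundle An `ar_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "ar_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    if (format == "csv") {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE, quote = TRUE)
    } else {
      jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                           dataframe = "rows", digits = NA, auto_unbox = TRUE)
    }
  }
  emit(bundle$descriptors, "descriptors")
  emit(bundle$dam, "dam")
  emit(bundle$phase_shift, "phase_shift")
  if (!is.null(bundle$fmo)) emit(bundle$fmo$table, "fmo")
  if (!is.null(bundle$assay)) emit(bundle$assay$ic50, "ic50")
  if (!is.null(bundle$correlation)) emit(bundle$correlation$summary, "correlation")
  emit(bundle$failures, "failures")
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(bundle$metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
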