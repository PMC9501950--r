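# Synthetic-data generator: energy triplets that invert the I/A definitions
# around a free neutral base (only differences matter downstream), and
# sigmoidal DPPH curves with multiplicative noise. Everything is seeded and
# leaves the global RNG state untouched.

# Run `expr` under a local RNG seed, restoring the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Generate an energy triplet realizing target I and A
#'
#' Inverts the vertical definitions around an arbitrary neutral base:
#' `E(neutral) = base`, `E(cation) = base + I/F`, `E(anion) = base - A/F`
#' (F = eV per hartree), so feeding the triplet back through
#' [ionization_potential()] / [electron_affinity()] recovers the targets
#' exactly (to floating point). The base is free because only energy
#' differences enter the pipeline.
#'
#' @param target_I,target_A Target vertical I and A in eV; requires
#'   `target_I > target_A`.
#' @param neutral_energy_base Neutral total energy in hartree.
#' @param phase Phase label.
#' @param compound_id Identifier stamped on the rows.
#' @param factor eV-per-hartree factor.
#' @return Three-row species data.frame (neutral, cation, anion).
#' @export
#' @examples
#' tr <- gen_energy_triplet(7.15, 0.07, -687.963)
#' ionization_potential(tr$energy_hartree[2], tr$energy_hartree[1])  # 7.15
gen_energy_triplet <- function(target_I, target_A, neutral_energy_base = -500,
                               phase = "gas", compound_id = "synthetic",
                               factor = hartree_ev_factor()) {
  stopifnot(is.finite(target_I), is.finite(target_A),
            is.finite(neutral_energy_base))
  if (target_I <= target_A) {
    stop("gen_energy_triplet(", compound_id, "): target I must exceed target A",
         call. = FALSE)
  }
  rbind(
    species_energy(compound_id, "neutral", phase, neutral_energy_base,
                   method_tag = "synthetic"),
    species_energy(compound_id, "cation", phase,
                   neutral_energy_base + target_I / factor,
                   method_tag = "synthetic"),
    species_energy(compound_id, "anion", phase,
                   neutral_energy_base - target_A / factor,
                   method_tag = "synthetic"))
}

#' Generate a noisy logistic dose-response curve
#'
#' Ground truth is the Hill logistic
#' `inhibition(c) = 100 / (1 + (IC50 / c)^hill)` (50% exactly at the IC50),
#' perturbed by multiplicative Gaussian noise
#' `y * (1 + N(0, noise_sd))` and clamped to \[-10, 110\] (clamping is
#' counted in the `"n_clamped"` attribute). Deterministic for a fixed seed;
#' the caller's RNG state is preserved.
#'
#' @param true_ic50 True IC50 in ppm, > 0.
#' @param hill_slope Hill coefficient (dimensionless, default 1).
#' @param concentrations Strictly positive, strictly increasing ppm vector.
#' @param noise_sd Relative noise standard deviation (fraction; 0.02 = 2%).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [dose_response_curve()] with attribute `"true_ic50"`.
#' @export
#' @examples
#' gen_dose_response(128.64, 1, c(50, 100, 128.64, 200, 400), noise_sd = 0)
gen_dose_response <- function(true_ic50, hill_slope = 1, concentrations,
                              noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(true_ic50), true_ic50 > 0,
            is.numeric(concentrations), all(concentrations > 0),
            !is.unsorted(concentrations, strictly = TRUE),
            noise_sd >= 0)
  clean <- 100 / (1 + (true_ic50 / concentrations)^hill_slope)
  noisy <- if (noise_sd > 0) {
    draw <- function() clean * (1 + stats::rnorm(length(clean), 0, noise_sd))
    if (is.null(seed)) draw() else with_local_seed(seed, draw())
  } else clean
  n_clamped <- sum(noisy < -10 | noisy > 110)
  if (n_clamped > 0) {
    message("gen_dose_response: clamped ", n_clamped, " reading(s) to [-10, 110]")
  }
  noisy <- pmin(pmax(noisy, -10), 110)
  curve <- dose_response_curve("synthetic", concentrations, inhibition = noisy)
  attr(curve, "true_ic50") <- true_ic50
  curve
}

#' Bundled reference panel of flavanone antiradicals
#'
#' Published B3LYP/6-31+G(2d,2p) vertical I/A values, HOMO energies and
#' DPPH IC50s for three prenylated flavanones isolated from
#' *Erythrina crista-galli* twigs (lupinifolin, citflavanone, lonchocarpol
#' A) and the two reference antioxidants (quercetin, ascorbic acid): the
#' standard worked example for this package and the ground-truth targets of
#' the `"flavanones"` synthetic preset. Citflavanone's gas-phase A appears
#' in the literature both as -0.00 and at higher precision as -0.01; the
#' higher-precision value is used here and the coarser one is noted.
#'
#' @return List of data.frames: `ia` (compound_id, phase, I_eV, A_eV),
#'   `homo` (compound_id, homo_eV, gas phase), `ic50` (compound_id,
#'   ic50_ppm), `extracts` (crude-extract IC50s, assay context only).
#' @export
flavanone_panel <- function() {
  ia <- data.frame(
    compound_id = c("lupinifolin", "citflavanone", "lonchocarpol_A",
                    "quercetin", "ascorbic_acid",
                    "lupinifolin", "citflavanone", "lonchocarpol_A"),
    phase = c(rep("gas", 5L), rep("methanol", 3L)),
    I_eV = c(7.15, 7.24, 7.24, 8.03, 9.74, 5.77, 5.76, 5.98),
    A_eV = c(0.07, -0.01, -0.10, 2.99, 3.06, 1.71, 1.74, 1.65),
    stringsAsFactors = FALSE)
  homo <- data.frame(
    compound_id = c("lupinifolin", "citflavanone", "lonchocarpol_A"),
    phase = "gas",
    homo_eV = c(-5.7590, -5.7835, -5.8950),
    stringsAsFactors = FALSE)
  ic50 <- data.frame(
    compound_id = c("lupinifolin", "citflavanone", "lonchocarpol_A",
                    "quercetin", "ascorbic_acid"),
    ic50_ppm = c(128.64, 548.72, 441.49, 8.14, 4.53),
    stringsAsFactors = FALSE)
  extracts <- data.frame(
    sample = c("n-hexane extract", "ethyl acetate extract"),
    ic50_ppm = c(536.47, 64.41),
    stringsAsFactors = FALSE)
  list(ia = ia, homo = homo, ic50 = ic50, extracts = extracts)
}

#' Specification for a synthetic compound panel
#'
#' Declares the ground truth a generated panel must realize: per-compound,
#' per-phase target I/A (eV), optional frontier orbitals, optional true
#' IC50s with Hill slope and relative noise, a neutral energy base and the
#' assay concentration grid. The `"flavanones"` preset uses the
#' [flavanone_panel()] values (five gas-phase compounds, three methanol
#' rows, three HOMO energies, five IC50s) with Hill slope 1 and 2%
#' multiplicative noise — a realistic microplate-readout error — on an
#' 8-point two-fold dilution series centered on each compound's IC50.
#'
#' @param preset `"flavanones"` or `"custom"`.
#' @param seed Integer master seed; per-curve seeds are derived from it.
#' @param compounds For `"custom"`: data.frame with columns `compound_id`,
#'   `phase`, `I_eV`, `A_eV` and optionally `homo_eV`, `lumo_eV`,
#'   `ic50_ppm`, `hill_slope`, `noise_sd`.
#' @param neutral_energy_base Neutral total energy in hartree (arbitrary;
#'   only differences matter).
#' @param concentrations `"auto"` (8-point two-fold series centered on each
#'   true IC50) or a strictly increasing ppm vector shared by all curves.
#' @param hill_slope,noise_sd Defaults applied where the compound table has
#'   none.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("flavanones", "custom"), seed = 1L,
                           compounds = NULL, neutral_energy_base = -500,
                           concentrations = "auto", hill_slope = 1,
                           noise_sd = 0.02) {
  preset <- match.arg(preset)
  if (preset == "flavanones") {
    panel <- flavanone_panel()
    compounds <- merge(panel$ia,
                       merge(panel$homo[, c("compound_id", "homo_eV")],
                             panel$ic50, by = "compound_id", all = TRUE),
                       by = "compound_id", all.x = TRUE)
  }
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "phase", "I_eV", "A_eV") %in% names(compounds)))
  if (any(compounds$I_eV <= compounds$A_eV)) {
    stop("synthetic_spec: every target must satisfy I > A", call. = FALSE)
  }
  for (col in c("homo_eV", "lumo_eV", "ic50_ppm")) {
    if (!col %in% names(compounds)) compounds[[col]] <- NA_real_
  }
  if (!"hill_slope" %in% names(compounds)) compounds$hill_slope <- hill_slope
  if (!"noise_sd" %in% names(compounds)) compounds$noise_sd <- noise_sd
  if (any(compounds$noise_sd < 0, na.rm = TRUE)) {
    stop("synthetic_spec: noise_sd must be >= 0", call. = FALSE)
  }
  if (is.numeric(concentrations) &&
      is.unsorted(concentrations, strictly = TRUE)) {
    stop("synthetic_spec: concentrations must be strictly increasing",
         call. = FALSE)
  }
  compounds <- compounds[order(compounds$compound_id, compounds$phase), ,
                         drop = FALSE]
  rownames(compounds) <- NULL
  structure(
    list(preset = preset, seed = as.integer(seed), compounds = compounds,
         neutral_energy_base = neutral_energy_base,
         concentrations = concentrations),
    class = "synthetic_spec")
}

# 8-point two-fold dilution series centered (geometrically) on the IC50.
auto_concentrations <- function(true_ic50) {
  true_ic50 * 2^seq(-3.5, 3.5, by = 1)
}

#' Generate a full synthetic panel
#'
#' Realizes a [synthetic_spec()] as the pipeline's own input dialects:
#' an energies table (triplets inverting the I/A definitions), an
#' equivalent ia_values table carrying HOMO/LUMO and true IC50 columns, and
#' an assay table of noisy logistic dose-response readings for every
#' compound with a true IC50. Deterministic for a fixed spec seed
#' (per-curve seeds are derived as `seed + row index`); running twice gives
#' identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @return List with data.frames `energies`, `ia_values`, `assay` and the
#'   `truth` table (the spec's compounds). Write with [write_panel()].
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cp <- spec$compounds
  energy_rows <- list(); assay_rows <- list()
  for (i in seq_len(nrow(cp))) {
    energy_rows[[i]] <- gen_energy_triplet(
      cp$I_eV[i], cp$A_eV[i], spec$neutral_energy_base,
      phase = cp$phase[i], compound_id = cp$compound_id[i])
    first_phase_row <- !duplicated(cp$compound_id)[i]
    if (is.finite(cp$ic50_ppm[i]) && first_phase_row) {
      conc <- if (identical(spec$concentrations, "auto")) {
        auto_concentrations(cp$ic50_ppm[i])
      } else spec$concentrations
      curve <- gen_dose_response(cp$ic50_ppm[i], cp$hill_slope[i], conc,
                                 noise_sd = cp$noise_sd[i],
                                 seed = spec$seed + i)
      assay_rows[[length(assay_rows) + 1L]] <- data.frame(
        compound_id = cp$compound_id[i],
        concentration_ppm = curve$concentration_ppm,
        inhibition_pct = curve$inhibition_pct,
        stringsAsFactors = FALSE)
    }
  }
  energies <- do.call(rbind, energy_rows)
  ia_values <- cp[, c("compound_id", "phase", "I_eV", "A_eV",
                      "homo_eV", "lumo_eV", "ic50_ppm")]
  assay <- if (length(assay_rows)) do.call(rbind, assay_rows) else
    data.frame(compound_id = character(), concentration_ppm = numeric(),
               inhibition_pct = numeric())
  rownames(energies) <- rownames(ia_values) <- rownames(assay) <- NULL
  list(energies = energies, ia_values = ia_values, assay = assay, truth = cp)
}

#' Write a generated panel as canonical CSV inputs
#'
#' Emits `energies.csv`, `ia_values.csv` and `assay.csv` (the exact
#' dialects consumed by [read_compound_table()] and [read_assay_table()])
#' into a directory.
#'
#' @param panel A [gen_panel()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(energies = file.path(dir, "energies.csv"),
             ia_values = file.path(dir, "ia_values.csv"),
             assay = file.path(dir, "assay.csv"))
  write_df_canonical <- function(df, path) {
    txt <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(df[i, , drop = FALSE], function(v) {
        if (is.numeric(v)) format_canonical(v) else as.character(v)
      }, ""), collapse = ",")
    }, "")
    con <- file(path, open = "wb")
    writeLines(c(paste(names(df), collapse = ","), txt), con, sep = "\n")
    close(con)
  }
  write_df_canonical(panel$energies, paths[["energies"]])
  write_df_canonical(panel$ia_values, paths[["ia_values"]])
  write_df_canonical(panel$assay, paths[["assay"]])
  invisible(paths)
}
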