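test_that("generated triplets invert the I/A definitions exactly", {
  tr <- gen_energy_triplet(7.15, 0.07, -687.963, compound_id = "lup")
  e <- setNames(tr$energy_hartree, tr$charge_state)
  expect_equal(unname(ionization_potential(e["cation"], e["neutral"])),
               7.15, tolerance = 1e-9)
  expect_equal(unname(electron_affinity(e["neutral"], e["anion"])),
               0.07, tolerance = 1e-9)
  # A = 0 means the anion is energy-degenerate with the neutral
  tr0 <- gen_energy_triplet(1.0, 0.0, 0.0)
  expect_equal(tr0$energy_hartree[tr0$charge_state == "anion"], 0)
  expect_equal(tr0$energy_hartree[tr0$charge_state == "cation"],
               1 / 27.211386, tolerance = 1e-15)
  expect_error(gen_energy_triplet(1, 2, 0), "exceed")
})

test_that("the noise-free dose-response follows the closed-form logistic", {
  c50 <- gen_dose_response(128.64, 1, c(64, 128.64, 256), noise_sd = 0)
  expect_equal(c50$inhibition_pct[c50$concentration_ppm == 128.64], 50)
  c10 <- gen_dose_response(10, 1, c(100), noise_sd = 0)
  expect_equal(c10$inhibition_pct, 100 / 1.1, tolerance = 1e-12)  # 90.909...
  expect_equal(attr(c50, "true_ic50"), 128.64)
})

test_that("generation is seed-deterministic and leaves the global RNG alone", {
  conc <- c(10, 20, 40, 80)
  a <- gen_dose_response(30, 1, conc, noise_sd = 0.05, seed = 99)
  b <- gen_dose_response(30, 1, conc, noise_sd = 0.05, seed = 99)
  expect_identical(a$inhibition_pct, b$inhibition_pct)
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_dose_response(30, 1, conc, 0.05, seed = 7))
  expect_identical(runif(1), before)
})

test_that("extreme noise draws are clamped to [-10, 110] with a notice", {
  expect_message(
    curve <- gen_dose_response(10, 1, c(1000, 2000, 4000), noise_sd = 3, seed = 2),
    "clamped")
  expect_true(all(curve$inhibition_pct >= -10 & curve$inhibition_pct <= 110))
})

test_that("the flavanones preset carries the published targets", {
  spec <- synthetic_spec("flavanones", seed = 1)
  panel <- gen_panel(spec)
  ia <- panel$ia_values
  expect_equal(sum(ia$phase == "gas"), 5L)
  expect_equal(sum(ia$phase == "methanol"), 3L)
  expect_equal(ia$I_eV[ia$compound_id == "lupinifolin" & ia$phase == "gas"], 7.15)
  expect_equal(ia$A_eV[ia$compound_id == "lonchocarpol_A" & ia$phase == "gas"], -0.10)
  expect_equal(ia$I_eV[ia$compound_id == "citflavanone" & ia$phase == "methanol"], 5.76)
  # energies dialect and assay curves cover every compound
  expect_equal(nrow(panel$energies), 8L * 3L)
  expect_setequal(unique(panel$assay$compound_id), panel$truth$compound_id)
})

test_that("a fixed seed reproduces the panel byte-for-byte", {
  d1 <- tempfile(); d2 <- tempfile()
  write_panel(gen_panel(synthetic_spec("flavanones", seed = 42)), d1)
  write_panel(gen_panel(synthetic_spec("flavanones", seed = 42)), d2)
  for (f in c("energies.csv", "ia_values.csv", "assay.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- tempfile()
  write_panel(gen_panel(synthetic_spec("flavanones", seed = 43)), d3)
  expect_false(identical(readLines(file.path(d1, "assay.csv")),
                         readLines(file.path(d3, "assay.csv"))))
})

test_that("spec invariants are enforced", {
  bad <- data.frame(compound_id = "x", phase = "gas", I_eV = 1, A_eV = 2)
  expect_error(synthetic_spec("custom", compounds = bad), "I > A")
  ok <- data.frame(compound_id = "x", phase = "gas", I_eV = 7, A_eV = 1)
  expect_error(synthetic_spec("custom", compounds = ok,
                              concentrations = c(2, 1, 3)), "increasing")
  expect_error(synthetic_spec("custom", compounds = ok, noise_sd = -1), ">= 0")
})

test_that("noise-free panels round-trip through the whole pipeline to 1e-6", {
  cp <- data.frame(compound_id = c("a", "b"), phase = "gas",
                   I_eV = c(7.5, 9.1), A_eV = c(0.3, 2.8),
                   ic50_ppm = c(120, 15), hill_slope = 1.5, noise_sd = 0)
  spec <- synthetic_spec("custom", seed = 5, compounds = cp)
  panel <- gen_panel(spec)
  d <- tempfile()
  paths <- write_panel(panel, d)
  recs <- read_compound_table(paths[["energies"]], "energies")
  desc <- descriptor_table(recs, "gas")
  target <- global_descriptors(cp$I_eV, cp$A_eV, compound_id = cp$compound_id)
  expect_rel_equal(desc$omega_eV, target$omega_eV, 1e-6)
  expect_rel_equal(desc$S, target$S, 1e-6)
  pts <- dam_points(desc)
  tpts <- dam_points(target)
  expect_rel_equal(pts$Rd, tpts$Rd, 1e-6)
  expect_rel_equal(pts$Ra, tpts$Ra, 1e-6)
  curves <- read_assay_table(paths[["assay"]])
  for (id in names(curves)) {
    fit <- fit_ic50(curves[[id]], "four_parameter_logistic")
    expect_rel_equal(fit$ic50, cp$ic50_ppm[cp$compound_id == id], 1e-4)
  }
})
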