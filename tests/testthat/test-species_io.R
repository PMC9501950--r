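test_that("unit conversion matches the fixed factor and round-trips", {
  expect_identical(hartree_to_ev(0), 0)
  expect_equal(hartree_to_ev(1), 27.211386)
  expect_equal(hartree_to_ev(0.263), 7.1566, tolerance = 1e-4)
  set.seed(11)
  x <- runif(50, -1000, 1000)
  expect_rel_equal(ev_to_hartree(hartree_to_ev(x)), x, 1e-12)
  expect_error(hartree_to_ev(Inf))
})

test_that("energies dialect reads one record per compound", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,charge_state,phase,energy_hartree",
               "cmp1,neutral,gas,-687.963",
               "cmp1,cation,gas,-687.700",
               "cmp1,anion,gas,-687.966"), f)
  recs <- read_compound_table(f, "energies")
  expect_length(recs, 1L)
  expect_s3_class(recs$cmp1, "compound_record")
  expect_equal(nrow(recs$cmp1$species), 3L)
  expect_setequal(recs$cmp1$species$charge_state, c("neutral", "cation", "anion"))
})

test_that("ia_values dialect fills overrides for the reference panel", {
  f <- write_gas_ia_csv()
  recs <- read_compound_table(f, "ia_values")
  expect_length(recs, 5L)
  expect_equal(recs$lupinifolin$ia_override$I_eV, 7.15)
  expect_equal(recs$lupinifolin$ia_override$A_eV, 0.07)
  expect_equal(record_ia(recs$quercetin, "gas")$source, "override")
})

test_that("format errors name the missing column; duplicates are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,charge_state,energy_hartree",
               "c1,neutral,-1.0"), f)
  expect_error(read_compound_table(f, "energies"), "phase")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,charge_state,phase,energy_hartree",
               "c1,neutral,gas,-1.0",
               "c1,neutral,gas,-2.0"), f2)
  expect_error(read_compound_table(f2, "energies"), "duplicate")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,phase,I_eV,A_eV",
               "c1,gas,7,0", "c1,gas,7,0"), f3)
  expect_error(read_compound_table(f3, "ia_values"), "duplicate")
})

test_that("a record missing the anion row is flagged incomplete", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,charge_state,phase,energy_hartree",
               "c1,neutral,gas,-687.963",
               "c1,cation,gas,-687.700"), f)
  rec <- read_compound_table(f, "energies")$c1
  v <- validate_record(rec, "gas")
  expect_false(v$eligible[v$stage == "descriptors"])
  expect_match(v$reason[v$stage == "descriptors"], "anion")
  expect_error(record_ia(rec, "gas"), "no I/A source")
})

test_that("validate_record reports stage eligibility from field presence", {
  r1 <- compound_record("a", ia_override = data.frame(phase = "gas",
                                                      I_eV = 7, A_eV = 0))
  v1 <- validate_record(r1, "gas")
  expect_true(all(v1$eligible[v1$stage %in% c("descriptors", "dam")]))
  expect_false(v1$eligible[v1$stage == "fmo"])
  r2 <- compound_record("b", homo_eV = -5.5, lumo_eV = -1.0)
  expect_true(validate_record(r2)$eligible[3])
  r3 <- compound_record("c")
  v3 <- validate_record(r3, "gas")
  expect_false(any(v3$eligible))
  expect_true(all(nzchar(v3$reason)))
})

test_that("an I/A override wins over an available triplet with a notice", {
  sp <- gen_energy_triplet(7.0, 0.5, -100, compound_id = "x")
  rec <- compound_record("x", species = sp,
                         ia_override = data.frame(phase = "gas",
                                                  I_eV = 7.15, A_eV = 0.07))
  expect_match(rec$notes, "override wins")
  ia <- record_ia(rec, "gas")
  expect_equal(ia$I_eV, 7.15)
  expect_equal(ia$source, "override")
  expect_match(ia$notes, "override used")
})

test_that("a value printed as -0.00 parses to 0 with the sign surfaced", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,phase,I_eV,A_eV",
               "citflavanone,gas,7.24,-0.00"), f)
  rec <- read_compound_table(f, "ia_values")$citflavanone
  expect_identical(rec$ia_override$A_eV, 0)
  expect_match(rec$notes, "printed as -0")
})

test_that("the canonical writer is byte-stable under read/write round-trips", {
  panel <- gen_panel(synthetic_spec("flavanones", seed = 3))
  d <- tempfile(); dir.create(d)
  p1 <- file.path(d, "t1.csv"); p2 <- file.path(d, "t2.csv")
  recs <- read_compound_table(write_panel(panel, d)[["ia_values"]], "ia_values")
  write_compound_table(recs, p1, "ia_values")
  recs2 <- read_compound_table(p1, "ia_values")
  write_compound_table(recs2, p2, "ia_values")
  expect_identical(readLines(p1), readLines(p2))
  # energies dialect too
  e1 <- file.path(d, "e1.csv"); e2 <- file.path(d, "e2.csv")
  er <- read_compound_table(file.path(d, "energies.csv"), "energies")
  write_compound_table(er, e1, "energies")
  write_compound_table(read_compound_table(e1, "energies"), e2, "energies")
  expect_identical(readLines(e1), readLines(e2))
})
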