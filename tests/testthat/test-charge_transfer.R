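test_that("donating and accepting powers reproduce the published 2-dp values", {
  expect_equal(round2(donating_power(7.15, 0.07)), 4.09)
  expect_equal(round2(accepting_power(7.15, 0.07)), 0.48)
  expect_equal(round2(donating_power(9.74, 3.06)), 9.75)
  expect_equal(round2(accepting_power(9.74, 3.06)), 3.35)
  # vanishing numerators
  expect_equal(donating_power(1, -3), 0)
  expect_equal(accepting_power(3, -1), 0)
  expect_error(donating_power(1, 1, compound_id = "flat"), "flat")
  expect_error(accepting_power(1, 2), "degenerate")
})

test_that("indices self-normalize the references to exactly 1", {
  na <- reference_atom("Na", 5.139, 0.548)
  f <- reference_atom("F", 17.423, 3.401)
  expect_identical(donation_index(reference_power(na, "donating"), na), 1)
  expect_identical(acceptance_index(reference_power(f, "accepting"), f), 1)
})

test_that("indices reproduce the published panel values", {
  expect_equal(round2(donation_index(donating_power(7.15, 0.07))), 1.18)
  expect_equal(round2(donation_index(donating_power(9.74, 3.06))), 2.81)
  expect_equal(round2(donation_index(donating_power(7.24, -0.01))), 1.17)
  expect_equal(round2(acceptance_index(accepting_power(7.15, 0.07))), 0.14)
  expect_equal(round2(acceptance_index(accepting_power(8.03, 2.99))), 1.05)
})

test_that("default reference powers are validated by the printed-ratio oracle", {
  # each printed row implies the reference power as omega(printed)/index(printed),
  # up to the +-0.005 rounding of both 2-dp values; the tolerance per row is
  # 1% plus that propagated rounding uncertainty (dominant for the small
  # omega+/Ra rows, e.g. 0.40/0.12)
  pd <- printed_dam()
  na_ratio <- pd$omega_minus_eV / pd$Rd
  f_ratio <- pd$omega_plus_eV / pd$Ra
  na_power <- reference_power(reference_atom("Na", 5.139, 0.548), "donating")
  f_power <- reference_power(reference_atom("F", 17.423, 3.401), "accepting")
  tol_na <- 0.01 + 0.005 / pd$omega_minus_eV + 0.005 / pd$Rd
  tol_f <- 0.01 + 0.005 / pd$omega_plus_eV + 0.005 / pd$Ra
  expect_true(all(abs(na_power - na_ratio) / na_ratio < tol_na))
  expect_true(all(abs(f_power - f_ratio) / f_ratio < tol_f))
  # and the aggregate ratios pin the anchors to a fraction of a percent
  expect_lt(abs(mean(na_ratio) - na_power) / na_power, 0.005)
  expect_lt(abs(mean(f_ratio) - f_power) / f_power, 0.005)
})

test_that("omega_minus - omega_plus equals chi (property, 1e-9 eV)", {
  set.seed(7)
  A <- runif(500, -3, 5)
  I <- A + runif(500, 0.02, 10)
  diff_ <- donating_power(I, A) - accepting_power(I, A)
  expect_true(max(abs(diff_ - (I + A) / 2)) < 1e-9)
})

test_that("powers are monotone in I and A on their increasing domains", {
  # d(omega-)/dI has the sign of 3I - 7A, d(omega+)/dA the sign of
  # (I + 3A)(7I - 3A): monotone growth holds past those roots, which covers
  # every chemically sensible (I, A) pair
  A <- 0.5
  I <- seq(7 * A / 3 + 0.1, 10, by = 0.25)
  expect_true(all(diff(donating_power(I, A)) > 0))
  I0 <- 8
  Agrid <- seq(-I0 / 3 + 0.1, 7.5, by = 0.25)
  expect_true(all(diff(accepting_power(I0, Agrid)) > 0))
})

test_that("indices are invariant under a common change of energy unit", {
  na <- reference_atom("Na", 5.139, 0.548)
  u <- 0.0367493  # arbitrary unit scale
  na_u <- reference_atom("Na", 5.139 * u, 0.548 * u)
  rd_ev <- donation_index(donating_power(7.15, 0.07), na)
  rd_u <- donation_index(donating_power(7.15 * u, 0.07 * u), na_u)
  expect_equal(rd_u, rd_ev, tolerance = 1e-12)
})

test_that("sector classification follows the quadrants with lower-side boundaries", {
  cfg <- ar_config()
  expect_match(classify_sector(Ra = 0.2, Rd = 0.8, cfg), "antioxidant")
  expect_match(classify_sector(Ra = 1.4, Rd = 2.5, cfg), "anti-reductant")
  # boundary values classify to the lower side
  expect_match(classify_sector(Ra = 1.0, Rd = 1.0, cfg), "antioxidant")
  expect_match(classify_sector(Ra = 0.5, Rd = 1.2, cfg), "weak donor")
  expect_match(classify_sector(Ra = 1.2, Rd = 0.5, cfg), "weak acceptor")
})

test_that("the DAM table carries both sector readings and the two anchors", {
  gas <- flavanone_panel()$ia
  gas <- gas[gas$phase == "gas", ]
  d <- global_descriptors(gas$I_eV, gas$A_eV, compound_id = gas$compound_id)
  dam <- build_dam_table(dam_points(d))
  expect_equal(nrow(dam), 7L)  # 5 compounds + 2 anchors
  anchors <- dam[dam$is_reference, ]
  expect_equal(anchors$Rd[grepl("Na", anchors$compound_id)], 1)
  expect_equal(anchors$Ra[grepl("F", anchors$compound_id)], 1)
  cmp <- dam[!dam$is_reference, ]
  # deterministic ordering by compound_id
  expect_identical(cmp$compound_id, sort(gas$compound_id))
  # relative reading matches the published grouping: flavanones donor-leaning,
  # standards acceptor-leaning (even ascorbic acid at Ra 0.98)
  rel <- setNames(cmp$sector_relative, cmp$compound_id)
  expect_identical(unname(rel[c("lupinifolin", "citflavanone", "lonchocarpol_A")]),
                   rep("donor-leaning", 3))
  expect_identical(unname(rel[c("quercetin", "ascorbic_acid")]),
                   rep("acceptor-leaning", 2))
})

test_that("degenerate compounds are excluded from the map, the rest proceed", {
  ia <- data.frame(compound_id = c("ok", "flat"), phase = "gas",
                   I_eV = c(7, 4), A_eV = c(1, 4))
  pts <- dam_points(ia)
  expect_equal(pts$compound_id, "ok")
  expect_equal(attr(pts, "failures")$compound_id, "flat")
  # empty input yields an empty table with anchors intact
  dam <- build_dam_table(dam_points(ia[0, ]))
  expect_equal(sum(dam$is_reference), 2L)
  expect_equal(nrow(dam), 2L)
})

test_that("DAM export embeds the configuration in the JSON variant", {
  gas <- data.frame(compound_id = "x", phase = "gas", I_eV = 7.15, A_eV = 0.07)
  dam <- build_dam_table(dam_points(gas))
  f <- tempfile(fileext = ".csv")
  write_dam_table(dam, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  js <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(js$config$donor_reference$ionization_potential, 5.139)
  expect_equal(nrow(js$points), 3L)
})
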