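test_that("percent inhibition is the standard DPPH ratio", {
  expect_equal(percent_inhibition(0.8, 0.4), 50.0)
  expect_equal(percent_inhibition(0.8, 0.8), 0.0)
  expect_equal(percent_inhibition(0.5, 0.1), 80.0)
  expect_error(percent_inhibition(0, 0.1), "> 0")
  expect_message(percent_inhibition(0.5, 0.6), "pro-oxidant")
})

test_that("an exact 50% observation is returned as the IC50 verbatim", {
  curve <- dose_response_curve("x", c(50, 100, 200), c(30, 50, 75))
  fit <- fit_ic50(curve, "loglinear_interpolation")
  expect_equal(fit$ic50, 100)
  expect_false(fit$extrapolated)
})

test_that("log-linear interpolation recovers a symmetric logistic midpoint", {
  conc <- c(25, 50, 200, 400)
  y <- 100 / (1 + 100 / conc)  # hill 1, true IC50 100; no point at 50%
  fit <- fit_ic50(dose_response_curve("x", conc, y))
  # bracketing points are log-symmetric about 100, so interpolation is exact
  expect_equal(fit$ic50, 100, tolerance = 1e-9)
})

test_that("interpolation preconditions are enforced", {
  low <- dose_response_curve("low", c(1, 2, 4), c(5, 10, 20))
  expect_error(fit_ic50(low), "bracket")
  ex <- fit_ic50(low, allow_extrapolation = TRUE)
  expect_true(ex$extrapolated)
  expect_gt(ex$ic50, 4)
  expect_error(fit_ic50(dose_response_curve("c", c(1, 2, 4), c(20, 20, 20))),
               "constant")
  expect_error(fit_ic50(dose_response_curve("s", c(1, 2), c(10, 60))), ">= 3")
})

test_that("the logistic fit recovers a noise-free generated IC50 to 0.01 ppm", {
  curve <- gen_dose_response(128.64, hill_slope = 1,
                             concentrations = 128.64 * 2^seq(-3.5, 3.5, 1),
                             noise_sd = 0)
  fit <- fit_ic50(curve, "four_parameter_logistic")
  expect_equal(fit$ic50, 128.64, tolerance = 0.01 / 128.64)
  expect_equal(fit$parameters$hill, 1, tolerance = 1e-3)
  expect_error(fit_ic50(dose_response_curve("s", c(1, 2, 4), c(10, 50, 80)),
                        "four_parameter_logistic"), ">= 4")
})

test_that("interpolation and logistic fits agree on dense noise-free curves", {
  conc <- 200 * 2^seq(-4, 4, by = 0.5)
  curve <- gen_dose_response(200, hill_slope = 1.3, concentrations = conc,
                             noise_sd = 0)
  f1 <- fit_ic50(curve, "loglinear_interpolation")$ic50
  f2 <- fit_ic50(curve, "four_parameter_logistic")$ic50
  expect_lt(abs(f1 - f2) / f2, 0.02)
})

test_that("IC50 recovery bias stays within spec at 0 and 2% noise", {
  conc <- 100 * 2^seq(-3.5, 3.5, 1)  # n = 8
  clean <- fit_ic50(gen_dose_response(100, 1, conc, 0),
                    "four_parameter_logistic")$ic50
  expect_lt(abs(clean - 100) / 100, 0.01)
  noisy <- fit_ic50(gen_dose_response(100, 1, conc, 0.02, seed = 1),
                    "four_parameter_logistic")$ic50
  expect_lt(abs(noisy - 100) / 100, 0.05)
})

test_that("pearson correlation matches hand-computed product-moment sums", {
  exact <- pearson_correlation(1:5, 2 * (1:5) + 1)
  expect_equal(exact$r, 1.0)
  expect_equal(unname(exact$residuals), rep(0, 5), tolerance = 1e-12)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1.0)
  cr <- pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(cr$r, 0.8)
  expect_equal(sum(cr$residuals), 0, tolerance = 1e-12)
  expect_error(pearson_correlation(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
  expect_error(pearson_correlation(1:4, 1:5), "length")
})

test_that("r is affine-invariant and flips sign under negation", {
  set.seed(5)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, sd = 0.3)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("the descriptor battery correlates every usable column with IC50", {
  panel <- flavanone_panel()
  gas <- panel$ia[panel$ia$phase == "gas", ]
  desc <- global_descriptors(gas$I_eV, gas$A_eV, compound_id = gas$compound_id)
  wide <- merge(desc, dam_points(desc)[, c("compound_id", "Rd", "Ra")],
                by = "compound_id")
  out <- correlate_descriptors(wide, panel$ic50)
  expect_true(all(c("I_eV", "A_eV", "Rd", "Ra") %in% out$summary$descriptor))
  expect_true(all(abs(out$summary$r) <= 1))
  expect_equal(out$results$I_eV$n, 5L)
})

test_that("assay tables read from both absorbance and inhibition forms", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,concentration_ppm,absorbance_sample,absorbance_control",
               "a,50,0.4,0.8", "a,100,0.2,0.8", "a,200,0.1,0.8"), f)
  curves <- read_assay_table(f)
  expect_equal(curves$a$inhibition_pct, c(50, 75, 87.5))
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,concentration_ppm,inhibition_pct",
               "b,10,20", "b,20,50", "b,40,80"), f2)
  expect_equal(fit_ic50(read_assay_table(f2)$b)$ic50, 20)
})
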