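# Shared fixtures: the published reference values used across tests.
# All tables are rebuilt in code; nothing binary is stored.

round2 <- function(x) round(x, 2)

# Printed gas-phase descriptor table (values as published, 2 dp).
printed_gas <- function() {
  data.frame(
    compound_id = c("lupinifolin", "citflavanone", "lonchocarpol_A",
                    "quercetin", "ascorbic_acid"),
    I_eV = c(7.15, 7.24, 7.24, 8.03, 9.74),
    A_eV = c(0.07, -0.00, -0.10, 2.99, 3.06),
    eta_eV = c(3.53, 3.62, 3.67, 2.51, 3.34),
    S = c(104.62, 102.14, 100.70, 147.01, 110.83),
    chi_eV = c(3.61, 3.61, 3.57, 5.51, 6.40),
    mu_eV = c(-3.61, -3.61, -3.57, -5.51, -6.40),
    omega_eV = c(0.24, 0.24, 0.23, 0.55, 0.75),
    stringsAsFactors = FALSE)
}

# Printed charge-transfer table (2 dp).
printed_dam <- function() {
  data.frame(
    compound_id = c("lupinifolin", "citflavanone", "lonchocarpol_A",
                    "quercetin", "ascorbic_acid"),
    omega_minus_eV = c(4.09, 4.06, 3.97, 9.10, 9.75),
    omega_plus_eV = c(0.48, 0.45, 0.40, 3.59, 3.35),
    Rd = c(1.18, 1.17, 1.14, 2.62, 2.81),
    Ra = c(0.14, 0.13, 0.12, 1.05, 0.98),
    stringsAsFactors = FALSE)
}

# Write a temporary ia_values table for the gas-phase panel.
write_gas_ia_csv <- function(path = tempfile(fileext = ".csv")) {
  ia <- flavanone_panel()$ia
  gas <- ia[ia$phase == "gas", ]
  writeLines(c("compound_id,phase,I_eV,A_eV",
               sprintf("%s,%s,%g,%g", gas$compound_id, gas$phase,
                       gas$I_eV, gas$A_eV)), path)
  path
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected), 1e-300)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / pmax(abs(expected), 1e-300)),
                              rel_tol))
}
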