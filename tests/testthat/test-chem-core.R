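# Formula parsing, monoisotopic masses, adduct arithmetic and the
# descriptor panel.

# independent isotope-mass literals (CODATA/AME), typed here so the adduct
# table is checked against a source other than the package's own table
ORACLE_MASS <- c(H = 1.007825032, C = 12.0, N = 14.003074, O = 15.994915,
                 Na = 22.98976928, K = 38.96370649, Cl = 34.96885268)
ORACLE_E <- 0.00054858

test_that("monoisotopic masses match the isotope-mass oracle", {
  expect_equal(monoisotopic_mass("H2O"),
               2 * ORACLE_MASS[["H"]] + ORACLE_MASS[["O"]],
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C6H12O6"), 180.063388, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  # additivity over concatenated formulas
  pairs <- list(c("C6H12O6", "H2O"), c("C5H5N5", "C2H6O"),
                c("NaCl", "C3H7NO2"))
  for (p in pairs) {
    expect_equal(monoisotopic_mass(p[1]) + monoisotopic_mass(p[2]),
                 monoisotopic_mass(paste0(p[1], p[2])),
                 tolerance = 1e-6)
  }
})

test_that("malformed formulas raise formula errors", {
  expect_error(monoisotopic_mass(""), "formula error")
  expect_error(monoisotopic_mass("C6H12O6+"), "formula error")
  expect_error(monoisotopic_mass("(CH3)2CO"), "formula error")
  expect_error(monoisotopic_mass("Xx2O"), "formula error")
  expect_error(monoisotopic_mass("C0H2"), "formula error")
})

test_that("adduct mass shifts equal brute-force isotope sums", {
  tab <- adduct_table()
  shift_of <- function(label) tab$mass_shift[tab$label == label]
  expect_equal(shift_of("[M+H]+"), ORACLE_MASS[["H"]] - ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+Na]+"), ORACLE_MASS[["Na"]] - ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+K]+"), ORACLE_MASS[["K"]] - ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+NH4]+"),
               ORACLE_MASS[["N"]] + 4 * ORACLE_MASS[["H"]] - ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M-H]-"), -(ORACLE_MASS[["H"]] - ORACLE_E),
               tolerance = 1e-6)
  expect_equal(shift_of("[M+Cl]-"), ORACLE_MASS[["Cl"]] + ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+HCOO]-"),
               ORACLE_MASS[["C"]] + ORACLE_MASS[["H"]] +
                 2 * ORACLE_MASS[["O"]] + ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+CH3COO]-"),
               2 * ORACLE_MASS[["C"]] + 3 * ORACLE_MASS[["H"]] +
                 2 * ORACLE_MASS[["O"]] + ORACLE_E,
               tolerance = 1e-6)
  expect_equal(shift_of("[M+Na-2H]-"),
               ORACLE_MASS[["Na"]] - 2 * ORACLE_MASS[["H"]] + ORACLE_E,
               tolerance = 1e-6)
})

test_that("adduct m/z arithmetic reproduces reference ions", {
  # protonated leucine enkephalin, the ESI lock-mass standard
  expect_equal(round(adduct_mz(monoisotopic_mass("C28H37N5O7"), "[M+H]+"), 4),
               556.2766)
  # electron-loss radical cation
  M <- 321.45
  expect_equal(adduct_mz(M, "[M]+"), M - 0.000549, tolerance = 1e-6)
  # sodiated glucose
  expect_equal(round(adduct_mz(180.063388, "[M+Na]+"), 4), 203.0526)
  expect_error(adduct_mz(100, "[M+Xy]+"), "adduct error")
  expect_error(adduct_mz(-5, "[M+H]+"), "> 0")
})

test_that("protonated/deprotonated pair differs by two proton masses", {
  for (M in c(76.1, 180.063388, 555.269, 901.2)) {
    expect_equal(adduct_mz(M, "[M+H]+") - adduct_mz(M, "[M-H]-"),
                 2 * 1.007276, tolerance = 1e-6)
  }
})

test_that("acetate vendor alias maps onto the canonical label", {
  expect_identical(normalize_adduct("[M+CH3OO]-"), "[M+CH3COO]-")
  expect_equal(adduct_mz(100, "[M+CH3OO]-"), adduct_mz(100, "[M+CH3COO]-"))
})

test_that("descriptor computation is complete, flagged, and deterministic", {
  d <- compute_descriptors(c("CCO", "not_a_smiles", "CC.O"))
  expect_identical(attr(d, "parsed"), c(TRUE, FALSE, TRUE))
  # small valid molecule: no missing entries
  expect_equal(sum(is.na(d[1, ])), 0)
  # unparseable: flagged, all-missing row, not dropped
  expect_true(all(is.na(d[2, ])))
  # disconnected structure: distance-based descriptors masked as missing
  expect_true(is.na(d[3, "wiener"]))
  expect_false(is.na(d[3, "logP"]))
  # strict mode raises a structure error instead
  expect_error(compute_descriptors("not_a_smiles", strict = TRUE),
               "structure error")
  # referential transparency
  d2 <- compute_descriptors("CCO")
  expect_identical(unname(d[1, ]), unname(d2[1, ]))
  expect_identical(colnames(d), descriptor_panel())
})
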