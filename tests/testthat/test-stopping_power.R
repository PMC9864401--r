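test_that("NIST-layout parser converts units and validates structure", {
  txt <- c(
    "PSTAR-like: protons in liquid water",
    "Kinetic   Collision Nuclear   Total     CSDA",
    "MeV       MeV cm2/g MeV cm2/g MeV cm2/g g/cm2",
    "  1.0   259.0   1.8   260.8   2.458E-02",
    " 10.0    45.4   0.27   45.67   1.230E+00",
    "100.0     7.22  0.069   7.289  7.718E+00")
  p <- ion_species("1H", 1L, 1L)
  tab <- load_nist_table(txt, p)
  expect_s3_class(tab, "sp_table")
  expect_equal(tab$energy, c(1, 10, 100))
  # MeV cm^2/g -> keV/um in unit-density water: factor 0.1
  expect_equal(tab$stopping, c(26.08, 4.567, 0.7289))
  # collision column option
  tab_el <- load_nist_table(txt, p, column = "collision")
  expect_equal(tab_el$stopping, c(25.90, 4.54, 0.722))
  # energies in MeV are divided by A
  he <- ion_species("4He", 2L, 4L)
  tab_he <- load_nist_table(txt, he, energy_unit = "MeV")
  expect_equal(tab_he$energy, c(0.25, 2.5, 25))

  expect_error(load_nist_table(c("header", "1.0 2.0", "oops 3.0"), p),
               "malformed numeric row at line 3")
  expect_error(load_nist_table(c("only header", "lines here"), p),
               "no numeric rows")
  expect_error(load_nist_table(c("h", "10 45.67", "1 260.8"), p),
               "not strictly ascending")
})

test_that("fixture tables round-trip bit-exactly through write/read", {
  path <- system.file("extdata", "stopping_power_1H_synthetic.csv",
                      package = "sobpr")
  tab <- read_sp_table(path)
  expect_gte(length(tab$energy), 20)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_sp_table(tab, tmp)
  tab2 <- read_sp_table(tmp)
  expect_identical(tab$energy, tab2$energy)
  expect_identical(tab$stopping, tab2$stopping)
  expect_identical(tab$species$Z, tab2$species$Z)
})

test_that("log-log interpolation is exact at nodes, geometric between them", {
  s <- ion_species("1H", 1L, 1L)
  tab <- sp_table(s, c(1, 100), c(30, 3))
  expect_equal(sp_interp(tab, 1), 30, tolerance = 1e-12)
  expect_equal(sp_interp(tab, 100), 3, tolerance = 1e-12)
  # at the geometric mean of the energies the value is the geometric mean
  expect_equal(sp_interp(tab, 10), sqrt(30 * 3), tolerance = 1e-12)
  # no silent extrapolation
  expect_error(sp_interp(tab, 0.5), "outside table range")
  expect_error(sp_interp(tab, 101), "outside table range")
})

test_that("interpolated stopping power is continuous and positive at nodes", {
  prov <- test_provider()
  for (s in beam_species()) {
    tab <- prov$tables[[sprintf("Z%d_A%d", s$Z, s$A)]]
    for (e in tab$energy[c(-1, -length(tab$energy))]) {
      left <- sp_interp(tab, e * (1 - 1e-10))
      right <- sp_interp(tab, e * (1 + 1e-10))
      expect_gt(left, 0)
      expect_lt(abs(left - right) / right, 1e-8)
    }
  }
})

test_that("stopping power decreases with energy above 1 MeV/n (Bethe regime)", {
  prov <- test_provider()
  for (s in beam_species()) {
    tab <- prov$tables[[sprintf("Z%d_A%d", s$Z, s$A)]]
    keep <- tab$energy >= 1
    expect_true(all(diff(tab$stopping[keep]) < 0), label = s$symbol)
  }
})

test_that("heavier ions stop harder at fixed energy per nucleon", {
  prov <- test_provider()
  e <- c(1, 10, 100)
  expect_true(all(stopping_power(prov, beam_species()$`12C`, e) >
                  stopping_power(prov, beam_species()$`1H`, e)))
})

test_that("effective-charge scaling has the right limits", {
  prov <- test_provider()
  proton <- prov$proton
  p <- ion_species("1H", 1L, 1L)
  # Z = 1: identity within 0.1% once the proton is fully stripped
  e <- exp(seq(log(2), log(500), length.out = 30))
  ratio <- effective_charge_stopping(p, e, proton) / sp_interp(proton, e)
  expect_true(all(abs(ratio - 1) < 1e-3))
  # at 1 MeV the Barkas factor itself deviates by ~0.6%
  expect_equal(effective_charge_stopping(p, 1, proton) / sp_interp(proton, 1),
               1, tolerance = 1e-2)
  # high-velocity carbon: S_C / S_p -> Z^2 = 36
  C <- beam_species()$`12C`
  expect_equal(effective_charge_stopping(C, 900, proton) /
                 sp_interp(proton, 900), 36, tolerance = 0.02 * 36)
  # 7Li at 50 MeV/n against an independent evaluation of the formula
  Li <- beam_species()$`7Li`
  gamma <- 1 + 50 / 931.494
  beta <- sqrt(1 - gamma^-2)
  zeff <- 3 * (1 - exp(-125 * beta * 3^(-2 / 3)))
  expect_equal(effective_charge_stopping(Li, 50, proton),
               sp_interp(proton, 50) * zeff^2, tolerance = 1e-12)
})

test_that("range-energy fit inverts exactly and tracks CSDA ranges", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  fit <- fit_range_energy(prov, p)
  expect_gt(fit$alpha, 0)
  expect_gt(fit$p, 1)
  expect_lt(fit$p, 2)
  # round-trip identity
  expect_lt(abs(150 - energy_from_range(fit, range_from_energy(fit, 150))) / 150,
            1e-10)
  # monotonicity on random pairs
  set.seed(7)
  e1 <- runif(100, 1, 400); e2 <- e1 + runif(100, 0.1, 100)
  expect_true(all(range_from_energy(fit, e2) > range_from_energy(fit, e1)))
  # the power law reproduces the integrated CSDA ranges within 2% (50-200 MeV)
  e <- seq(50, 200, by = 10)
  rel <- abs(range_from_energy(fit, e) / csda_range(prov, p, e) - 1)
  expect_lt(max(rel), 0.02)
  expect_error(range_from_energy(fit, -1), "positive")
  expect_error(energy_from_range(fit, 0), "positive")
})

test_that("table constructors reject malformed input", {
  s <- ion_species("1H", 1L, 1L)
  expect_error(sp_table(s, numeric(0), numeric(0)), "empty")
  expect_error(sp_table(s, c(1, 1), c(2, 2)), "ascending")
  expect_error(sp_table(s, c(1, 2), c(2, -1)), "positive")
  expect_error(ion_species("x", 0, 1))
  expect_error(ion_species("x", 2, 1), "A must be")
})
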