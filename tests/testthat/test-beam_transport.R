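test_that("depth grid uses half-open 1-mm bins with centered depths", {
  g <- depth_grid()
  expect_equal(g$n_bins, 200L)
  expect_equal(g$depths[1], 0.5)
  expect_equal(g$depths[200], 199.5)
  expect_error(depth_grid(0, 10))
})

test_that("pristine peak approaches dose ~ S(E(z)) in the zero-straggling limit", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  fit <- fit_range_energy(prov, p)
  E0 <- energy_from_range(fit, 120)
  pk <- pristine_peak(p, E0, depth_grid(), prov, straggling_fraction = 1e-3)
  z <- pk$grid$depths
  inside <- z < 110
  expected <- stopping_power(prov, p, energy_from_range(fit, 120 - z[inside]))
  ratio <- pk$dose[inside] / expected
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-3)
  # the peak sits in the final bins before the range, dose vanishes beyond
  expect_gt(which.max(pk$dose), 115)
  expect_lt(max(pk$dose[z > 122]), 1e-12 * max(pk$dose))
})

test_that("peak position matches the module's own range fit within one bin", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  fit <- fit_range_energy(prov, p)
  pk <- pristine_peak(p, energy_from_range(fit, 100), depth_grid(), prov)
  expect_lte(abs(which.max(pk$dose) - 100), 1.5)
})

test_that("dose is linear in the incident fluence", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  pk1 <- pristine_peak(p, 100, depth_grid(), prov, fluence0 = 1)
  pk2 <- pristine_peak(p, 100, depth_grid(), prov, fluence0 = 2)
  expect_equal(pk2$dose, 2 * pk1$dose, tolerance = 1e-12)
  expect_equal(pk2$fluence$phi, 2 * pk1$fluence$phi, tolerance = 1e-12)
})

test_that("pristine peak validates its inputs", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  expect_error(pristine_peak(p, 300, depth_grid(), prov), "exceeds phantom")
  expect_error(pristine_peak(p, 100, depth_grid(), prov,
                             straggling_fraction = 0.2), "straggling_fraction")
})

test_that("ripple filter is an identity at sigma 0 and conserves dose", {
  prov <- test_provider()
  p <- beam_species()$`1H`
  pk <- pristine_peak(p, 100, depth_grid(), prov)
  expect_identical(apply_ripple_filter(pk, 0), pk)
  sm <- apply_ripple_filter(pk, 2)
  expect_equal(sum(sm$dose), sum(pk$dose), tolerance = 1e-6)
  expect_equal(sum(sm$fluence$phi), sum(pk$fluence$phi), tolerance = 1e-6)
  # FWHM strictly increases under smearing
  fwhm <- function(d) sum(d >= max(d) / 2)
  expect_gt(fwhm(sm$dose), fwhm(pk$dose))
})

test_that("fragment spectra follow the attenuation losses", {
  prov <- test_provider()
  C <- beam_species()$`12C`
  fit <- fit_range_energy(prov, C)
  E0 <- energy_from_range(fit, 120)
  cfg <- default_fragmentation(C)
  pk <- pristine_peak(C, E0, depth_grid(), prov, lambda = cfg$lambda)

  # all-zero production fractions: an empty tail
  cfg0 <- cfg
  for (i in seq_along(cfg0$channels)) cfg0$channels[[i]]$fraction <- 0
  fr0 <- fragment_spectra(pk, cfg0, prov)
  expect_equal(sum(fr0$phi), 0)

  fr <- fragment_spectra(pk, cfg, prov)
  pk_full <- add_fragments(pk, fr, prov)
  z <- pk$grid$depths
  # carbon deposits dose beyond its range through lighter fragments
  expect_gt(sum(pk_full$dose[z > 130 & z < 160]), 0)
  # a proton beam has no charged-fragment tail
  p <- beam_species()$`1H`
  pkp <- pristine_peak(p, energy_from_range(fit_range_energy(prov, p), 120),
                       depth_grid(), prov)
  expect_lt(max(pkp$dose[z > 130]), 1e-12 * max(pkp$dose))

  # tail fluence is linear in the production fractions
  cfg2 <- cfg
  for (i in seq_along(cfg2$channels))
    cfg2$channels[[i]]$fraction <- 2 * cfg2$channels[[i]]$fraction
  fr2 <- fragment_spectra(pk, cfg2, prov)
  expect_equal(fr2$phi, 2 * fr$phi, tolerance = 1e-9)

  # fragment charge must be below the primary's
  bad <- cfg
  bad$channels[[1]]$species <- ion_species("12C", 6L, 12L)
  expect_error(fragment_spectra(pk, bad, prov), "Z >= primary")

  # fragment dose at the entrance bin stays below 5% of the total
  expect_lt(sum(dose_from_fluence(fr, prov)[1, , ]) / pk_full$dose[1], 0.05)
})

test_that("energy-integrated primary fluence never grows with depth", {
  prov <- test_provider()
  for (sym in c("1H", "12C")) {
    s <- beam_species()[[sym]]
    cfg <- default_fragmentation(s)
    pk <- pristine_peak(s, 100, depth_grid(), prov, lambda = cfg$lambda)
    tot <- rowSums(pk$fluence$phi[, , 1])
    expect_true(all(diff(tot) <= 1e-12), label = sym)
  }
})

test_that("build_library tiles the target with shared grid and binning", {
  lib <- test_library("1H")
  expect_gte(length(lib$peaks), 25)
  expect_gte(max(lib$ranges), 130)
  expect_lte(min(lib$ranges), 80)
  expect_true(all(diff(lib$ranges) <= 2 + 1e-9))
  for (pk in lib$peaks) {
    expect_identical(pk$grid, lib$grid)
    expect_identical(pk$fluence$energy_edges, lib$energy_edges)
  }
  expect_error(build_library(beam_species()$`1H`, 80, 130,
                             energy_spacing = 50), "too coarse")
})

test_that("mixed field is the weighted sum of its peaks", {
  lib <- test_library("1H")
  n <- length(lib$peaks)
  w1 <- rep(0, n); w1[10] <- 1
  f1 <- mixed_field(w1, lib)
  expect_equal(f1$dose$values, lib$peaks[[10]]$dose, tolerance = 1e-12)

  set.seed(11)
  wa <- runif(n); wb <- runif(n)
  fa <- mixed_field(wa, lib); fb <- mixed_field(wb, lib)
  fab <- mixed_field(2 * wa + 3 * wb, lib)
  expect_equal(fab$dose$values, 2 * fa$dose$values + 3 * fb$dose$values,
               tolerance = 1e-9)
  expect_equal(fab$fluence$phi, 2 * fa$fluence$phi + 3 * fb$fluence$phi,
               tolerance = 1e-9)

  # two equal-weight beams equal the hand-summed curves
  w2 <- rep(0, n); w2[c(3, 7)] <- 1
  f2 <- mixed_field(w2, lib)
  expect_identical(f2$dose$values,
                   lib$peaks[[3]]$dose + lib$peaks[[7]]$dose)

  expect_error(mixed_field(rep(-1, n), lib), "non-negative")
  expect_error(mixed_field(rep(1, n - 1), lib), "weight count")
})

test_that("ripple-filtered library peaks conserve the unfiltered dose", {
  prov <- test_provider()
  C <- beam_species()$`12C`
  cfg <- default_fragmentation(C)
  pk <- pristine_peak(C, 200, depth_grid(), prov, lambda = cfg$lambda)
  pk <- add_fragments(pk, fragment_spectra(pk, cfg, prov), prov)
  sm <- apply_ripple_filter(pk, 1.4)
  expect_equal(sum(sm$dose), sum(pk$dose), tolerance = 1e-6)
})

test_that("peak-to-entrance ratio decreases with atomic number at equal range", {
  prov <- test_provider()
  ratios <- vapply(beam_species(), function(s) {
    fit <- fit_range_energy(prov, s)
    cfg <- default_fragmentation(s)
    pk <- pristine_peak(s, energy_from_range(fit, 130), depth_grid(), prov,
                        lambda = cfg$lambda)
    if (length(cfg$channels))
      pk <- add_fragments(pk, fragment_spectra(pk, cfg, prov), prov)
    pk <- apply_ripple_filter(pk, default_ripple_sigma(s, 130))
    max(pk$dose) / mean(pk$dose[1:5])
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
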