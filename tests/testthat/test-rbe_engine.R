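test_that("yield tables interpolate exactly at nodes and order by charge", {
  m <- test_yields()
  p <- beam_species()$`1H`; C <- beam_species()$`12C`
  tp <- m$tables[["Z1_A1"]]
  k <- 5
  expect_equal(dsb_yield(m, p, tp$energy[k]), tp$yield[k], tolerance = 1e-12)
  # at the highest tabulated proton energy the field is photon-like
  top <- dsb_yield(m, p, max(tp$energy)) / m$reference_yield
  expect_gte(top, 0.95)
  expect_lte(top, 1.10)
  # LET ordering at 10 MeV/n
  expect_gt(dsb_yield(m, C, 10), dsb_yield(m, p, 10))
  # out-of-validity energies are an error
  expect_error(dsb_yield(m, p, 1e-3), "outside table range")
  # species without a table are a hard error, never silently skipped
  expect_error(dsb_yield(m, ion_species("56Fe", 26L, 56L), 10),
               "no DSB-yield table")
})

test_that("the bundled yield fixture is a snapshot of the synthetic surrogate", {
  bundled <- test_yields()
  generated <- synthetic_yield_model()
  expect_setequal(names(bundled$tables), names(generated$tables))
  for (k in names(bundled$tables))
    expect_equal(bundled$tables[[k]]$yield, generated$tables[[k]]$yield,
                 tolerance = 1e-8)
})

test_that("per-species RBE is the dose-weighted yield over the reference", {
  ref <- CO60_REFERENCE_YIELD
  expect_identical(species_rbe(c(1, 1), c(ref, ref)), 1)
  expect_equal(species_rbe(1, 2 * ref), 2)
  # doses (1, 3), yields (ref, 2 ref): (1 + 3*2)/4 = 1.75
  expect_equal(species_rbe(c(1, 3), c(ref, 2 * ref)), 1.75)
  # scale invariance in dose
  expect_equal(species_rbe(c(10, 30), c(ref, 2 * ref)), 1.75)
  expect_true(is.na(species_rbe(c(0, 0), c(ref, ref))))
})

test_that("total RBE is the dose-weighted convex combination", {
  expect_equal(total_rbe(5, 1.3), 1.3)
  expect_equal(total_rbe(c(1, 1), c(1, 2)), 1.5)
  set.seed(21)
  d <- runif(4); r <- runif(4, 1, 3)
  # independent loop oracle
  num <- 0; den <- 0
  for (i in 1:4) { num <- num + d[i] * r[i]; den <- den + d[i] }
  expect_equal(total_rbe(d, r), num / den, tolerance = 1e-12)
  expect_true(is.na(total_rbe(c(0, 0), c(NA, NA))))
  expect_error(total_rbe(c(1, 1), c(1, NA)), "undefined")
})

test_that("a uniform-yield model collapses every RBE to exactly 1", {
  prov <- test_provider()
  uni <- uniform_yield_model()
  pk <- pristine_peak(beam_species()$`1H`, 100, depth_grid(), prov)
  prof <- rbe_profile(pk$fluence, uni, prov)
  vals <- prof$total$values
  expect_true(all(abs(vals[!is.na(vals)] - 1) < 1e-12))
})

test_that("total RBE lies between the per-species extremes at every depth", {
  prov <- test_provider()
  m <- test_yields()
  field <- test_field("12C")
  prof <- rbe_profile(field$fluence, m, prov)
  for (d in which(!is.na(prof$total$values))) {
    rs <- prof$per_species_rbe[d, prof$per_species_dose[d, ] > 0]
    expect_gte(prof$total$values[d], min(rs) - 1e-9)
    expect_lte(prof$total$values[d], max(rs) + 1e-9)
  }
})

test_that("RBE is invariant under uniform rescaling of the fluence", {
  prov <- test_provider()
  m <- test_yields()
  pk <- pristine_peak(beam_species()$`4He`, 80, depth_grid(), prov)
  a <- rbe_profile(pk$fluence, m, prov)$total$values
  scaled <- pk$fluence; scaled$phi <- 13 * scaled$phi
  b <- rbe_profile(scaled, m, prov)$total$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("mono-component RBE grows toward the Bragg peak", {
  prov <- test_provider()
  m <- test_yields()
  p <- beam_species()$`1H`
  pk <- pristine_peak(p, 100, depth_grid(), prov)
  prof <- rbe_profile(pk$fluence, m, prov)
  vals <- prof$total$values
  peak_bin <- which.max(pk$dose)
  expect_true(all(diff(vals[1:peak_bin]) > -1e-6))
  expect_gt(vals[peak_bin], vals[1])
})

test_that("carbon reaches higher RBE than protons over the same SOBP", {
  reg <- function(prof) {
    z <- prof$grid$depths
    max(prof$total$values[z > 80 & z < 131], na.rm = TRUE)
  }
  prov <- test_provider(); m <- test_yields()
  rc <- rbe_profile(test_field("12C")$fluence, m, prov)
  rp <- rbe_profile(test_field("1H")$fluence, m, prov)
  expect_gt(reg(rc), reg(rp))
})

test_that("yield-model constructor enforces physical invariants", {
  t1 <- data.frame(energy = c(1, 10), yield = c(9, 8.5))
  attr(t1, "species") <- ion_species("1H", 1L, 1L)
  expect_s3_class(dsb_yield_model(list(Z1_A1 = t1)), "dsb_yield_model")
  t2 <- data.frame(energy = c(10, 1), yield = c(9, 9))
  attr(t2, "species") <- ion_species("1H", 1L, 1L)
  expect_error(dsb_yield_model(list(Z1_A1 = t2)), "ascend")
  t3 <- data.frame(energy = c(1, 10), yield = c(9, 2))
  attr(t3, "species") <- ion_species("1H", 1L, 1L)
  expect_error(dsb_yield_model(list(Z1_A1 = t3)), "not physical")
})
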