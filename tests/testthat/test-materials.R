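test_that("stopping power and CSDA range agree with the brute-force oracle over 5-70 MeV", {
  mats <- default_materials()
  for (nm in c("water", "aluminum", "tungsten", "kapton", "air")) {
    m <- mats[[nm]]
    for (e in seq(5, 70, by = 5)) {
      expect_lt(abs(mass_stopping_power(m, e) /
                      oracle_stopping(m$z_over_a, m$i_value, e) - 1),
                0.005, label = sprintf("S(%s, %g MeV)", nm, e))
      expect_lt(abs(csda_range(m, e) /
                      oracle_range(m$z_over_a, m$i_value, e) - 1),
                0.005, label = sprintf("R(%s, %g MeV)", nm, e))
    }
  }
})

test_that("water at 68 MeV: stopping power within 2% of the oracle, heavier than tungsten", {
  mats <- default_materials()
  s_w <- mass_stopping_power(mats$water, 68)
  expect_lt(abs(s_w / oracle_stopping(mats$water$z_over_a, 78, 68) - 1), 0.02)
  expect_gt(s_w, mass_stopping_power(mats$tungsten, 68))
})

test_that("stopping power decreases and range increases with the I-value", {
  mats <- default_materials()
  for (nm in c("water", "aluminum", "lung", "bone")) {
    lo <- mats[[nm]]; lo$i_value <- lo$i_value * 0.94
    hi <- mats[[nm]]; hi$i_value <- hi$i_value * 1.06
    for (e in c(5, 20, 68)) {
      expect_gt(mass_stopping_power(lo, e), mass_stopping_power(hi, e))
      expect_lt(csda_range(lo, e), csda_range(hi, e))
    }
  }
})

test_that("CSDA range is strictly increasing in energy", {
  w <- default_materials()$water
  e <- seq(2, 240, length.out = 80)
  expect_true(all(diff(csda_range(w, e)) > 0))
})

test_that("range at the cutoff energy is the residual alone", {
  w <- default_materials()$water
  expect_lte(csda_range(w, 1), 0.01)
  expect_equal(csda_range(w, 1), 0.0025, tolerance = 1e-6)
})

test_that("energy window violations raise a domain error naming the window", {
  w <- default_materials()$water
  expect_error(mass_stopping_power(w, 0.5), "\\[1, 250\\] MeV")
  expect_error(csda_range(w, 300), "\\[1, 250\\] MeV")
})

test_that("slab traversal is range-additive and handles edge cases", {
  mats <- default_materials()
  for (nm in c("water", "aluminum", "kapton")) {
    m <- mats[[nm]]
    t_tot <- 0.8
    e_once <- energy_after_slab(m, 68, t_tot)
    e_split <- energy_after_slab(m, energy_after_slab(m, 68, t_tot / 2),
                                 t_tot / 2)
    expect_lt(abs(e_once - e_split), 1e-6)
    expect_lt(e_once, 68)
  }
  expect_identical(energy_after_slab(mats$water, 68, 0), 68)
  expect_error(energy_after_slab(mats$water, 10, 5), "stops in slab")
})

test_that("Kapton window energy loss matches the first-order S*t estimate", {
  kap <- default_materials()$kapton
  t_gcm2 <- 5.00e-3 * 1.42
  loss <- 68 - energy_after_slab(kap, 68, t_gcm2)
  est <- mass_stopping_power(kap, 68) * t_gcm2
  expect_gt(loss, 0.05 * 0.8)        # order 0.05-0.1 MeV
  expect_lt(loss, 0.1 * 1.2)
  expect_lt(abs(loss / est - 1), 0.2)
})

test_that("Bragg additivity reproduces elemental values and log-weighted mixes", {
  expect_equal(bragg_additivity_i(data.frame(element = "Al", fraction = 1)),
               166.0)
  expect_equal(bragg_additivity_i(data.frame(element = "W", fraction = 1)),
               727.0)
  # 50/50 C/O mix: Z/A nearly equal, so the electron-weighted log mean is
  # close to the geometric mean of 78 and 95 eV (frozen oracle value)
  mix <- bragg_additivity_i(data.frame(element = c("C", "O"),
                                       fraction = c(0.5, 0.5)))
  expect_equal(mix, 86.10, tolerance = 1e-3)
  expect_lt(abs(mix - sqrt(78 * 95)), 0.1)
  expect_error(bragg_additivity_i(data.frame(element = "Xx", fraction = 1)),
               "unknown element")
  expect_error(bragg_additivity_i(data.frame(element = "O", fraction = 0.9)),
               "sum to 1")
})

test_that("water range shift for the ICRU I-value band is a fraction of a millimetre", {
  w76 <- default_materials()$water; w76$i_value <- 76
  w80 <- default_materials()$water; w80$i_value <- 80
  swing_mm <- 10 * (csda_range(w80, 68) - csda_range(w76, 68))
  expect_gt(swing_mm, 0.2)           # full 76 -> 80 eV swing
  expect_lt(swing_mm, 0.4)
  per_side <- swing_mm / 2           # 78 +/- 2 eV, ~0.15 mm per side
  expect_gt(per_side, 0.1)
  expect_lt(per_side, 0.3)
})

test_that("material constructor enforces its invariants", {
  expect_error(material("x", data.frame(element = "O", fraction = 1), -1),
               "density")
  expect_error(material("x", data.frame(element = "O", fraction = 1), 1,
                        i_value = -5), "i_value")
  expect_error(material("x", data.frame(element = "O", fraction = 1), 1,
                        i_value = 95, i_uncertainty = -1), "i_uncertainty")
  expect_error(material("x", data.frame(element = "O", fraction = 0.5), 1),
               "sum to 1")
})
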