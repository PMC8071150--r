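state0 <- transport_beam(beam_source(), build_beamline(FALSE))

test_that("water Bragg curve is non-negative with a unique distal global maximum", {
  p <- water_depth_dose(FALSE)
  expect_true(all(p$dose >= 0))
  expect_gt(max(p$dose), 0)
  i <- which.max(p$dose)
  expect_equal(sum(p$dose == max(p$dose)), 1L)
  expect_gt(p$depth_mm[i], 30)                 # the Bragg peak, not the plateau
  expect_gt(max(p$dose) / p$dose[1], 2)        # clear peak-to-plateau contrast
  expect_equal(diff(p$depth_mm)[1], 0.2)
  expect_true(all(abs(diff(p$depth_mm) - 0.2) < 1e-9))
})

test_that("entrance dose ratios equal stopping-power ratios when fluence and nuclear terms are off", {
  w <- default_materials()$water
  p <- bragg_curve(state0, water_medium(40), fluence_params = flat_fluence,
                   nuclear_mfp_cm = 1e12)
  r0 <- 10 * csda_range(w, state0$mean_energy)
  z1 <- 5.1; z2 <- 15.1
  d_ratio <- p$dose[p$depth_mm == z1] / p$dose[p$depth_mm == z2]
  e1 <- protonuq:::energy_at_range(w, (r0 - z1) / 10)
  e2 <- protonuq:::energy_at_range(w, (r0 - z2) / 10)
  s_ratio <- mass_stopping_power(w, e1) / mass_stopping_power(w, e2)
  expect_equal(d_ratio, s_ratio, tolerance = 0.01)
})

test_that("scaling the medium density by k scales geometric R80 by 1/k", {
  p1 <- bragg_curve(state0, water_medium(40))
  w <- default_materials()$water
  p2 <- bragg_curve(state0, layered_medium(list(w), 1.25, 36))
  expect_equal(range_r80(p2) * 1.25, range_r80(p1), tolerance = 0.005)
})

test_that("peak position moves deeper when upstream areal density is removed", {
  p_with <- water_depth_dose(TRUE)
  p_without <- water_depth_dose(FALSE)
  expect_gt(peak_position(p_without), peak_position(p_with))
  # removing the window too (thinner by 5%) pushes the peak deeper again
  p_thin <- water_depth_dose(beamline = perturb_stack(
    build_beamline(FALSE), "kapton_window", thickness_scale = 0.95))
  expect_gte(range_r80(p_thin), range_r80(p_without))
})

test_that("zero energy spread returns the monoenergetic curve bit-identically", {
  direct <- water_depth_dose(FALSE, sigma_e = 0)
  viaconv <- convolve_energy_spread(function(e) {
    st <- transport_beam(beam_source(e), build_beamline(FALSE))
    bragg_curve(st, water_medium(40))
  }, 68, sigma_e = 0)
  expect_identical(direct$dose, viaconv$dose)
  expect_error(convolve_energy_spread(identity, 68, 1, n_components = 4))
})

test_that("energy spread broadens the peak and lowers the peak-to-plateau ratio", {
  p0 <- water_depth_dose(FALSE)
  p1 <- water_depth_dose(FALSE, sigma_e = 0.68)
  p2 <- water_depth_dose(FALSE, sigma_e = 1.00)
  ratio <- function(p) max(p$dose) / p$dose[1]
  expect_lt(ratio(p1), ratio(p0))
  expect_lt(ratio(p2), ratio(p1))
  width80 <- function(p) {
    above <- p$depth_mm[p$dose >= 0.8 * max(p$dose)]
    max(above) - min(above)
  }
  expect_gt(width80(p2), width80(p0))
})

test_that("doubling the quadrature nodes leaves the metrics essentially unchanged", {
  reg <- default_regions()$biological_sample
  m9 <- profile_metrics(water_depth_dose(FALSE, sigma_e = 1,
                                         n_components = 9), reg)
  m17 <- profile_metrics(water_depth_dose(FALSE, sigma_e = 1,
                                          n_components = 17), reg)
  expect_lt(abs(m17$r80_mm - m9$r80_mm) / m9$r80_mm, 0.001)
  expect_lt(abs(m17$plateau_dose / m9$plateau_dose - 1), 0.001)
  expect_lt(abs(m17$hi98 - m9$hi98), 0.001)
})

test_that("plateau metrics are insensitive to the nuclear-removal constant", {
  reg <- default_regions()$biological_sample
  m1 <- profile_metrics(water_depth_dose(FALSE), reg)
  for (mfp in c(66.7, 200)) {                  # +-50% of the 1%/cm removal rate
    m <- profile_metrics(water_depth_dose(FALSE, nuclear_mfp_cm = mfp), reg)
    expect_lt(abs(m$r80_mm - m1$r80_mm), 0.05)
    expect_lt(abs(m$hi98 - m1$hi98), 0.02)
  }
})

test_that("an all-water phantom column reproduces the water-tank curve", {
  wph <- make_water_cylinder()
  pw <- phantom_depth_dose(state0, wph, backing_water_mm = 0)
  pt <- bragg_curve(state0, water_medium(40))
  expect_lt(max(abs(pw$dose - pt$dose)) / max(pt$dose), 1e-9)
})

test_that("a lung insert pushes R80 deeper than a same-length soft column", {
  w <- default_materials()$water
  lu <- default_materials()$lung
  soft <- layered_medium(list(w, w, w), c(1, 1, 1), c(5, 10, 35))
  lungcol <- layered_medium(list(w, lu, w), c(1, 0.26, 1), c(5, 10, 35))
  expect_gt(range_r80(bragg_curve(state0, lungcol)),
            range_r80(bragg_curve(state0, soft)))
})

test_that("degenerate media are rejected", {
  expect_error(layered_medium(list(default_materials()$water), 1, 0))
  expect_error(bragg_curve(state0,
                           structure(list(materials = list(),
                                          density = numeric(0),
                                          thickness_mm = numeric(0),
                                          provenance = "water"),
                                     class = "layered_medium")),
               "zero-length")
})
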