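test_that("water cylinder: HU 0 everywhere, 40 mm long, converts to unit-density water", {
  ph <- make_water_cylinder()
  expect_true(all(ph$hu == 0))
  expect_equal(dim(ph$hu)[1] * ph$spacing_mm, 40)
  expect_equal(ph$spacing_mm, 0.2)
  conv <- hu_to_material(ph$hu)
  expect_true(all(conv$material == "water"))
  expect_true(all(conv$density == 1.000))
})

test_that("mouse phantoms are deterministic under seed and anatomically plausible", {
  for (rg in c("brain", "lungs", "intestine")) {
    a <- make_mouse_phantom(rg, seed = 7)
    b <- make_mouse_phantom(rg, seed = 7)
    expect_identical(a$hu, b$hu)
    # body thickness along the lateral beam axis within the mouse range
    col <- protonuq:::phantom_column(a, "lateral")
    body <- which(col > -900)
    thickness <- (max(body) - min(body) + 1) * 0.2
    expect_gte(thickness, 15)
    expect_lte(thickness, 27)
    expect_true(all(a$hu >= -1000 & a$hu <= 3000))
  }
  c1 <- make_mouse_phantom("intestine", seed = 1)
  c2 <- make_mouse_phantom("intestine", seed = 2)
  expect_false(identical(c1$hu, c2$hu))   # gas pockets move with the seed
})

test_that("lungs contain sub--300 HU voxels in the beam path, the brain column does not", {
  lungs <- protonuq:::phantom_column(make_mouse_phantom("lungs", 1), "lateral")
  brain <- protonuq:::phantom_column(make_mouse_phantom("brain", 1), "lateral")
  body_l <- lungs[lungs > -900]
  body_b <- brain[brain > -900]
  expect_gt(sum(body_l < -300), 0)
  expect_equal(sum(body_b < -300), 0)
})

test_that("HU noise: zero amplitude is the identity, offsets invert within clipping", {
  ph <- make_mouse_phantom("brain", 1)
  expect_identical(add_hu_noise(ph, 0)$hu, ph$hu)
  back <- add_hu_noise(add_hu_noise(ph, 40), -40)
  expect_identical(back$hu, ph$hu)
  vox <- add_hu_noise(ph, 40, mode = "voxelwise", seed = 3)
  expect_true(all(abs(vox$hu - ph$hu) <= 40 + 1e-9))
  expect_true(all(vox$hu >= -1000))
})

test_that("a +40 HU offset raises the mean converted density of soft tissue", {
  ph <- make_mouse_phantom("intestine", 1)
  conv0 <- hu_to_material(ph$hu)
  conv1 <- hu_to_material(add_hu_noise(ph, 40)$hu)
  soft <- conv0$material == "water"
  expect_gt(mean(conv1$density[soft]), mean(conv0$density[soft]))
})

test_that("resampling pools block means, conserves HU mass, and rejects bad ratios", {
  ph <- make_mouse_phantom("lungs", 1)
  for (sp in c(0.4, 0.8)) {
    rs <- resample_phantom(ph, sp)
    k <- sp / 0.2
    expect_equal(dim(rs$hu), dim(ph$hu) / k)
    # total HU mass (sum x voxel volume) conserved exactly
    expect_equal(sum(rs$hu) * sp^3, sum(ph$hu) * 0.2^3, tolerance = 1e-12)
  }
  uniform <- make_water_cylinder()
  expect_true(all(resample_phantom(uniform, 0.8)$hu == 0))
  expect_error(resample_phantom(ph, 0.5), "integer multiple")
  expect_error(resample_phantom(ph, 0.1), "integer multiple")
  odd <- ph; odd$hu <- ph$hu[1:98, , ]
  expect_error(resample_phantom(odd, 0.8), "divisible")
})

test_that("block means on a hand-built array match direct block averaging", {
  ph <- make_water_cylinder()
  set.seed(11)
  ph$hu <- array(round(stats::runif(4 * 4 * 4, -1000, 1500)), c(4, 4, 4))
  rs <- resample_phantom(ph, 0.4)
  manual <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    manual[i, j, k] <- mean(ph$hu[(2 * i - 1):(2 * i),
                                  (2 * j - 1):(2 * j),
                                  (2 * k - 1):(2 * k)])
  }
  expect_identical(rs$hu, manual)
})

test_that("HU calibration anchors and continuity hold", {
  conv <- hu_to_material(c(0, -600, 700, -1000, 3000))
  expect_equal(conv$material[1], "water")
  expect_equal(conv$density[1], 1.000)
  expect_equal(conv$material[2], "lung")
  expect_lt(conv$density[2], 0.5)
  expect_equal(conv$material[3], "bone")
  expect_gt(conv$density[3], 1.2)
  cal <- hu_calibration()
  for (b in cal$breaks$hu_min[-1]) {
    jump <- abs(cal$density_fn(b + 1e-6) - cal$density_fn(b - 1e-6))
    expect_lt(jump, 0.05)
  }
  expect_error(hu_to_material(-1500), "calibration domain")
  expect_error(hu_to_material(3500), "calibration domain")
})

test_that("tissue I-value scaling is bounded, identity at 1, and deepens the range at 1.06", {
  mats <- default_materials()
  expect_identical(assign_tissue_i_values(mats, 1), mats)
  up <- assign_tissue_i_values(mats, 1.06)
  expect_equal(up$lung$i_value, mats$lung$i_value * 1.06)
  expect_equal(up$aluminum$i_value, mats$aluminum$i_value)  # beamline untouched
  expect_error(assign_tissue_i_values(mats, 1.1), "scale")
  st <- transport_beam(beam_source(), build_beamline(TRUE))
  ph <- make_mouse_phantom("intestine", 1)
  r_base <- range_r80(phantom_depth_dose(st, ph))
  r_up <- range_r80(phantom_depth_dose(st, ph, i_value_scale = 1.06))
  r_dn <- range_r80(phantom_depth_dose(st, ph, i_value_scale = 0.94))
  expect_gt(r_up, r_base)
  expect_lt(r_dn, r_base)
})
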