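test_that("RBE/CBE weighting sums the four components", {
  # unit component doses in tumor: 3.8 + 2.9 + 2.4 + 1.0
  expect_equal(weight_components(1, 1, 1, 1, "tumor", fix_tissues), 10.1)
  expect_equal(weight_components(1, 1, 1, 1, "skin", fix_tissues),
               2.5 + 2.9 + 2.4 + 1.0)
  expect_equal(weight_components(1, 1, 1, 1, "brain", fix_tissues),
               1.34 + 2.9 + 2.4 + 1.0)
  expect_error(weight_components(1, 1, 1, 1, "bone", fix_tissues),
               "unknown tissue")
})

test_that("zero flux yields zero dose rate everywhere", {
  ph <- coarse_phantom()
  beam0 <- beam_model(epithermal_intensity = 0)
  fl <- flux_map(aperture_emission(beam0, if_a_pattern(), fix_grid), ph, beam0)
  dr <- equivalent_dose_rate(fl, fix_tissues, ph)
  expect_true(all(dr$total == 0))
})

test_that("skin and tumor voxels with equal flux differ only via the boron term", {
  ph <- coarse_phantom()
  fl <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                 fix_beam)
  fl$thermal[] <- 1; fl$fast[] <- 0.5; fl$gamma_rate[] <- 0.2
  dr <- equivalent_dose_rate(fl, fix_tissues, ph)
  skin_v <- dr$total[tissue_mask(ph, "skin")][1]
  tumor_v <- dr$total[tissue_mask(ph, "tumor")][1]
  k <- fix_tissues$kerma
  boron_diff <- k$boron_per_ppm * fix_tissues$blood_boron_ppm *
    (3.8 * fix_tissues$tumor_blood_ratio - 2.5 * fix_tissues$skin_blood_ratio)
  expect_equal(tumor_v - skin_v, boron_diff)
  # non-boron components are identical across the two tissues
  for (cc in c("nitrogen", "hydrogen", "gamma")) {
    expect_equal(dr$components[[cc]][tissue_mask(ph, "skin")][1],
                 dr$components[[cc]][tissue_mask(ph, "tumor")][1])
  }
})

test_that("stored components sum to the total at every voxel", {
  ph <- coarse_phantom("small_rect")
  fl <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                 fix_beam)
  dr <- equivalent_dose_rate(fl, fix_tissues, ph)
  expect_equal(Reduce(`+`, dr$components), dr$total, tolerance = 1e-12)
})

test_that("combine_fields evaluates the time-weighted mean exactly", {
  expect_equal(combine_fields(6, 0, 5), 1.0)
  expect_equal(combine_fields(1, 2, 5), 11 / 6)
  for (r in 2:5) expect_equal(combine_fields(3.7, 3.7, r), 3.7)
  a <- array(1:8, c(2, 2, 2)); b <- array(8:1, c(2, 2, 2))
  expect_equal(combine_fields(a, b, 3), (a + 3 * b) / 4)
  expect_error(combine_fields(a, array(0, c(2, 2, 3)), 3), "do not match")
  expect_error(combine_fields(1, 2, 1), "2, 3, 4, 5")
  expect_equal(combine_fields(1, 2, 1, allow_any = TRUE), 1.5)
  expect_error(combine_fields(1, 2, 2.5), "integer")
})

test_that("prescription takes the limiting normal tissue", {
  rx <- prescribe(0.2, 0.1)
  expect_equal(rx$time_min, 60)
  expect_equal(rx$limiting_tissue, "skin")
  rx2 <- prescribe(0.1, 0.5)
  expect_equal(rx2$time_min, 30)
  expect_equal(rx2$limiting_tissue, "brain")
  # doubling both rates halves the time
  expect_equal(prescribe(0.4, 0.2)$time_min, 30)
  # simultaneous saturation is labeled skin-limited
  expect_equal(prescribe(12 / 60, 15 / 60)$limiting_tissue, "skin")
  expect_error(prescribe(0, 0), "no finite prescription")
})

test_that("a plan with IF-B identical to IF-A equals the single-field plan", {
  ph <- coarse_phantom()
  p_single <- plan_doses(if_a_pattern(), NULL, NULL, ph, fix_beam,
                         fix_tissues, fix_grid)
  p_twin <- plan_doses(if_a_pattern(), if_a_pattern(), 3, ph, fix_beam,
                       fix_tissues, fix_grid)
  expect_equal(p_twin$dose, p_single$dose, tolerance = 1e-12)
  expect_equal(p_twin$time_min, p_single$time_min, tolerance = 1e-12)
})

test_that("prescription saturates exactly one normal-tissue limit", {
  for (case in c("wide_disk", "small_rect")) {
    ph <- coarse_phantom(case)
    p <- plan_doses(if_a_pattern(), shape_to_pattern(edge_shape(), 5), 5,
                    ph, fix_beam, fix_tissues, fix_grid)
    sat_skin <- abs(p$skin_max - 12) / 12
    sat_brain <- abs(p$brain_max - 15) / 15
    expect_lt(min(sat_skin, sat_brain), 1e-9)
    expect_lte(p$skin_max, 12 * (1 + 1e-9))
    expect_lte(p$brain_max, 15 * (1 + 1e-9))
  }
})

test_that("dose scales linearly: intensity cancels out of the delivered dose", {
  ph <- coarse_phantom()
  beam2 <- beam_model(epithermal_intensity =
                        fix_beam$epithermal_intensity * 2)
  p1 <- plan_doses(if_a_pattern(), NULL, NULL, ph, fix_beam, fix_tissues,
                   fix_grid)
  p2 <- plan_doses(if_a_pattern(), NULL, NULL, ph, beam2, fix_tissues,
                   fix_grid)
  expect_equal(p2$time_min, p1$time_min / 2, tolerance = 1e-12)
  expect_equal(p2$dose, p1$dose, tolerance = 1e-12)
})

test_that("minimum tumor dose grows with blood boron concentration", {
  ph <- coarse_phantom()
  d_min <- vapply(c(10, 24, 40), function(ppm) {
    tiss <- tissue_model(blood_boron_ppm = ppm)
    plan_doses(if_a_pattern(), shape_to_pattern(edge_shape(), 5), 3, ph,
               fix_beam, tiss, fix_grid)$d_min_tumor
  }, numeric(1))
  expect_true(all(diff(d_min) > 0))
})

test_that("tissue model validates its parameters", {
  expect_error(tissue_model(blood_boron_ppm = -1), "> 0")
  expect_error(tissue_model(skin_blood_ratio = 0), "> 0")
  expect_error(tissue_model(cbe_boron = c(tumor = 3.8)), "must name")
})
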