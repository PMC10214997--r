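test_that("emissions vanish at zero beam intensity and validate inputs", {
  beam0 <- beam_model(epithermal_intensity = 0)
  em <- aperture_emission(beam0, if_a_pattern(), fix_grid)
  expect_true(all(em$thermal == 0) && all(em$fast == 0) && all(em$gamma == 0))
  expect_error(beam_model(profile_sigma_cm = -1), "profile_sigma_cm")
  expect_error(
    beam_model(materials = list(pe = list(thermal_yield_per_cm = 0.6,
                                          self_attenuation = -0.1,
                                          fast_attenuation = 0.5,
                                          gamma_attenuation = 0.06),
                                lif_pe = beam_model()$materials$lif_pe)),
    "positive")
})

test_that("LiF-PE shielding is monotone in thickness and below PE emission", {
  shape <- edge_shape()
  em2 <- aperture_emission(fix_beam, shape_to_pattern(shape, 2), fix_grid)
  em5 <- aperture_emission(fix_beam, shape_to_pattern(shape, 5), fix_grid)
  lif <- em2$material == "LiF-PE"
  for (cc in c("thermal", "fast", "gamma")) {
    expect_true(all(em5[[cc]][lif] <= em2[[cc]][lif]), label = cc)
  }
  # same cells under IF-A (PE) emit at least as much in every component
  em_pe <- aperture_emission(fix_beam, if_a_pattern(), fix_grid)
  for (cc in c("thermal", "fast", "gamma")) {
    expect_true(all(em2[[cc]][lif] <= em_pe[[cc]][lif]), label = cc)
  }
})

test_that("IF-B emission is larger at a perimeter PE cell than at the core", {
  em <- aperture_emission(fix_beam, shape_to_pattern(edge_shape(), 5),
                          fix_grid)
  core_th <- max(em$thermal[em$central & em$core])
  perim_th <- em$thermal[em$central & em$site %in% c(1L, 29L)]
  # site 1 is PE, site 29 is LiF-PE in this pattern
  expect_gt(em$thermal[which(em$site == 1L)], core_th)
})

test_that("flux superposition: a pattern map equals the sum of cell-group maps", {
  ph <- coarse_phantom()
  em <- aperture_emission(fix_beam, shape_to_pattern(edge_shape(), 5),
                          fix_grid)
  split_at <- seq_len(nrow(em)) <= 20
  em_a <- em; em_b <- em
  for (cc in c("thermal", "fast", "gamma")) {
    em_a[[cc]][!split_at] <- 0
    em_b[[cc]][split_at] <- 0
  }
  m_full <- flux_map(em, ph, fix_beam)
  m_a <- flux_map(em_a, ph, fix_beam)
  m_b <- flux_map(em_b, ph, fix_beam)
  for (cc in c("thermal", "fast", "gamma_rate")) {
    expect_equal(m_full[[cc]], m_a[[cc]] + m_b[[cc]], tolerance = 1e-12)
  }
})

test_that("a single active cell reproduces its kernel in closed form", {
  ph <- coarse_phantom()
  em <- aperture_emission(fix_beam, if_a_pattern(), fix_grid)
  keep <- 10   # one off-axis central cell
  for (cc in c("thermal", "fast", "gamma")) {
    v <- em[[cc]][keep]
    em[[cc]][] <- 0
    em[[cc]][keep] <- v
  }
  m <- flux_map(em, ph, fix_beam)
  k <- fix_beam$kernels$thermal
  expected <- em$thermal[keep] *
    outer(outer(exp(-((ph$x - em$x[keep])^2) / (2 * k$sigma_cm^2)),
                exp(-((ph$y - em$y[keep])^2) / (2 * k$sigma_cm^2))),
          (1 - k$buildup_beta * exp(-ph$z / k$buildup_z0_cm)) *
            exp(-ph$z / k$lambda_cm))
  expect_equal(m$thermal, expected, tolerance = 1e-12)
})

test_that("mirror-symmetric pattern and phantom give a mirror-symmetric map", {
  ph <- coarse_phantom()
  for (pat in list(if_a_pattern(), shape_to_pattern(edge_shape(), 5))) {
    m <- flux_map(aperture_emission(fix_beam, pat, fix_grid), ph, fix_beam)
    expect_equal(m$thermal, mirror_flux_x(m$thermal), tolerance = 1e-12)
    expect_equal(m$fast, mirror_flux_x(m$fast), tolerance = 1e-12)
  }
})

test_that("thicker LiF-PE never increases thermal flux anywhere", {
  ph <- coarse_phantom()
  shape <- edge_shape()
  maps <- lapply(c(2, 3, 5), function(t) {
    flux_map(aperture_emission(fix_beam, shape_to_pattern(shape, t),
                               fix_grid), ph, fix_beam)$thermal
  })
  expect_true(all(maps[[2]] <= maps[[1]] + 1e-15))
  expect_true(all(maps[[3]] <= maps[[2]] + 1e-15))
})

test_that("kernel map equals the brute-force dense-sum oracle", {
  ph <- coarse_phantom()
  em <- aperture_emission(fix_beam, shape_to_pattern(edge_shape(), 5),
                          fix_grid)
  fast_map <- flux_map(em, ph, fix_beam)
  dense <- dense_flux_oracle(em, ph, fix_beam)
  for (cc in c("thermal", "fast", "gamma_rate")) {
    expect_equal(fast_map[[cc]], dense[[cc]], tolerance = 1e-10)
  }
})

test_that("flux_at_points samples the layout in order", {
  ph <- make_head_phantom("wide_disk", 0.5)
  lay <- make_evaluation_layout(ph)
  m <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                fix_beam)
  # uniform synthetic field: every point reads the same value
  m$thermal[] <- 7
  expect_equal(unname(flux_at_points(m, lay)), rep(7, 10))
})

test_that("IF-A field is center-peaked with about half the flux 5 cm out", {
  ph <- make_head_phantom("wide_disk", 0.5)
  lay <- make_evaluation_layout(ph)
  m <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                fix_beam)
  phi <- flux_at_points(m, lay)
  expect_length(phi, 10)
  expect_true(all(phi[1] >= phi[5:7]))
  ratio <- phi[[1]] / mean(phi[5:7])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("IF-B field is higher at the 5-cm edge than at the center", {
  ph <- make_head_phantom("wide_disk", 0.5)
  lay <- make_evaluation_layout(ph)
  m <- flux_map(aperture_emission(fix_beam, shape_to_pattern(edge_shape(), 5),
                                  fix_grid), ph, fix_beam)
  phi <- flux_at_points(m, lay)
  expect_true(all(phi[5:7] > phi[[1]]))
})

test_that("combining IF-A and IF-B flattens the surface flux", {
  ph <- make_head_phantom("wide_disk", 0.5)
  lay <- make_evaluation_layout(ph)
  m_a <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                  fix_beam)
  m_b <- flux_map(aperture_emission(fix_beam,
                                    shape_to_pattern(edge_shape(), 5),
                                    fix_grid), ph, fix_beam)
  u_a <- uniformity_index(flux_at_points(m_a, lay))
  u_im <- uniformity_index(flux_at_points(combine_fields(m_a, m_b, 5), lay))
  expect_lt(u_im, u_a)
})

test_that("points outside the flux grid are rejected", {
  ph <- coarse_phantom()
  m <- flux_map(aperture_emission(fix_beam, if_a_pattern(), fix_grid), ph,
                fix_beam)
  lay <- make_evaluation_layout(make_head_phantom("wide_disk", 0.5))
  lay$points$x[3] <- 99
  expect_error(flux_at_points(m, lay), "outside")
})
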