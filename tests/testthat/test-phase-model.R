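test_that("pointwise phase matches closed-form chord arithmetic", {
  m <- ref_model
  # outside the body's projected disc both chords vanish
  expect_identical(phase_at(m, 7, 7), 0)
  expect_identical(phase_at(m, 0, -6.2), 0)
  # body centre: chord 12 um, nucleus not crossed -> (2*pi/0.6328) * 0.04 * 12
  expect_equal(phase_at(m, 0, 0), 4.766006554, tolerance = 1e-9)
  # nucleus centre: body chord 2*sqrt(27), nucleus chord 5
  expect_equal(phase_at(m, 3, 0), 8.099154879, tolerance = 1e-9)
  # vectorised evaluation agrees with scalar evaluation
  xs <- c(-7, -3, 0, 2, 3, 5, 7)
  expect_equal(phase_at(m, xs, 0.5),
               vapply(xs, function(x) phase_at(m, x, 0.5), numeric(1)))
})

test_that("model validation rejects non-nested inclusions", {
  body <- sphere_component(c(0, 0, 0), 6, 1.37, name = "body")
  bad <- sphere_component(c(4.5, 0, 0), 2.5, 1.45, name = "nucleus")
  expect_error(cell_model(body, list(bad)), "nucleus")
  expect_error(sphere_component(c(0, 0, 0), -1, 1.4), "radius")
  expect_error(sphere_component(c(0, 0, 0), 1, 0.9), "refractive index")
})

test_that("rendered map is nonnegative, compactly supported and y-mirror symmetric", {
  map <- render_phase_map(ref_model, ref_grid)
  v <- map$values
  expect_true(all(v >= 0))
  # exactly zero on and outside the body's rim
  r2 <- outer(y_coords(ref_grid)^2, x_coords(ref_grid)^2, "+")
  expect_true(all(v[r2 >= 36] == 0))
  expect_true(any(v[r2 < 36] > 0))
  # the model is mirror-symmetric in y and the pixel-centre grid is symmetric
  expect_equal(v, v[nrow(v):1, ])
  # the map's maximum is the maximum of phase_at over pixel centres, on y = 0
  peak <- which(v == max(v), arr.ind = TRUE)
  expect_equal(unname(peak[1, "row"]), center_row)
  expect_equal(max(v),
               max(phase_at(ref_model, x_coords(ref_grid),
                            y_coords(ref_grid)[center_row])))
})

test_that("zero index contrast renders an all-zero map", {
  m0 <- cell_model(sphere_component(c(0, 0, 0), 6, 1.33),
                   medium_index = 1.33, wavelength = 0.6328)
  expect_true(all(render_phase_map(m0, ref_grid)$values == 0))
})

test_that("phase is additive in index contrast", {
  full <- render_phase_map(ref_model, ref_grid)
  body_only <- render_phase_map(single_sphere_model(), ref_grid)
  # inclusion contrast alone: a sphere carrying only the n2 - n1 contrast
  nuc_contrast <- cell_model(sphere_component(c(3, 0, 0), 2.5, 1.33 + 0.08),
                             medium_index = 1.33, wavelength = 0.6328)
  nuc_only <- render_phase_map(nuc_contrast, ref_grid)
  expect_equal(full$values, body_only$values + nuc_only$values)
})

test_that("closed-form lateral derivative is correct and refuses rim points", {
  m <- ref_model
  # -x term vanishes at the body centre; the nucleus disc is not crossed
  expect_equal(analytic_gradient_profile(m, 0, 0), 0)
  # C1 * (-3/sqrt(27)) at the nucleus centre (nucleus term is zero there)
  expect_equal(analytic_gradient_profile(m, 3, 0), -0.4586091945,
               tolerance = 1e-9)
  expect_error(analytic_gradient_profile(m, 6, 0), "undefined at boundary")
  expect_error(analytic_gradient_profile(m, 5.5, 0), "undefined at boundary")
  # odd symmetry of the single-sphere derivative
  s <- single_sphere_model()
  xs <- c(0.5, 1.5, 3.2, 5.1)
  expect_equal(analytic_gradient_profile(s, xs, 0),
               -analytic_gradient_profile(s, -xs, 0))
})

test_that("noise injection hits the requested SNR and is seed-reproducible", {
  map <- render_phase_map(ref_model, ref_grid)
  # a very large SNR forces sigma to (numerically) zero
  quiet <- add_gaussian_noise(map, noise_spec(300, seed = 1))
  expect_equal(quiet$values, map$values, tolerance = 1e-12)
  # empirical SNR of the injected field: 255^2 samples pin it within 0.2 dB
  noisy <- add_gaussian_noise(map, noise_spec(35, seed = 7))
  p_sig <- mean(map$values^2)
  p_noise <- mean((noisy$values - map$values)^2)
  expect_lt(abs(10 * log10(p_sig / p_noise) - 35), 0.2)
  # determinism: same seed twice gives bit-identical maps
  again <- add_gaussian_noise(map, noise_spec(35, seed = 7))
  expect_identical(noisy$values, again$values)
  other <- add_gaussian_noise(map, noise_spec(35, seed = 8))
  expect_false(identical(noisy$values, other$values))
  # all-zero input has no definable SNR
  zero <- phase_map(matrix(0, 4, 4), grid_spec(1, 1, 4, 4))
  expect_error(add_gaussian_noise(zero, noise_spec(35)), "signal power")
})

test_that("noise injection leaves the caller's RNG stream untouched", {
  map <- render_phase_map(ref_model, grid_spec(15, 15, 32, 32))
  set.seed(99); r1 <- stats::runif(3)
  set.seed(99); invisible(add_gaussian_noise(map, noise_spec(35, seed = 5)))
  r2 <- stats::runif(3)
  expect_identical(r1, r2)
})
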