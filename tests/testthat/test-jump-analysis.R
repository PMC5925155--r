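make_profile <- function(samples) {
  n <- length(samples)
  g <- grid_spec(n, 2, n, 2)
  m <- gradient_map(rbind(samples, 0), g, axis = "x")
  extract_profile(m, profile_line("row", 1))
}

test_that("jump detection finds one extremum per same-sign suprathreshold run", {
  p <- make_profile(c(0, 0, 10, 0, 0, -10, 0))
  j <- detect_jumps(p, threshold_fraction = 0.5)
  expect_identical(j$index, c(3L, 6L))
  expect_identical(j$sign, c(1L, -1L))
  expect_equal(j$magnitude, c(10, 10))
  # constant profile has no jumps
  expect_identical(nrow(detect_jumps(make_profile(rep(2, 6)))), 0L)
  expect_identical(nrow(detect_jumps(make_profile(rep(0, 6)))), 0L)
  # a run keeps one jump even when several samples cross the threshold
  p2 <- make_profile(c(0, 4, 9, 6, 0, -5, -8, -2, 0))
  j2 <- detect_jumps(p2, threshold_fraction = 0.3)
  expect_identical(j2$index, c(3L, 7L))
  # ties resolve to the lowest index
  p3 <- make_profile(c(0, 7, 7, 0, 0))
  expect_identical(detect_jumps(p3, 0.5)$index, 2L)
  # the padded terminal sample is never a jump
  p4 <- make_profile(c(0, 0, 0, 10))
  expect_identical(nrow(detect_jumps(p4, 0.5)), 0L)
  expect_error(detect_jumps(p, threshold_fraction = 0), "threshold_fraction")
  expect_error(detect_jumps(p, threshold_fraction = 1), "threshold_fraction")
})

test_that("nested +/- jump sequences pair outside-in", {
  j <- data.frame(index = c(28L, 138L, 221L, 229L), sign = c(1L, 1L, -1L, -1L))
  pr <- pair_jumps(j)
  expect_identical(pr$left_index, c(28L, 138L))
  expect_identical(pr$right_index, c(229L, 221L))
  expect_identical(pr$level, 1:2)
  j2 <- data.frame(index = c(35L, 162L, 196L, 222L), sign = c(1L, 1L, -1L, -1L))
  pr2 <- pair_jumps(j2)
  expect_identical(pr2$left_index, c(35L, 162L))
  expect_identical(pr2$right_index, c(222L, 196L))
  # a single +/- pair
  pr3 <- pair_jumps(data.frame(index = c(5L, 90L), sign = c(1L, -1L)))
  expect_identical(nrow(pr3), 1L)
  # odd counts and non-nested sign patterns are refused with the sequence named
  expect_error(pair_jumps(data.frame(index = c(1L, 2L, 3L),
                                     sign = c(1L, 1L, -1L))), "even")
  expect_error(pair_jumps(data.frame(index = c(1L, 5L, 9L, 12L),
                                     sign = c(1L, -1L, 1L, -1L))),
               "not strictly nested|nested-hill")
})

test_that("pixel pairs convert to micrometres through the grid calibration", {
  # agreement at the printed 3-decimal precision (201 px = 11.8235... um)
  expect_lt(abs(pixel_pair_distance(28, 229, ref_grid) - 11.823), 1e-3)
  expect_equal(round(pixel_pair_distance(138, 221, ref_grid), 3), 4.882)
  expect_equal(round(pixel_pair_distance(162, 196, ref_grid), 3), 2.000)
  expect_equal(pixel_pair_distance(40, 40, ref_grid), 0)
  expect_error(pixel_pair_distance(10, 400, ref_grid), "outside")
  expect_error(pixel_pair_distance(50, 20, ref_grid), "i <= j")
})

test_that("distance reports carry pair separations plus left/right gaps", {
  pr <- pair_jumps(data.frame(index = c(28L, 138L, 221L, 229L),
                              sign = c(1L, 1L, -1L, -1L)))
  rep <- build_distance_report(pr, ref_grid)
  expect_identical(rep$type, c("diameter", "diameter", "gap", "gap"))
  expect_true(all(abs(rep$microns - c(11.823, 4.882, 6.471, 0.471)) < 1e-3))
  expect_identical(rep$pixels, c(201L, 83L, 110L, 8L))
  # physical separation is exactly pixels times pitch
  expect_equal(rep$microns, rep$pixels * ref_pitch)
  pr_c <- pair_jumps(data.frame(index = c(35L, 162L, 196L, 222L),
                                sign = c(1L, 1L, -1L, -1L)))
  rep_c <- build_distance_report(pr_c, ref_grid)
  expect_true(all(abs(rep_c$microns - c(11.000, 2.000, 7.471, 1.529)) < 1e-3))
  # a single pair yields one diameter row and no gap rows
  one <- build_distance_report(
    pair_jumps(data.frame(index = c(5L, 90L), sign = c(1L, -1L))), ref_grid)
  expect_identical(nrow(one), 1L)
  expect_identical(one$type, "diameter")
})

test_that("error statistics aggregate diameters and relative errors as reported", {
  rep <- as_distance_report(c(11.823, 4.882, 6.471, 0.471),
                            c("diameter", "diameter", "gap", "gap"))
  s <- diameter_error_stats(rep, c(12, 5, 6.5, 0.5))
  # max error over the diameter rows only
  expect_equal(s$max_diameter_error_um, 0.177)
  # mean relative error over all four rows, 2.5% to 2 significant figures
  expect_equal(signif(s$mean_relative_error_pct, 2), 2.5)
  expect_equal(s$mean_relative_error_pct,
               100 * mean(c(0.177 / 12, 0.118 / 5, 0.029 / 6.5, 0.029 / 0.5)),
               tolerance = 1e-12)
  # perfect agreement gives all-zero errors
  s0 <- diameter_error_stats(as_distance_report(c(12, 5), c("diameter", "diameter")),
                             c(12, 5))
  expect_equal(s0$max_diameter_error_um, 0)
  expect_equal(s0$mean_relative_error_pct, 0)
  # rows with unknown truth drop out of the mean
  s_na <- diameter_error_stats(rep, c(12, 5, NA, NA))
  expect_equal(s_na$mean_relative_error_pct,
               100 * mean(c(0.177 / 12, 0.118 / 5)))
  expect_error(diameter_error_stats(rep, c(12, 5)), "4 report rows")
  expect_error(diameter_error_stats(rep, c(12, 5, 0, 0.5)), "nonzero")
})

test_that("profiles crossing both discs give 4 nested jumps, others 2", {
  map <- render_phase_map(ref_model, ref_grid)
  gx <- forward_diff_gradient(map, "x")
  # rows through the nucleus (|y| < 2.5 with a margin above one pixel)
  for (r in c(95L, 110L, 128L, 150L, 165L)) {
    j <- detect_jumps(extract_profile(gx, profile_line("row", r)))
    expect_identical(j$sign, c(1L, 1L, -1L, -1L))
    p <- pair_jumps(j)
    expect_identical(nrow(p), 2L)
    expect_true(p$left_index[2] > p$left_index[1] &&
                p$right_index[2] < p$right_index[1])
  }
  # rows crossing the body but missing the nucleus
  for (r in c(30L, 60L, 200L, 225L)) {
    j <- detect_jumps(extract_profile(gx, profile_line("row", r)))
    expect_identical(j$sign, c(1L, -1L))
  }
})

test_that("squared and signed profiles locate the same jump pixels", {
  map <- render_phase_map(ref_model, ref_grid)
  gx <- forward_diff_gradient(map, "x")
  sq <- modulus_squared(gx)
  for (r in c(60L, 110L, 128L, 150L)) {
    line <- profile_line("row", r)
    ps <- extract_profile(gx, line)
    pq <- extract_profile(sq, line)
    js <- detect_jumps(ps)
    jq <- detect_jumps(pq, signed = ps)
    expect_identical(jq$index, js$index)
    expect_identical(jq$sign, js$sign)
    expect_equal(jq$magnitude, abs(ps$samples[jq$index]))
  }
  # a squared profile without its signed companion cannot assign signs
  expect_error(detect_jumps(extract_profile(sq, profile_line("row", 128))),
               "signed")
})

test_that("doubling the grid moves each reported distance by less than a coarse pixel", {
  report_for <- function(n) {
    g <- grid_spec(15, 15, n, n)
    map <- render_phase_map(ref_model, g)
    prof <- signed_profile(map, profile_line("row", which.min(abs(y_coords(g)))))
    build_distance_report(pair_jumps(detect_jumps(prof)), g,
                          step_um = prof$step_um)
  }
  coarse <- report_for(255L)
  fine <- report_for(510L)
  expect_identical(nrow(fine), nrow(coarse))
  expect_true(all(abs(fine$microns - coarse$microns) < ref_pitch + 1e-12))
})
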