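test_that("validity mask applies the background and saturation rules", {
  co <- matrix(c(2, 254, 3, 255), 2, 2) # columns: (2,254), (3,255)
  cross <- matrix(128, 2, 2)
  m <- make_validity_mask(co, cross)
  expect_equal(m$valid, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(m$n_background_excluded, 1L)
  expect_equal(m$n_saturated_excluded, 1L)

  all_mid <- matrix(128, 3, 3)
  m <- make_validity_mask(all_mid, all_mid)
  expect_true(all(m$valid))
  expect_equal(m$n_background_excluded + m$n_saturated_excluded, 0L)
})

test_that("a pixel bad in any frame of either channel is excluded everywhere", {
  co <- array(128, dim = c(2, 2, 3))
  cross <- array(128, dim = c(2, 2, 3))
  co[1, 1, 3] <- 255          # saturated only in frame 3
  cross[2, 2, 1] <- 0         # background only in the cross channel
  m <- make_validity_mask(co, cross)
  expect_false(m$valid[1, 1])
  expect_false(m$valid[2, 2])
  expect_equal(sum(m$valid), 2L)
  expect_equal(m$n_saturated_excluded, 1L)
  expect_equal(m$n_background_excluded, 1L)

  expect_error(make_validity_mask(matrix(1, 2, 2), matrix(1, 3, 3)),
               "identical dimensions")
  expect_error(make_validity_mask(co, cross, low = 10, high = 5),
               "thresholds")
})

test_that("frame averaging is the per-pixel mean with sentinel propagation", {
  stack <- array(c(1, 2, 3), dim = c(1, 1, 3))
  stack <- array(rep(c(1, 2, 3), each = 4), dim = c(2, 2, 3))
  expect_equal(average_frames(stack), matrix(2, 2, 2))

  one <- matrix(runif(16, 10, 200), 4, 4)
  expect_equal(average_frames(one), one)

  x <- matrix(sample(10:200, 16), 4, 4)
  rep3 <- array(rep(x, 3), dim = c(4, 4, 3))
  expect_equal(average_frames(rep3), x)

  v <- make_validity_mask(rep3, rep3)
  v$valid[1, 1] <- FALSE
  avg <- average_frames(rep3, v)
  expect_true(is.na(avg[1, 1]))
  expect_equal(avg[-1], x[-1])
})

test_that("the polarization ratio reproduces hand-worked values", {
  expect_equal(compute_fpol(200, 0, 0.75), 1.0)
  expect_equal(compute_fpol(75, 100, 0.75), 0.0)
  expect_equal(compute_fpol(175, 140, 0.75), 0.25)
  expect_error(compute_fpol(0, 0, 0.75), "denominator")
  expect_true(is.na(compute_fpol(0, 0, 0.75, na_undefined = TRUE)))
  expect_error(compute_fpol(-1, 5, 0.75), "non-negative")
  expect_error(compute_fpol(1, 5, -0.75), "positive")
})

test_that("Fpol is bounded, monotone, and scale invariant", {
  set.seed(41)
  fco <- runif(500, 0, 255)
  fcross <- runif(500, 0, 255)
  for (g in c(0.5, 0.75, 1.3)) {
    p <- compute_fpol(fco, fcross, g, na_undefined = TRUE)
    ok <- !is.na(p)
    expect_true(all(p[ok] >= -1 & p[ok] <= 1))
    # strictly increasing in fco, decreasing in fcross
    expect_true(all(compute_fpol(fco + 1, fcross, g) > p, na.rm = TRUE))
    expect_true(all(compute_fpol(fco, fcross + 1, g,
                                 na_undefined = TRUE) < p, na.rm = TRUE))
    # homogeneity of degree zero
    for (c_ in c(0.1, 7)) {
      expect_equal(compute_fpol(c_ * fco, c_ * fcross, g, na_undefined = TRUE),
                   p, tolerance = 1e-12)
    }
  }
})

test_that("emission image follows the configured total-signal convention", {
  pair <- make_uniform_pair(100, 400 / 3, g = 0.75)
  expect_equal(compute_emission(pair), matrix(200, 4, 4), tolerance = 1e-9)
  expect_equal(compute_emission(pair, "co_plus_cross"),
               matrix(100 + 400 / 3, 4, 4))
  expect_equal(compute_emission(pair, "co_plus_2g_cross"),
               matrix(300, 4, 4), tolerance = 1e-9)

  pairx <- make_uniform_pair(137, 0)
  expect_equal(compute_emission(pairx), matrix(137, 4, 4))

  field <- polarized_field(matrix(c(2, 100, 100, 100), 2, 2),
                           matrix(100, 2, 2), pixel_pitch_um = 0.4)
  pair_na <- average_channels(field)
  expect_true(is.na(compute_emission(pair_na)[1, 1]))
})

test_that("fpol_map matches a naive double-loop oracle", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 24L
    co <- matrix(round(runif(n^2, 0, 255)), n, n)
    cross <- matrix(round(runif(n^2, 0, 255)), n, n)
    field <- polarized_field(co, cross, g_factor = 0.75,
                             pixel_pitch_um = 0.4)
    pair <- average_channels(field)
    got <- fpol_map(pair)
    ref <- naive_fpol_map(pair$fco_avg, pair$fcross_avg, 0.75)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("fpol_map is constant on a synthesized uniform field", {
  ch <- solve_intensities(0.25, 280, 0.75)
  pair <- make_uniform_pair(round(ch$fco), round(ch$fcross))
  m <- fpol_map(pair)
  expect_true(all(abs(m - 0.25) <= 0.01))

  cross_only <- make_uniform_pair(0, 100)
  expect_true(all(fpol_map(cross_only) == -1))

  bg <- polarized_field(matrix(1, 3, 3), matrix(1, 3, 3),
                        pixel_pitch_um = 0.4)
  expect_true(all(is.na(fpol_map(average_channels(bg)))))
})

test_that("G calibration recovers the configured factor", {
  co <- matrix(75, 8, 8)
  cross <- matrix(100, 8, 8)
  expect_equal(estimate_g(co, cross), 0.75)
  expect_equal(estimate_g(co, co), 1.0)
  # nonzero reference polarization
  ch <- solve_intensities(0.2, 200, 0.9)
  expect_equal(estimate_g(matrix(ch$fco, 4, 4), matrix(ch$fcross, 4, 4),
                          reference_fpol = 0.2), 0.9, tolerance = 1e-12)
  expect_error(estimate_g(co, matrix(0, 8, 8)), "calibration")

  # noisy isotropic synthetic field: law of large numbers within 1%
  cfg <- imaging_config(image_size_px = 256L)
  iso <- render_sample(list(sample_id = "iso", n_cells = 12L,
                            fpol_mean = 1e-6, fpol_sd = 0), cfg, seed = 21)
  f <- iso$fields[[1]]
  sel <- iso$label_maps[[1]] > 0
  m <- make_validity_mask(f$co_frames, f$cross_frames)
  co_avg <- average_frames(f$co_frames, m)
  cross_avg <- average_frames(f$cross_frames, m)
  g_hat <- mean(co_avg[sel], na.rm = TRUE) / mean(cross_avg[sel], na.rm = TRUE)
  expect_lt(abs(g_hat - 0.75) / 0.75, 0.01)
})

test_that("per-cell Fpol aggregates intensities before the ratio", {
  fco <- matrix(c(150, 200, 50, 50), 2, 2)
  fcross <- matrix(c(120, 160, 50, 50), 2, 2)
  field <- polarized_field(fco, fcross, g_factor = 0.75, pixel_pitch_um = 0.4)
  pair <- average_channels(field)
  labels <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  rec <- cell_fpol(labels, pair)
  expect_equal(rec$fco_sum, 350)
  expect_equal(rec$fcross_sum, 280)
  expect_equal(rec$fpol, 0.25)
  expect_equal(rec$n_pixels, 2L)
  expect_equal(rec$area_um2, 2 * 0.4^2)

  # single-pixel cell equals the pixelwise ratio
  labels1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  rec1 <- cell_fpol(labels1, pair)
  expect_equal(rec1$fpol, compute_fpol(150, 120, 0.75))

  # uniform cell: any sub-region gives the same Fpol (degree-zero homogeneity)
  pairu <- make_uniform_pair(175, 140, n = 6L)
  big <- matrix(0L, 6, 6); big[2:5, 2:5] <- 1L
  small <- matrix(0L, 6, 6); small[3, 3] <- 1L
  expect_equal(cell_fpol(big, pairu)$fpol, cell_fpol(small, pairu)$fpol)

  # cell_fpol equals compute_fpol on the channel means over the same pixels
  set.seed(10)
  co <- matrix(round(runif(36, 20, 240)), 6, 6)
  cross <- matrix(round(runif(36, 20, 240)), 6, 6)
  pr <- average_channels(polarized_field(co, cross, pixel_pitch_um = 0.4))
  sel <- big == 1L
  expect_equal(cell_fpol(big, pr)$fpol,
               compute_fpol(mean(pr$fco_avg[sel]), mean(pr$fcross_avg[sel]),
                            0.75), tolerance = 1e-12)
})

test_that("cells without valid pixels are flagged and excluded", {
  co <- matrix(255, 3, 3); co[1, ] <- 100
  cross <- matrix(100, 3, 3)
  pair <- average_channels(polarized_field(co, cross, pixel_pitch_um = 0.4))
  labels <- matrix(0L, 3, 3)
  labels[1, 1] <- 1L   # valid row
  labels[3, 3] <- 2L   # saturated row -> no valid pixels
  expect_warning(rec <- cell_fpol(labels, pair), "no valid pixels")
  expect_equal(rec$label, 1L)
})
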