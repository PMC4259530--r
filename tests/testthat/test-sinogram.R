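test_that("count_window sums exactly the bins inside the window", {
  set.seed(31)
  p <- generate_protocol(n_angles = 3, n_positions = 9, seed = 31)
  vals <- array(rpois(3 * 9 * 150, 2), dim = c(3, 9, 150))
  psth <- structure(list(values = vals, bin_width = 0.002, window = c(0, 0.3),
                         n_repeats_averaged = 3, modality = "spikes",
                         angles = p$angles, spacing = 40,
                         length_unit = "micrometre"), class = "psth_stack")
  off <- count_window(psth, c(0, 0.150), "OFF")
  on <- count_window(psth, c(0.150, 0.300), "ON")
  tot <- count_window(psth, c(0, 0.300), "total")
  # brute-force bin sums per (angle, position)
  for (a in 1:3) for (k in 1:9) {
    expect_equal(off$values[a, k], sum(vals[a, k, 1:75]))
    expect_equal(on$values[a, k], sum(vals[a, k, 76:150]))
  }
  # OFF + ON partition the total window
  expect_equal(off$values + on$values, tot$values)
  # z axis centred at the grid middle
  expect_equal(off$z[5], 0)
  # baseline subtraction: rate x window x repeats per entry
  offb <- count_window(psth, c(0, 0.150), baseline_rate = 4)
  expect_equal(offb$values, off$values - 4 * 0.150 * 3)
  expect_error(count_window(psth, c(0, 0.4)), "outside")
  expect_warning(count_window(psth, c(0, 0.1501)), "snap")
})

test_that("all-zero PSTH gives an all-zero sinogram", {
  p <- generate_protocol(seed = 1)
  psth <- build_psth(numeric(0), p)
  expect_equal(max(abs(count_window(psth)$values)), 0)
})

test_that("fluorescence integrals match an independent trapezoid oracle", {
  fr <- 10
  nb <- 20
  tt <- (seq_len(nb) - 0.5) / fr
  ker <- exp(-tt / 0.4) * (1 - exp(-tt / 0.05))
  vals <- array(0, dim = c(2, 3, nb))
  vals[1, 2, ] <- ker
  vals[2, 3, ] <- 5          # rectangle of height 5
  psth <- structure(list(values = vals, bin_width = 1 / fr, window = c(0, 2),
                         n_repeats_averaged = 1, modality = "fluorescence",
                         angles = c(0, 90), spacing = 3.2,
                         length_unit = "degree"), class = "psth_stack")
  sg <- fluorescence_integral(psth, c(0, 2))
  expect_equal(sg$values[1, 2], pracma::trapz(tt, ker), tolerance = 1e-9)
  # rectangle fully inside the window: height x (integration span)
  expect_equal(sg$values[2, 3], pracma::trapz(tt, rep(5, nb)), tolerance = 1e-12)
  expect_equal(sg$values[1, 1], 0)
  expect_error(fluorescence_integral(build_psth(numeric(0), generate_protocol(seed = 1))),
               "fluorescence")
})

test_that("noiseless sinogram rows are proportional to true line integrals", {
  p <- default_protocol(seed = 1)
  nrn <- default_off_cell(p, centre = c(40, -40))
  g <- expected_rate(nrn, p)
  fl <- p$flashes
  vals <- matrix(0, 5, 29)
  for (i in seq_len(nrow(fl))) {
    a <- match(fl$angle_deg[i], p$angles)
    k <- fl$position_index[i] + 1L
    vals[a, k] <- vals[a, k] +
      sum(g$rate[g$t >= fl$onset_s[i] & g$t < fl$onset_s[i] + 0.15]) * 0.001
  }
  # dense numerical projection of the ground-truth map
  proj <- oracle_project(nrn$components[[1]]$map, p$angles, protocol_z(p), 40)
  for (a in 1:5)
    expect_gt(cor(vals[a, ], proj[a, ]), 0.99)
  # projection-mass invariance across angles (evoked counts only)
  evoked <- rowSums(vals) - 2 * 0.15 * 3 * 29
  expect_lt(max(abs(evoked / mean(evoked) - 1)), 0.05)
})

test_that("orientation tuning finds the bar axis aligned with the RF's long axis", {
  # oriented cell at 90 deg: noiseless forward projection
  nrn <- make_model_rf("oriented", theta = 90, sigma_major = 240,
                       sigma_minor = 80)
  ang9 <- (0:8) * 20
  sg <- project_image(neuron_map(nrn), angles = ang9)
  ot <- orientation_tuning(sg)
  expect_equal(ot$preferred_angle, 90)
  expect_gt(ot$selectivity_index, 0.3)

  # isotropic field: near-flat tuning
  iso <- make_model_rf("gaussian", sigma_major = 120, sigma_minor = 120)
  ot2 <- orientation_tuning(project_image(neuron_map(iso), angles = ang9))
  expect_lt(ot2$selectivity_index, 0.1)

  # single nonzero entry: fully selective; row at projection angle 36
  vals <- matrix(0, 5, 9); vals[2, 4] <- 1
  s <- fbpmap:::new_sinogram(vals, (0:4) * 36, seq(-4, 4) * 40, 40)
  ot3 <- orientation_tuning(s)
  expect_equal(ot3$selectivity_index, 1)
  expect_equal(ot3$projection_angles[which.max(ot3$peak_response)], 36)
  expect_equal(ot3$preferred_angle, (36 + 90) %% 180)

  # degenerate all-zero sinogram
  ot4 <- orientation_tuning(fbpmap:::new_sinogram(matrix(0, 5, 9), (0:4) * 36,
                                                  seq(-4, 4) * 40, 40))
  expect_true(ot4$degenerate)
  expect_equal(ot4$selectivity_index, 0)
})

test_that("sinogram CSV round-trips", {
  p <- generate_protocol(n_angles = 3, n_positions = 7, seed = 2)
  vals <- matrix(rnorm(21), 3, 7)
  s <- fbpmap:::new_sinogram(vals, p$angles, protocol_z(p), 40, "OFF")
  f <- withr::local_tempfile(fileext = ".csv")
  write_sinogram(s, f)
  back <- read_sinogram(f)
  expect_equal(back$values, s$values, tolerance = 1e-12)
  expect_equal(back$angles, s$angles)
  expect_equal(back$z, s$z)
  expect_equal(back$component, "OFF")
})
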