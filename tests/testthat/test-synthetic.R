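test_that("model neurons are built to their requested geometry", {
  # gaussian: the stored map fits back to the requested parameters exactly
  nrn <- make_model_rf("gaussian", centre = c(80, -40), sigma_major = 150,
                       sigma_minor = 100, theta = 20)
  f <- fit_gaussian2d(neuron_map(nrn))
  hw <- sqrt(2 * log(2))
  expect_equal(f$centre_x, 80, tolerance = 1e-5)
  expect_equal(f$centre_y, -40, tolerance = 1e-5)
  expect_equal(f$half_width_major, 150 * hw, tolerance = 1e-5)
  expect_equal(f$half_width_minor, 100 * hw, tolerance = 1e-5)
  expect_equal(f$orientation, 20, tolerance = 1e-3)

  # concentric ON-OFF: the OFF centre is smaller than the ON surround
  oo <- make_model_rf("on_off_concentric")
  fo <- fit_gaussian2d(neuron_map(oo, "OFF"))
  fn <- fit_gaussian2d(neuron_map(oo, "ON"))
  expect_lt(fo$half_width_major, fn$half_width_major)
  expect_equal(vapply(oo$components, `[[`, "", "label"), c("OFF", "ON"))

  # oriented: elongation at least 2:1 is enforced
  ori <- make_model_rf("oriented", sigma_major = 150, sigma_minor = 100)
  fo2 <- fit_gaussian2d(neuron_map(ori))
  expect_gte(fo2$half_width_major / fo2$half_width_minor, 1.9)
  expect_error(make_model_rf("squares"))
})

test_that("bar overlaps agree with dense numerical integration", {
  nrn <- make_model_rf("gaussian", centre = c(40, -40))
  p <- default_protocol(seed = 1)
  ov <- fbpmap:::.bar_overlaps(nrn$components[[1]]$map, 40, p$angles,
                               protocol_z(p), 80, super = 8L)
  # oracle: 32x denser rasterisation of the same geometry
  ov_dense <- fbpmap:::.bar_overlaps(nrn$components[[1]]$map, 40, p$angles,
                                     protocol_z(p), 80, super = 32L)
  expect_lt(max(abs(ov - ov_dense)) / max(ov_dense), 5e-3)
})

test_that("expected_rate reduces to the baseline without stimulus drive", {
  p <- default_protocol(seed = 1)
  # zero-amplitude map: rate == baseline everywhere
  nrn <- make_model_rf("gaussian")
  nrn$components[[1]]$gain <- 0
  r <- expected_rate(nrn, p, t = c(0.05, 10, 100))
  expect_equal(r, rep(2, 3))
  # a cell far outside the sampled area: baseline during every flash
  far <- make_model_rf("gaussian", centre = c(5000, 5000))
  r2 <- expected_rate(far, p, t = p$flashes$onset_s[1:20] + 0.08)
  expect_equal(r2, rep(2, 20), tolerance = 1e-6)
})

test_that("the rate excursion is proportional to the map mass under the bar", {
  p <- default_protocol(seed = 1)
  nrn <- make_model_rf("gaussian", centre = c(0, 0), sigma_major = 120,
                       sigma_minor = 120, baseline_rate = 0,
                       kernel = biphasic_kernel(w = 0))  # monophasic
  nrn$components[[1]]$gain <- 1
  ov <- fbpmap:::.bar_overlaps(nrn$components[[1]]$map, 40, p$angles,
                               protocol_z(p), 80)
  g <- expected_rate(nrn, p)
  fl <- p$flashes
  # peak rate during each flash of angle 0 vs overlap of that bar
  sel <- which(fl$angle_deg == 0)[1:29]
  peaks <- vapply(fl$onset_s[sel], function(on)
    max(g$rate[g$t >= on & g$t < on + 0.45]), numeric(1))
  o <- ov[1, fl$position_index[sel] + 1L]
  keep <- o > 1e-6 * max(o)
  ratio <- peaks[keep] / o[keep]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("simulate_spikes is a seeded inhomogeneous Poisson sampler", {
  # pure baseline: count within 3 sigma of rate x duration
  nrn <- make_model_rf("gaussian", baseline_rate = 5)
  nrn$components[[1]]$gain <- 0
  sp <- simulate_spikes(nrn, NULL, duration = 100, seed = 91)
  expect_lt(abs(length(sp) - 500), 3 * sqrt(500))
  # reproducible; different seeds differ
  expect_identical(sp, simulate_spikes(nrn, NULL, duration = 100, seed = 91))
  expect_false(identical(sp, simulate_spikes(nrn, NULL, duration = 100, seed = 92)))
  # inter-spike intervals of the homogeneous process are exponential
  ks <- stats::ks.test(diff(sp), "pexp", rate = 5)
  expect_gt(ks$p.value, 0.01)
  # zero rate: empty train
  z <- make_model_rf("gaussian", baseline_rate = 0)
  z$components[[1]]$gain <- 0
  expect_length(simulate_spikes(z, NULL, duration = 50, seed = 93), 0)
  # runaway rates are guarded
  hot <- make_model_rf("gaussian", baseline_rate = 2e4)
  expect_error(simulate_spikes(hot, NULL, duration = 1, seed = 94), "10 kHz")
})

test_that("simulated calcium noise has the requested standard deviation", {
  p <- generate_protocol(n_angles = 2, n_positions = 5, seed = 95,
                         flash_duration = 0.5, duty_cycle = 2.5)
  quiet <- make_model_rf("gaussian", grid = 5, baseline_rate = 0)
  quiet$components[[1]]$gain <- 0
  cal <- calcium_model(noise_sd = 0.3, frame_rate = 100)
  tr <- simulate_calcium(quiet, p, cal, duration = 100, seed = 96,
                         rate_based = TRUE)
  expect_gte(ncol(tr$traces), 1e4)
  expect_lt(abs(sd(tr$traces[1, ]) / 0.3 - 1), 0.1)
  expect_error(calcium_model(rise = 0.5, decay = 0.4), "decay > rise")
})

test_that("neurons and protocols serialise together for reproducible runs", {
  p <- generate_protocol(n_angles = 2, n_positions = 7, seed = 97)
  nrn <- make_model_rf("gaussian", grid = 7)
  sp1 <- simulate_spikes(nrn, p, seed = 98)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spikes(sp1, "u1", f)
  back <- read_spikes(f, unit = "u1")
  expect_equal(back, sp1, tolerance = 1e-12)
})
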