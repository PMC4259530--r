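test_that("a single spike lands in the correct PSTH cell and bin", {
  p <- generate_protocol(seed = 1)
  fl <- p$flashes
  i <- which(fl$angle_deg == 0 & fl$position_index == 3)[1]
  spike <- fl$onset_s[i] + 0.055
  psth <- build_psth(spike, p, bin_width = 0.008, window = c(0, 0.296))
  expect_equal(sum(psth$values), 1)
  # 55 ms falls in the 7th 8-ms bin (1-based)
  expect_equal(psth$values[1, 4, 7], 1)
})

test_that("PSTH assembly deshuffles: invariant to flash presentation order", {
  p1 <- generate_protocol(seed = 10)
  p2 <- generate_protocol(seed = 11)   # same multiset, different order
  # deterministic response: one spike 50 ms after every flash of position 5
  mk_spikes <- function(p) {
    fl <- p$flashes
    sort(fl$onset_s[fl$position_index == 5] + 0.0513)
  }
  a <- build_psth(mk_spikes(p1), p1)
  b <- build_psth(mk_spikes(p2), p2)
  expect_equal(a$values, b$values)
})

test_that("spike counts are conserved and scale linearly with repeats", {
  p1 <- generate_protocol(n_repeats = 1, seed = 4)
  p2 <- generate_protocol(n_repeats = 2, seed = 4)
  resp <- function(p) sort(c(p$flashes$onset_s + 0.0213, p$flashes$onset_s + 0.1117))
  a <- build_psth(resp(p1), p1)
  b <- build_psth(resp(p2), p2)
  expect_equal(sum(a$values), 2 * nrow(p1$flashes))  # all spikes inside window
  expect_equal(b$values, 2 * a$values)               # identical per-repeat response
  # spikes outside all analysis windows are ignored
  c <- build_psth(c(resp(p1), max(p1$flashes$onset_s) + 10), p1)
  expect_equal(sum(c$values), sum(a$values))
})

test_that("PSTH of a simulated OFF cell matches the Poisson rate oracle", {
  p <- default_protocol(seed = 1)
  nrn <- default_off_cell(p)
  sp <- simulate_spikes(nrn, p, seed = 77)
  psth <- build_psth(sp, p)
  # expectation for the strongest-overlap (angle, position), chosen from
  # the model itself so the comparison is not selection-biased
  g <- expected_rate(nrn, p)
  fl <- p$flashes
  ov <- fbpmap:::.bar_overlaps(nrn$components[[1]]$map, 40, p$angles,
                               protocol_z(p), 80)
  best <- which(ov == max(ov), arr.ind = TRUE)[1, ]
  a <- best[1]; pos <- best[2]
  sel <- fl$angle_deg == p$angles[a] & fl$position_index == pos - 1L
  mu <- sum(vapply(fl$onset_s[sel], function(on)
    sum(g$rate[g$t >= on & g$t < on + 0.3]) * 0.001, numeric(1)))
  observed <- sum(psth$values[a, pos, ])
  expect_lt(abs(observed - mu), 3 * sqrt(mu))
})

test_that("fluorescence PSTH subtracts baselines and averages repeats", {
  p <- generate_protocol(n_angles = 2, n_positions = 5, flash_duration = 0.5,
                         duty_cycle = 2.5, n_repeats = 2, seed = 9,
                         length_unit = "degree")
  dur <- (nrow(p$flashes) + 1) * p$duty_cycle + 2
  fr <- 10
  n_frames <- ceiling(dur * fr)
  # constant trace: all-zero PSTH after baseline subtraction
  tr <- structure(list(roi_ids = "r1", frame_rate = fr,
                       traces = matrix(7, 1, n_frames)), class = "roi_trace_set")
  psth <- build_fluorescence_psth(tr, "r1", p, window = c(0, 2))
  expect_equal(max(abs(psth$values)), 0)
  expect_equal(psth$bin_width, 1 / fr)

  # responses r and -r on the two repeats of one flash average to zero
  fl <- p$flashes
  idx <- which(fl$angle_deg == 0 & fl$position_index == 2)
  y <- numeric(n_frames)
  mid <- (seq_len(n_frames) - 0.5) / fr
  y[mid >= fl$onset_s[idx[1]] & mid < fl$onset_s[idx[1]] + 2] <- 3
  y[mid >= fl$onset_s[idx[2]] & mid < fl$onset_s[idx[2]] + 2] <- -3
  tr$traces <- matrix(y, 1)
  psth2 <- build_fluorescence_psth(tr, "r1", p, window = c(0, 2))
  expect_equal(max(abs(psth2$values[1, 3, ])), 0)
  expect_error(build_fluorescence_psth(tr, "nope", p), "unknown ROI")
})

test_that("noise-free calcium responses equal the direct convolution oracle", {
  p <- generate_protocol(n_angles = 2, n_positions = 7, bar_width = 6.2,
                         position_spacing = 3.2, flash_duration = 0.5,
                         duty_cycle = 2.5, n_repeats = 1, seed = 21,
                         length_unit = "degree")
  nrn <- calibrate_gain(make_model_rf("gaussian", grid = 7, spacing = 3.2,
                                      sigma_major = 5, sigma_minor = 5,
                                      baseline_rate = 0,
                                      length_unit = "degree"), p, 50)
  cal <- calcium_model(noise_sd = 0, frame_rate = 10)
  tr <- simulate_calcium(nrn, p, cal, seed = 1, rate_based = TRUE)
  # oracle: convolve the expected rate with the indicator kernel directly
  dur <- max(p$flashes$onset_s) + p$duty_cycle + 0.5
  g <- expected_rate(nrn, p)
  dt <- 0.001
  kt <- seq(0, cal$decay * 6, by = dt)
  ker <- (1 - exp(-kt / cal$rise)) * exp(-kt / cal$decay)
  ker <- ker / max(ker)
  conv_full <- stats::convolve(c(g$rate * dt, numeric(length(ker))), rev(ker),
                               type = "open")
  f_idx <- round(((seq_len(ncol(tr$traces)) - 0.5) / 10) / dt) + 1L
  expect_lt(max(abs(tr$traces[1, ] - conv_full[f_idx])), 1e-8)
})

test_that("ROI trace CSV round-trips", {
  tr <- structure(list(roi_ids = c("a", "b"), frame_rate = 10,
                       traces = matrix(rnorm(40), 2, 20)),
                  class = "roi_trace_set")
  f <- withr::local_tempfile(fileext = ".csv")
  write_roi_traces(tr, f)
  back <- read_roi_traces(f)
  expect_equal(back$roi_ids, tr$roi_ids)
  expect_equal(back$frame_rate, 10)
  expect_equal(back$traces, tr$traces, tolerance = 1e-12)
})
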