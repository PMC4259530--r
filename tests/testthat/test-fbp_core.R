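test_that("forward projection conserves mass and localises a point source", {
  set.seed(51)
  # band-limited random image restricted to the inscribed disc: the z range
  # spans the grid width, so mass in the corners would leave the sampled
  # band at oblique angles, and pixel-scale textures alias on oblique
  # lattices
  img <- fbpmap:::.gauss_blur(matrix(runif(29 * 29), 29, 29), 1)
  img[!interior_mask(29, margin = 2)] <- 0
  sg <- project_image(rf_image(img, 1), angles = c(0, 17, 36, 90, 133))
  for (a in seq_along(sg$angles))
    expect_equal(sum(sg$values[a, ]), sum(img), tolerance = 0.02)

  # centred single-pixel impulse.  For axis-aligned angles the sampling
  # lines coincide with the pixel lattice and the pulse is exact; oblique
  # angles spread a few percent into adjacent samples (bilinear footprint)
  pt <- matrix(0, 29, 29); pt[15, 15] <- 1
  sgp <- project_image(rf_image(pt, 1), angles = c(0, 36, 72, 90, 108, 144))
  for (a in seq_along(sgp$angles)) {
    expect_equal(which.max(sgp$values[a, ]), 15)
    expect_equal(sum(sgp$values[a, ]), 1, tolerance = 0.2)
    if (sgp$angles[a] %in% c(0, 90)) {
      expect_equal(sgp$values[a, 15], 1, tolerance = 1e-9)
      expect_equal(sum(abs(sgp$values[a, -15])), 0, tolerance = 1e-9)
    }
  }
  expect_error(project_image(rf_image(matrix(0, 0, 0), 1), 0), "square|empty")
})

test_that("five-angle projections of the model peak at the projected centre", {
  truth <- oval_model()   # centre (1, -1) in pixel units
  sg <- project_image(rf_image(truth, 1), angles = (0:4) * 36)
  for (a in 1:5) {
    phi <- sg$angles[a] * pi / 180
    z_expected <- 1 * cos(phi) + (-1) * sin(phi)
    z_hat <- sg$z[which.max(sg$values[a, ])]
    expect_lte(abs(z_hat - z_expected), 1)  # within one sample
  }
})

test_that("the reconstruction filter annihilates DC and the stop band", {
  set.seed(52)
  n <- 29
  z <- seq_len(n) - 15
  mk <- function(row) fbpmap:::new_sinogram(matrix(row, 1), 0, z, 1)
  cfg <- recon_config("ramp-hamming", cutoff = 0.6)

  # exact annihilation holds at the level of the frequency response: the
  # ramp zeroes DC and the window support ends at the cutoff
  m <- 64                              # padded length for n = 29
  nu <- c(seq(0, m / 2), seq(-(m / 2 - 1), -1)) / m
  H <- fbpmap:::.filter_response(nu, "ramp-hamming", 0.6)
  expect_identical(H[1], 0)                          # DC
  expect_true(all(H[abs(nu) > 0.6 * 0.5 + 1e-12] == 0))  # stop band

  # at row level the zero-padding (finite support) leaves only spectral
  # leakage: residuals are small fractions of the input
  row <- runif(n) + 5
  f <- filter_projections(mk(row), cfg)
  expect_lt(abs(mean(f$values)), 5e-3 * sum(abs(row)))
  row2 <- sin(2 * pi * (28 / m) * (seq_len(n) - 1))   # above the cutoff
  f2 <- filter_projections(mk(row2), cfg)
  expect_lt(max(abs(f2$values)), 0.05 * max(abs(row2)))

  # cutoff 0.6 strictly reduces high-band energy relative to full band
  wn <- rnorm(n)
  e_hi <- function(v) { sp <- Mod(fft(c(v, numeric(64 - n))))^2; sum(sp[20:45]) }
  f06 <- filter_projections(mk(wn), recon_config("ramp-hamming", 0.6))
  f10 <- filter_projections(mk(wn), recon_config("ramp-hamming", 1.0))
  expect_lt(e_hi(f06$values), e_hi(f10$values))
  short <- fbpmap:::new_sinogram(matrix(rnorm(3), 1), 0, 1:3, 1)
  expect_error(filter_projections(short, cfg), "at least 4")
})

test_that("frequency-domain filtering equals direct circular convolution", {
  set.seed(53)
  n <- 29
  row <- rnorm(n)
  s <- fbpmap:::new_sinogram(matrix(row, 1), 0, seq_len(n) - 15, 1)
  cfg <- recon_config("ramp-hamming", 0.6, pad_factor = 2)
  f <- filter_projections(s, cfg)
  # build the same kernel in the spatial domain and convolve directly
  m <- 2 * 2^ceiling(log2(n))
  nu <- c(seq(0, m / 2), seq(-(m / 2 - 1), -1)) / m
  H <- fbpmap:::.filter_response(nu, "ramp-hamming", 0.6)
  kern <- Re(stats::fft(H, inverse = TRUE)) / m
  padded <- c(row, numeric(m - n))
  direct <- vapply(seq_len(m), function(i)
    sum(padded * kern[(i - seq_len(m)) %% m + 1L]), numeric(1))
  expect_equal(f$values[1, ], direct[seq_len(n)], tolerance = 1e-8)
})

test_that("back projection geometry: rows smear along the bar direction", {
  # a single unfiltered row at angle 0 must give column-constant ridges
  n <- 15
  row <- rnorm(n)
  s <- fbpmap:::new_sinogram(matrix(row, 1), 0, seq_len(n) - 8, 1)
  img <- back_project(s, recon_config("none"))
  for (j in seq_len(n))
    expect_lt(diff(range(img$values[, j])), 1e-10)
  expect_equal(img$values[1, ], row * pi / 2, tolerance = 1e-9)

  # all-zero sinogram reconstructs to zero
  z0 <- fbpmap:::new_sinogram(matrix(0, 5, n), (0:4) * 36, seq_len(n) - 8, 1)
  expect_equal(max(abs(reconstruct(z0)$values)), 0)
})

test_that("filtered back projection of a point source matches the oracle", {
  n <- 29
  pt <- matrix(0, n, n); pt[15, 15] <- 1
  ang <- (0:35) * 5
  sg <- project_image(rf_image(pt, 1), angles = ang)
  rec <- reconstruct(sg, recon_config("ramp", cutoff = 1))
  ctr <- find_centre(rec)
  expect_equal(c(ctr$row, ctr$col), c(15, 15))
  orc <- oracle_ifbp(sg$values, ang, sg$z, 1, n)
  msk <- interior_mask(n)
  expect_lt(sqrt(mean((rec$values[msk] - orc[msk])^2)) / max(rec$values), 0.05)
})

test_that("reconstruction is a linear operator", {
  set.seed(54)
  n <- 21
  z <- seq_len(n) - 11
  ang <- (0:4) * 36
  s1 <- fbpmap:::new_sinogram(matrix(rnorm(5 * n), 5), ang, z, 1)
  s2 <- fbpmap:::new_sinogram(matrix(rnorm(5 * n), 5), ang, z, 1)
  comb <- fbpmap:::new_sinogram(2.5 * s1$values - 1.3 * s2$values, ang, z, 1)
  r <- reconstruct(comb)$values
  r12 <- 2.5 * reconstruct(s1)$values - 1.3 * reconstruct(s2)$values
  expect_equal(r, r12, tolerance = 1e-8)
})

test_that("dense-angle round trip recovers a smooth image", {
  truth <- oval_model()
  ang <- (0:59) * 3
  rec <- reconstruct(project_image(rf_image(truth, 1), angles = ang),
                     recon_config("ramp", cutoff = 1))
  expect_lt(nrmse(rec$values, truth, interior_mask(29)), 0.05)
})

test_that("rotating the object by one angle step cyclically shifts the sinogram", {
  ang <- (0:4) * 36
  base <- gaussian_rf_matrix(29, x0 = 0, y0 = 0, theta = 60)
  rot <- gaussian_rf_matrix(29, x0 = 0, y0 = 0, theta = 96)  # +36 deg
  sg_b <- project_image(rf_image(base, 1), angles = ang)
  sg_r <- project_image(rf_image(rot, 1), angles = ang)
  # row phi of the rotated object = row (phi - 36) of the base; the wrapped
  # row picks up a z flip (R(z, phi + 180) = R(-z, phi))
  shifted <- sg_b$values[c(5, 1:4), ]
  shifted[1, ] <- rev(shifted[1, ])
  expect_gt(cor(as.vector(shifted), as.vector(sg_r$values)), 0.98)
  rec_r <- reconstruct(sg_r)
  rec_shift <- reconstruct(fbpmap:::new_sinogram(shifted, ang, sg_b$z, 1))
  expect_gt(cor(as.vector(rec_r$values), as.vector(rec_shift$values)), 0.98)
})

test_that("rf_image coordinate conventions and CSV round trip", {
  m <- matrix(rnorm(49), 7, 7)
  rf <- rf_image(m, 40, "OFF")
  co <- rf_coords(rf)
  expect_equal(co$x[4], 0)
  expect_equal(co$y[1], 120)     # top row has the largest y
  f <- withr::local_tempfile(fileext = ".csv")
  write_rf_csv(rf, f)
  back <- read_rf_csv(f)
  expect_equal(back$values, m, tolerance = 1e-9)
  expect_equal(back$pixel_size, 40)
  expect_equal(back$component, "OFF")
  expect_error(rf_image(matrix(0, 2, 3), 1), "square")
})
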