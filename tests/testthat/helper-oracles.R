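# Independent oracles used throughout the suite.  These deliberately share
# no code with the package: the forward projector integrates on a rotated
# dense sub-grid, the inverse-Radon oracle filters by direct spatial-domain
# convolution with the classic discrete ramp kernel and back-projects with
# linear interpolation.

# dense forward projection: sample the image on a 4x-refined grid and
# accumulate sums into z bins by nearest-bin assignment
oracle_project <- function(img, angles_deg, z, spacing) {
  n <- nrow(img)
  f <- 4L
  idx <- (seq_len(n * f) - 0.5) / f - 0.5   # sub-pixel centres, pixel units
  xs <- idx - (n - 1) / 2
  ys <- rev(xs)
  sub <- img[rep(seq_len(n), each = f), rep(seq_len(n), each = f)] / f^2
  out <- matrix(0, length(angles_deg), length(z))
  zb <- c(z - spacing / 2, max(z) + spacing / 2)
  for (a in seq_along(angles_deg)) {
    phi <- angles_deg[a] * pi / 180
    zz <- outer(ys * sin(phi), xs * cos(phi), "+") * spacing
    bin <- findInterval(as.vector(zz), zb)
    ok <- bin >= 1 & bin <= length(z)
    out[a, ] <- as.vector(tapply(as.vector(sub)[ok],
                                 factor(bin[ok], levels = seq_along(z)),
                                 sum, default = 0))
  }
  out[is.na(out)] <- 0
  out
}

# discrete ramp (Ram-Lak) kernel: DTFT is |nu| for |nu| <= 1/2
ramlak_kernel <- function(half_len) {
  k <- -half_len:half_len
  h <- numeric(length(k))
  h[k == 0] <- 0.25
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd])^2
  h
}

# independent filtered back projection: spatial-domain ramp convolution +
# linear interpolation; same geometry conventions as the package
oracle_ifbp <- function(sino_vals, angles_deg, z, spacing, n_out) {
  h <- ramlak_kernel(ncol(sino_vals))
  filt <- t(apply(sino_vals, 1, function(row) {
    full <- stats::convolve(row, rev(h), type = "open")
    full[(length(h) - 1) / 2 + seq_along(row)]
  }))
  idx <- seq_len(n_out) - 1
  x <- (idx - (n_out - 1) / 2) * spacing
  y <- ((n_out - 1) / 2 - idx) * spacing
  xg <- matrix(x, n_out, n_out, byrow = TRUE)
  yg <- matrix(y, n_out, n_out)
  acc <- matrix(0, n_out, n_out)
  for (a in seq_along(angles_deg)) {
    phi <- angles_deg[a] * pi / 180
    zq <- xg * cos(phi) + yg * sin(phi)
    v <- stats::approx(z, filt[a, ], xout = as.vector(zq), rule = 1)$y
    v[is.na(v)] <- 0
    acc <- acc + matrix(v, n_out, n_out)
  }
  acc * pi / length(angles_deg)
}

# interior mask: pixels within the inscribed circle minus a margin
interior_mask <- function(n, margin = 2) {
  idx <- seq_len(n) - (n + 1) / 2
  outer(idx, idx, function(a, b) sqrt(a^2 + b^2)) <= (n - 1) / 2 - margin
}

nrmse <- function(est, ref, mask = TRUE) {
  sqrt(mean((est[mask] - ref[mask])^2)) / (max(ref) - min(ref))
}

# canonical oval test model (29 x 29): 2:1 ellipse, oblique, slightly
# off-centre
oval_model <- function() gaussian_rf_matrix(29)

oval_truth_params <- function() {
  hw <- sqrt(2 * log(2))
  list(x0 = 1, y0 = -1, hw_major = 4.5 * hw, hw_minor = 2.25 * hw,
       theta = 60, ratio = 2)
}

# standard MEA-style protocol and a calibrated default OFF cell, reused by
# several test files
default_protocol <- function(seed = 1, n_repeats = 3L)
  generate_protocol(n_angles = 5, n_positions = 29, bar_width = 80,
                    position_spacing = 40, flash_duration = 0.1,
                    duty_cycle = 0.5, n_repeats = n_repeats, contrast = -1,
                    seed = seed)

default_off_cell <- function(protocol, centre = c(80, -40))
  calibrate_gain(make_model_rf("gaussian", centre = centre), protocol)
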