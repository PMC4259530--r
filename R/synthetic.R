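#' Evaluate a rotated 2-D Gaussian on a square pixel grid
#'
#' Utility for building model receptive-field maps.  Coordinates follow the
#' `rf_image` convention: the grid centre is `(0, 0)`, `x` increases with
#' column, `y` decreases with row.  The defaults give the package's
#' canonical oval test object on a 29 x 29 grid: a 2:1 ellipse slightly off
#' centre, oriented obliquely so that its axes coincide with neither the
#' pixel axes nor any projection direction of the standard five-angle set.
#'
#' @param n grid side in pixels.
#' @param pixel_size pixel pitch in physical units (default 1: pixel units).
#' @param x0,y0 centre in the same units.
#' @param sigma_major,sigma_minor Gaussian sigmas along the major/minor axes.
#' @param theta orientation of the major axis, degrees counter-clockwise
#'   from +x.
#' @param amplitude peak value (may be negative).
#' @return an `n x n` matrix.
#' @export
gaussian_rf_matrix <- function(n, pixel_size = 1, x0 = 1, y0 = -1,
                               sigma_major = 4.5, sigma_minor = 2.25,
                               theta = 60, amplitude = 1) {
  idx <- seq_len(n) - 1
  x <- (idx - (n - 1) / 2) * pixel_size
  y <- ((n - 1) / 2 - idx) * pixel_size
  xg <- matrix(x, n, n, byrow = TRUE)
  yg <- matrix(y, n, n)
  .gauss2d(xg, yg, amplitude, x0, y0, sigma_major, sigma_minor,
           theta * pi / 180, 0)
}

#' Biphasic temporal kernel (difference of gamma functions)
#'
#' `h(t) = (t/tau1)^n exp(n - t/tau1) - w (t/tau2)^n exp(n - t/tau2)`,
#' sampled at `dt` over `[0, t_max]` and normalised so that its running
#' integral peaks at 1 (which makes a neuron's `gain` the peak rate
#' excursion per unit stimulus drive for a sustained step).  With the
#' defaults the kernel peaks near 50 ms and has decayed by ~120 ms, so that
#' with a ~30 ms response latency the OFF response to a 100 ms flash is
#' complete within 150 ms of onset, matching typical retinal flash
#' responses; it integrates to a small value so step responses are
#' transient.
#'
#' @param tau1,tau2 time constants (s) of the positive and negative lobes.
#' @param n_shape gamma shape exponent.
#' @param w weight of the negative lobe (0 = monophasic).
#' @param t_max kernel support (s); `dt` sample interval (s).
#' @return list with `t`, `v` (kernel samples, 1/s), `H` (running integral,
#'   dimensionless), and `dt`.
#' @export
biphasic_kernel <- function(tau1 = 0.010, tau2 = 0.013, n_shape = 5,
                            w = 0.8, t_max = 0.4, dt = 0.001) {
  t <- seq(0, t_max, by = dt)
  g <- function(tau) (t / (n_shape * tau))^n_shape * exp(n_shape - t / tau)
  v <- g(tau1) - w * g(tau2)
  H <- cumsum(v) * dt
  pk <- max(H)
  list(t = t, v = v / pk, H = H / pk, dt = dt)
}

#' Construct a model linear-nonlinear neuron
#'
#' Builds the ground-truth neurons used to validate the mapping pipeline.
#' A neuron is a set of components, each with a signed spatial map (2-D
#' Gaussian weights on the reconstruction grid), a biphasic temporal
#' kernel, a response latency and a gain; plus a baseline firing rate and a
#' rectifying output nonlinearity.  OFF components are driven by luminance
#' decrements (the onset of a dark bar), ON components by increments (its
#' offset).
#'
#' Kinds:
#' * `"gaussian"`: a single OFF component with an elliptical Gaussian map --
#'   the typical dark-bar-mapped retinal ganglion cell.
#' * `"on_off_concentric"`: a small central OFF component plus a larger
#'   concentric ON component with its own latency, emulating overlapping
#'   ON/OFF receptive fields.
#' * `"oriented"`: a strongly elongated OFF component (axis ratio >= 2),
#'   emulating an orientation-selective cell.
#'
#' @param kind model type, see above.
#' @param grid map side in pixels; `spacing` pixel pitch (length units).
#' @param centre RF centre `c(x, y)` in length units.
#' @param sigma_major,sigma_minor Gaussian sigmas (length units) of the
#'   (main) component.
#' @param theta orientation of the major axis, degrees.
#' @param baseline_rate spontaneous rate, spikes/s.
#' @param gain peak-rate excursion (spikes/s) per unit stimulus drive; see
#'   [calibrate_gain()] for setting it against a protocol.
#' @param latency response latency of the OFF component, seconds.
#' @param on_latency latency of the ON component
#'   (`"on_off_concentric"` only).
#' @param on_sigma sigma (length units) of the concentric ON component.
#' @param on_gain gain of the ON component.
#' @param kernel,on_kernel temporal kernels as returned by
#'   [biphasic_kernel()].
#' @param nonlinearity `"rectify"` (half-wave) or `"rectify-power"`.
#' @param power exponent for `"rectify-power"`.
#' @param length_unit `"micrometre"` or `"degree"`.
#' @return an object of class `ln_neuron`.
#' @export
make_model_rf <- function(kind = c("gaussian", "on_off_concentric", "oriented"),
                          grid = 29L, spacing = 40, centre = c(0, 0),
                          sigma_major = 180, sigma_minor = 120, theta = 20,
                          baseline_rate = 2, gain = 5, latency = 0.03,
                          on_latency = 0.05, on_sigma = 180, on_gain = 5,
                          kernel = biphasic_kernel(),
                          on_kernel = biphasic_kernel(),
                          nonlinearity = c("rectify", "rectify-power"),
                          power = 1,
                          length_unit = c("micrometre", "degree")) {
  kind <- match.arg(kind)
  nonlinearity <- match.arg(nonlinearity)
  length_unit <- match.arg(length_unit)
  grid <- as.integer(grid)
  mk <- function(smaj, smin, th)
    gaussian_rf_matrix(grid, spacing, centre[1], centre[2], smaj, smin, th, 1)
  comps <- switch(kind,
    gaussian = list(list(label = "OFF",
                         map = mk(sigma_major, sigma_minor, theta),
                         kernel = kernel, latency = latency, gain = gain)),
    oriented = {
      if (sigma_major / sigma_minor < 2) {
        sigma_major <- 2 * sigma_minor   # enforce the defining elongation
      }
      list(list(label = "OFF", map = mk(sigma_major, sigma_minor, theta),
                kernel = kernel, latency = latency, gain = gain))
    },
    on_off_concentric = list(
      list(label = "OFF", map = mk(min(sigma_major, sigma_minor) * 0.75,
                                   min(sigma_major, sigma_minor) * 0.75, 0),
           kernel = kernel, latency = latency, gain = gain),
      list(label = "ON", map = mk(on_sigma, on_sigma, 0),
           kernel = on_kernel, latency = on_latency, gain = on_gain)))
  structure(list(kind = kind, components = comps, baseline_rate = baseline_rate,
                 nonlinearity = nonlinearity, power = power,
                 grid = grid, spacing = spacing, centre = centre,
                 sigma_major = sigma_major, sigma_minor = sigma_minor,
                 theta = theta, length_unit = length_unit),
            class = "ln_neuron")
}

#' @export
print.ln_neuron <- function(x, ...) {
  cat(sprintf("LN model neuron ('%s'): %d component(s) on a %d x %d grid (%g per px)\n",
              x$kind, length(x$components), x$grid, x$grid, x$spacing))
  for (cp in x$components)
    cat(sprintf("  %s: gain %.3g, latency %g ms\n", cp$label, cp$gain,
                1000 * cp$latency))
  cat(sprintf("  baseline %g Hz, nonlinearity %s\n", x$baseline_rate,
              x$nonlinearity))
  invisible(x)
}

# Weighted overlap of a spatial map with every bar of a protocol.
# Bars are rasterised with 8 x 8 sub-pixel sampling: each map pixel
# contributes its value times the fraction of its area covered by the band
# |x cos(phi) + y sin(phi) - z_p| <= bar_width / 2.
# Returns an n_angles x n_positions matrix.
.bar_overlaps <- function(map, pixel_size, angles, z, bar_width, super = 8L) {
  n <- nrow(map)
  ns <- n * super
  # sub-pixel centre coordinates on the refined grid
  idx_s <- seq_len(ns) - 1
  xs <- (idx_s - (ns - 1) / 2) * pixel_size / super
  ys <- rev(xs)                       # y decreases with row
  # aggregation: A %*% ind %*% t(A) sums sub-pixels per coarse pixel
  A <- matrix(0, n, ns)
  A[cbind(rep(seq_len(n), each = super), seq_len(ns))] <- 1
  out <- matrix(0, length(angles), length(z))
  for (a in seq_along(angles)) {
    phi <- angles[a] * pi / 180
    zsub <- outer(ys * sin(phi), xs * cos(phi), "+")   # ns x ns
    for (k in seq_along(z)) {
      ind <- (zsub >= z[k] - bar_width / 2) & (zsub <= z[k] + bar_width / 2)
      cov <- A %*% ind %*% t(A) / super^2
      out[a, k] <- sum(map * cov)
    }
  }
  out
}

# Fine-grained expected-rate trace for a bar protocol.
# Returns list(t, rate, drive) on a dt grid covering [0, duration].
.rate_grid_bars <- function(neuron, protocol, dt = 0.001, duration = NULL) {
  fl <- protocol$flashes
  if (is.null(duration))
    duration <- max(fl$onset_s) + protocol$duty_cycle + 0.5
  nt <- ceiling(duration / dt) + 1L
  tt <- (seq_len(nt) - 1L) * dt
  drive <- numeric(nt)
  z <- protocol_z(protocol)
  for (cp in neuron$components) {
    ov <- .bar_overlaps(cp$map, neuron$spacing, protocol$angles, z,
                        protocol$bar_width)
    pol <- if (cp$label == "OFF") -1 else 1
    Hk <- cp$kernel$H; kd <- cp$kernel$dt; nk <- length(Hk)
    a_idx <- match(fl$angle_deg, protocol$angles)
    D_steps <- round(fl$duration_s / dt)
    for (i in seq_len(nrow(fl))) {
      o <- ov[a_idx[i], fl$position_index[i] + 1L]
      amp <- cp$gain * o * pol * fl$contrast[i]
      if (abs(amp) < 1e-12) next
      i0 <- round((fl$onset_s[i] + cp$latency) / dt) + 1L
      # step response H(tau) - H(tau - D) on the fine grid
      len <- min(nk + D_steps[i], nt - i0 + 1L)
      if (len <= 0) next
      tau_idx <- seq_len(len)
      Hr <- function(ix) { v <- numeric(length(ix))
        ok <- ix >= 1 & ix <= nk; v[ok] <- Hk[ix[ok]]
        v[ix > nk] <- Hk[nk]; v }
      resp <- Hr(tau_idx) - Hr(tau_idx - D_steps[i])
      drive[i0:(i0 + len - 1L)] <- drive[i0:(i0 + len - 1L)] + amp * resp
    }
  }
  rate <- .apply_nonlin(neuron, drive)
  list(t = tt, rate = rate, drive = drive)
}

.apply_nonlin <- function(neuron, drive) {
  x <- neuron$baseline_rate + drive
  switch(neuron$nonlinearity,
         "rectify" = pmax(0, x),
         "rectify-power" = pmax(0, x)^neuron$power)
}

# Fine-grained expected-rate trace for a checkerboard movie.  The movie
# grid is assumed congruent with the neuron's map grid (same size and
# physical pitch).  The effective stimulus for a component is the
# map-weighted sum of the frame contrasts (+/-1), signed by polarity, and
# the drive is its convolution with the temporal kernel.
.rate_grid_checkerboard <- function(neuron, movie, dt = 0.001, duration = NULL) {
  if (is.null(duration)) duration <- movie$n_frames / movie$refresh_rate
  nt <- ceiling(duration / dt) + 1L
  tt <- (seq_len(nt) - 1L) * dt
  fr_of_t <- pmin(floor(tt * movie$refresh_rate) + 1L, movie$n_frames)
  drive <- numeric(nt)
  nfr <- max(fr_of_t)
  for (cp in neuron$components) {
    if (!all(dim(cp$map) == movie$grid))
      stop("checkerboard grid must match the neuron's map grid")
    pol <- if (cp$label == "OFF") -1 else 1
    u <- vapply(seq_len(nfr), function(f)
      sum(cp$map * (2 * movie$values[f, , ] - 1)), numeric(1)) * pol
    s_fine <- u[fr_of_t]
    k <- cp$kernel$v * cp$kernel$dt       # discrete-convolution weights
    lat_steps <- round(cp$latency / dt)
    g <- stats::convolve(c(rep(0, lat_steps), s_fine), rev(k), type = "open")
    drive <- drive + cp$gain * g[seq_len(nt)]
  }
  rate <- .apply_nonlin(neuron, drive)
  list(t = tt, rate = rate, drive = drive)
}

#' Expected firing rate of a model neuron under a stimulus
#'
#' Deterministic, noise-free rate of the linear-nonlinear cascade:
#' each component's spatial map is overlapped with the stimulus (bar
#' footprints by 8 x 8 super-sampled rasterisation; checkerboard squares by
#' map-weighted sums), the resulting drive is passed through the temporal
#' kernel at the component's latency, summed over components onto the
#' baseline rate, and rectified.  This is the analytic oracle against which
#' sampled spike trains and the reconstruction pipeline are validated.
#'
#' @param neuron an `ln_neuron`.
#' @param stimulus a `stim_protocol` or a `checkerboard`.
#' @param t times (s) at which to evaluate, or `NULL` for the full fine
#'   grid.
#' @param dt internal evaluation step (s).
#' @return if `t` is given, a vector of rates (spikes/s) at `t`; otherwise
#'   a list with `t` and `rate` covering the stimulus duration.
#' @export
expected_rate <- function(neuron, stimulus, t = NULL, dt = 0.001) {
  g <- if (inherits(stimulus, "stim_protocol"))
    .rate_grid_bars(neuron, stimulus, dt)
  else if (inherits(stimulus, "checkerboard"))
    .rate_grid_checkerboard(neuron, stimulus, dt)
  else stop("stimulus must be a stim_protocol or a checkerboard")
  if (is.null(t)) return(g[c("t", "rate")])
  stats::approx(g$t, g$rate, xout = t, rule = 2)$y
}

#' Set a neuron's gain to reach a target peak firing rate
#'
#' Scales component gains so that the neuron's maximum expected rate under
#' the given protocol equals `peak_rate`.  This decouples the
#' physiologically meaningful quantity (peak evoked rate, spikes/s) from
#' the stimulus geometry that determines raw overlap values.
#'
#' With `balance = TRUE` (the default) each component is first rescaled so
#' all components reach the same peak drive: for mixed ON-OFF cells this
#' gives OFF and ON bursts of comparable amplitude, as observed in real
#' ON-OFF ganglion cells, rather than letting the spatially larger
#' component dominate.
#'
#' @param neuron an `ln_neuron`; `protocol` a `stim_protocol`.
#' @param peak_rate target maximum rate, spikes/s (default 150: a
#'   robust transient burst for a retinal ganglion cell).
#' @param balance equalise per-component peak drives before the overall
#'   scaling.
#' @return the neuron with rescaled gains.
#' @export
calibrate_gain <- function(neuron, protocol, peak_rate = 150, balance = TRUE) {
  if (balance && length(neuron$components) > 1) {
    for (k in seq_along(neuron$components)) {
      solo <- neuron
      for (j in seq_along(solo$components))
        if (j != k) solo$components[[j]]$gain <- 0
      mx <- max(.rate_grid_bars(solo, protocol, dt = 0.001)$drive)
      if (mx > 0)
        neuron$components[[k]]$gain <- neuron$components[[k]]$gain / mx
    }
  }
  g <- .rate_grid_bars(neuron, protocol, dt = 0.001)
  mx <- max(g$drive)
  if (mx <= 0) stop("neuron produces no positive drive under this protocol")
  sc <- (peak_rate - neuron$baseline_rate) / mx
  for (k in seq_along(neuron$components))
    neuron$components[[k]]$gain <- neuron$components[[k]]$gain * sc
  neuron
}

#' Sample a spike train from a model neuron (inhomogeneous Poisson)
#'
#' Thinning: candidate events are drawn from a homogeneous Poisson process
#' at the peak rate and accepted with probability `rate(t) / rate_max`.
#' Fully reproducible given the seed.
#'
#' @param neuron an `ln_neuron`; `stimulus` a `stim_protocol` or
#'   `checkerboard`.
#' @param duration recording length (s); default the stimulus duration.
#' @param seed integer seed.
#' @param dt internal rate-grid step (s).
#' @return sorted numeric vector of spike times (s).
#' @export
simulate_spikes <- function(neuron, stimulus, duration = NULL, seed,
                            dt = 0.001) {
  if (missing(seed)) stop("'seed' must be given")
  g <- if (inherits(stimulus, "stim_protocol"))
    .rate_grid_bars(neuron, stimulus, dt, duration)
  else if (inherits(stimulus, "checkerboard"))
    .rate_grid_checkerboard(neuron, stimulus, dt, duration)
  else if (is.null(stimulus))
    list(t = c(0, duration), rate = rep(neuron$baseline_rate, 2))
  else stop("stimulus must be a stim_protocol, a checkerboard, or NULL")
  if (is.null(duration)) duration <- max(g$t)
  rmax <- max(g$rate)
  if (rmax > 1e4) stop("rate exceeds 10 kHz; check gain calibration")
  if (rmax <= 0) return(numeric(0))
  set.seed(as.integer(seed))
  n_cand <- stats::rpois(1, rmax * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  r_at <- stats::approx(g$t, g$rate, xout = cand, rule = 2)$y
  keep <- stats::runif(n_cand) < r_at / rmax
  cand[keep]
}

#' Calcium-indicator response model
#'
#' Double-exponential kernel `(1 - exp(-t/rise)) * exp(-t/decay)`,
#' normalised to peak 1, emulating a GCaMP-class indicator.
#'
#' @param rise,decay rise and decay time constants (s); `decay > rise > 0`.
#' @param amplitude fluorescence change per spike (arbitrary units).
#' @param noise_sd additive Gaussian noise SD per frame.
#' @param frame_rate acquisition rate, Hz (default 10, a typical two-photon
#'   frame scan).
#' @return an object of class `calcium_model`.
#' @export
calcium_model <- function(rise = 0.05, decay = 0.4, amplitude = 1,
                          noise_sd = 0.05, frame_rate = 10) {
  if (!(decay > rise && rise > 0)) stop("need decay > rise > 0")
  structure(list(rise = rise, decay = decay, amplitude = amplitude,
                 noise_sd = noise_sd, frame_rate = frame_rate),
            class = "calcium_model")
}

#' Simulate ROI fluorescence traces from model neurons
#'
#' Each neuron's activity (sampled spikes by default, or the noise-free
#' expected rate when `rate_based = TRUE` -- appropriate for non-spiking
#' compartments such as bipolar-cell terminals) is convolved with the
#' calcium kernel, sampled at the imaging frame rate, and corrupted with
#' additive Gaussian noise.
#'
#' @param neurons an `ln_neuron` or list of them (one ROI each).
#' @param stimulus a `stim_protocol`.
#' @param cal a [calcium_model()].
#' @param duration recording length (s); default the stimulus duration.
#' @param seed integer seed.
#' @param rate_based convolve the expected rate instead of sampled spikes.
#' @return a `roi_trace_set` (ROI ids `"roi1"`, `"roi2"`, ...).
#' @export
simulate_calcium <- function(neurons, stimulus, cal = calcium_model(),
                             duration = NULL, seed, rate_based = FALSE) {
  if (missing(seed)) stop("'seed' must be given")
  if (inherits(neurons, "ln_neuron")) neurons <- list(neurons)
  if (is.null(duration))
    duration <- max(stimulus$flashes$onset_s) + stimulus$duty_cycle + 0.5
  dt <- 0.001
  nt <- ceiling(duration / dt) + 1L
  kt <- seq(0, cal$decay * 6, by = dt)
  ker <- (1 - exp(-kt / cal$rise)) * exp(-kt / cal$decay)
  ker <- ker / max(ker)
  n_frames <- floor(duration * cal$frame_rate)
  f_idx <- round(((seq_len(n_frames) - 0.5) / cal$frame_rate) / dt) + 1L
  traces <- matrix(0, length(neurons), n_frames)
  for (k in seq_along(neurons)) {
    if (rate_based) {
      g <- .rate_grid_bars(neurons[[k]], stimulus, dt, duration)
      act <- g$rate * dt
    } else {
      sp <- simulate_spikes(neurons[[k]], stimulus, duration,
                            seed = as.integer(seed) + k - 1L, dt = dt)
      act <- numeric(nt)
      if (length(sp)) {
        bi <- pmin(floor(sp / dt) + 1L, nt)
        act <- tabulate(bi, nbins = nt)
      }
    }
    tr <- stats::convolve(c(act, numeric(length(ker))), rev(ker),
                          type = "open")[seq_len(nt)]
    traces[k, ] <- cal$amplitude * tr[f_idx]
  }
  set.seed(as.integer(seed) + 7777L)
  traces <- traces + matrix(stats::rnorm(length(traces), 0, cal$noise_sd),
                            nrow(traces), ncol(traces))
  structure(list(roi_ids = paste0("roi", seq_along(neurons)),
                 frame_rate = cal$frame_rate, traces = traces),
            class = "roi_trace_set")
}

#' Ground-truth spatial map of a model neuron as an `rf_image`
#'
#' @param neuron an `ln_neuron`; `component` index or label.
#' @export
neuron_map <- function(neuron, component = 1L) {
  if (is.character(component))
    component <- match(component, vapply(neuron$components, `[[`, "", "label"))
  cp <- neuron$components[[component]]
  rf_image(cp$map, neuron$spacing, cp$label, neuron$length_unit)
}
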