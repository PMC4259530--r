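#' Map a receptive field from flashed-bar responses
#'
#' The main entry point: runs the full estimation cascade for one unit --
#' PSTH assembly, windowed sinogram construction (one component per
#' analysis window), filtered back projection, and quantification (centre,
#' 2-D Gaussian fit, SNR) -- and returns everything as a single fitted
#' object.
#'
#' For spike inputs the default windows separate the OFF component
#' (`[0, 0.150)` s after the onset of a dark bar) from the ON component
#' (`[0.150, 0.300)` s, following bar offset).  For fluorescence inputs the
#' response integral over the full window is used (a single `"total"`
#' component) unless windows are given.
#'
#' @param x spike times (numeric vector, seconds) or a `roi_trace_set`.
#' @param protocol the `stim_protocol` that was presented.
#' @param windows named list of analysis windows (`c(start, stop)` in
#'   seconds); names become component labels.
#' @param config a [recon_config()].
#' @param bin_width native PSTH bin width, seconds (spike inputs).
#' @param temporal_bin bin width of the spatiotemporal stack, seconds
#'   (default 8 ms, i.e. 125 Hz; must be a multiple of `bin_width`).
#' @param psth_window overall PSTH span, seconds.
#' @param roi ROI id (fluorescence inputs).
#' @param baseline_window pre-onset baseline interval (fluorescence).
#' @param temporal also compute the spatiotemporal stack and the centre
#'   impulse response.
#' @return an object of class `fbp_rf`: list with `psth`, `sinograms`,
#'   `images` (one `rf_image` per component), `centres`, `fits`
#'   (2-D Gaussian fits or NULL where the fit failed), `snr` reports,
#'   `temporal` (an `st_rf` or NULL), `impulse` (an `impulse_response` or
#'   NULL), `protocol`, `config`.
#' @examples
#' p <- generate_protocol(seed = 1)
#' nrn <- calibrate_gain(make_model_rf("gaussian"), p)
#' sp <- simulate_spikes(nrn, p, seed = 2)
#' fit <- fbp_rf(sp, p)
#' fit
#' coef(fit)
#' @export
fbp_rf <- function(x, protocol,
                   windows = NULL,
                   config = recon_config(),
                   bin_width = 0.002, temporal_bin = 0.008,
                   psth_window = c(0, 0.3),
                   roi = NULL, baseline_window = c(-0.5, 0),
                   temporal = FALSE) {
  if (inherits(x, "roi_trace_set")) {
    if (is.null(roi)) roi <- x$roi_ids[1]
    psth <- build_fluorescence_psth(x, roi, protocol,
                                    window = c(0, protocol$duty_cycle),
                                    baseline_window = baseline_window)
    if (is.null(windows)) windows <- list(total = psth$window)
    sinos <- lapply(names(windows), function(nm)
      fluorescence_integral(psth, windows[[nm]], component = nm))
  } else {
    psth <- build_psth(x, protocol, bin_width = bin_width,
                       window = psth_window)
    if (is.null(windows)) windows <- list(OFF = c(0, 0.150), ON = c(0.150, 0.300))
    sinos <- lapply(names(windows), function(nm)
      count_window(psth, windows[[nm]], component = nm))
  }
  names(sinos) <- names(windows)
  images <- lapply(sinos, reconstruct, cfg = config)
  centres <- lapply(images, find_centre)
  fits <- lapply(images, function(im)
    tryCatch(fit_gaussian2d(im), error = function(e) NULL))
  snrs <- lapply(images, function(im)
    tryCatch(snr(im), error = function(e) NULL))
  st <- ir <- NULL
  if (temporal) {
    st <- temporal_stack(psth, config, bin_width = temporal_bin)
    ctr <- centres[[1]]
    st_step <- step_response(st, cbind(ctr$row, ctr$col))
    ir <- impulse_response(st_step, stimulus_contrast = protocol$contrast)
  }
  structure(list(psth = psth, sinograms = sinos, images = images,
                 centres = centres, fits = fits, snr = snrs,
                 temporal = st, impulse = ir,
                 protocol = protocol, config = config),
            class = "fbp_rf")
}

#' @export
print.fbp_rf <- function(x, ...) {
  cat("Receptive field mapped by filtered back projection\n")
  cat(sprintf("  %d angles x %d positions, %s modality\n",
              length(x$protocol$angles), x$protocol$n_positions,
              x$psth$modality))
  unit <- if (x$protocol$length_unit == "micrometre") "um" else "deg"
  for (nm in names(x$images)) {
    ctr <- x$centres[[nm]]
    sn <- x$snr[[nm]]
    cat(sprintf("  %s: centre (%g, %g) %s%s\n", nm, ctr$x, ctr$y, unit,
                if (!is.null(sn)) sprintf(", |SNR| %.1f", sn$snr_abs) else ""))
  }
  invisible(x)
}

#' @export
summary.fbp_rf <- function(object, ...) {
  unit <- if (object$protocol$length_unit == "micrometre") "um" else "deg"
  print(object)
  for (nm in names(object$fits)) {
    f <- object$fits[[nm]]
    if (is.null(f)) { cat(sprintf("  %s: Gaussian fit failed\n", nm)); next }
    cat(sprintf("  %s fit: centre (%.1f, %.1f) %s, half-widths %.1f / %.1f %s, orientation %.0f deg\n",
                nm, f$centre_x, f$centre_y, unit,
                f$half_width_major, f$half_width_minor, unit, f$orientation))
  }
  invisible(object)
}

#' @export
coef.fbp_rf <- function(object, ...) {
  rows <- lapply(names(object$fits), function(nm) {
    f <- object$fits[[nm]]
    if (is.null(f)) return(NULL)
    cbind(component = nm, as.data.frame(as.list(coef(f))))
  })
  do.call(rbind, rows)
}

#' @export
plot.fbp_rf <- function(x, component = 1L, ...) {
  im <- x$images[[component]]
  plot(im, ...)
  f <- x$fits[[component]]
  if (!is.null(f)) {
    th <- seq(0, 2 * pi, length.out = 120)
    a <- f$half_width_major; b <- f$half_width_minor
    rot <- f$orientation * pi / 180
    ex <- f$centre_x + a * cos(th) * cos(rot) - b * sin(th) * sin(rot)
    ey <- f$centre_y + a * cos(th) * sin(rot) + b * sin(th) * cos(rot)
    graphics::lines(ex, ey, col = "red", lwd = 2)
  }
  invisible(x)
}
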