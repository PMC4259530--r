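#' Locate the centre of a receptive field
#'
#' The RF centre is defined as the pixel with the maximum absolute value
#' (dark-bar protocols give negative-going OFF fields, so the sign is not
#' assumed).  Ties are broken by first occurrence in row-major order.
#'
#' @param rf an `rf_image`.
#' @return list with `row`, `col` (1-based indices), `x`, `y` (physical
#'   coordinates), `value` (signed pixel value) and `degenerate` (TRUE for
#'   an all-zero image, in which case the grid centre is returned).
#' @export
find_centre <- function(rf) {
  m <- rf$values
  n <- nrow(m)
  if (all(m == 0)) {
    i <- j <- (n + 1) %/% 2
    co <- rf_coords(rf)
    return(list(row = i, col = j, x = co$x[j], y = co$y[i], value = 0,
                degenerate = TRUE))
  }
  # row-major tie-break: scan transposed (column-major over t(m) is row-major over m)
  k <- which.max(t(abs(m)))
  i <- (k - 1) %/% n + 1
  j <- (k - 1) %% n + 1
  co <- rf_coords(rf)
  list(row = i, col = j, x = co$x[j], y = co$y[i], value = m[i, j],
       degenerate = FALSE)
}

# evaluate a rotated elliptical Gaussian surface on grids xg, yg
.gauss2d <- function(xg, yg, amp, x0, y0, sx, sy, theta, offset) {
  ct <- cos(theta); st <- sin(theta)
  u <- (xg - x0) * ct + (yg - y0) * st
  v <- -(xg - x0) * st + (yg - y0) * ct
  offset + amp * exp(-0.5 * (u^2 / sx^2 + v^2 / sy^2))
}

#' Fit a rotated 2-D Gaussian to a receptive field
#'
#' Nonlinear least squares (Levenberg-Marquardt) of an elliptical Gaussian
#' with rotation and constant offset,
#' `f(x, y) = offset + A exp(-(u^2 / 2 s_maj^2 + v^2 / 2 s_min^2))` with
#' `(u, v)` the coordinates rotated by the orientation angle.  Axis extents
#' are reported as half-widths at half-maximum amplitude,
#' `sigma * sqrt(2 ln 2)`.  Initialisation is from image moments around the
#' maximum-|value| pixel unless `init` is given.  The amplitude may be
#' negative (OFF fields).
#'
#' When the fitted field is near-isotropic (axis ratio < 1.05) the
#' orientation is flagged unidentifiable.
#'
#' @param rf an `rf_image`.
#' @param init optional named list overriding the self-computed start values
#'   (`amp`, `x0`, `y0`, `sx`, `sy`, `theta` (radians), `offset`).
#' @return an object of class `rf_gaussian_fit`: list with `centre_x`,
#'   `centre_y`, `amplitude`, `half_width_major`, `half_width_minor`,
#'   `sigma_major`, `sigma_minor`, `orientation` (degrees in `[0, 180)`,
#'   angle of the major axis from +x, counter-clockwise), `offset`,
#'   `residual_ss`, `orientation_identifiable`, and `fit` (the underlying
#'   `nls` object).
#' @export
fit_gaussian2d <- function(rf, init = NULL) {
  m <- rf$values
  n <- nrow(m)
  co <- rf_coords(rf)
  xg <- matrix(co$x, n, n, byrow = TRUE)
  yg <- matrix(co$y, n, n)
  ctr <- find_centre(rf)
  sgn <- if (ctr$value < 0) -1 else 1
  w <- sgn * (m - stats::median(m))
  w[w < 0] <- 0
  if (sum(w) <= 0) stop("image has no dominant extremum to fit")
  mx <- sum(w * xg) / sum(w); my <- sum(w * yg) / sum(w)
  vx <- sum(w * (xg - mx)^2) / sum(w)
  vy <- sum(w * (yg - my)^2) / sum(w)
  vxy <- sum(w * (xg - mx) * (yg - my)) / sum(w)
  # principal axes of the moment ellipse seed sigma and orientation
  th0 <- 0.5 * atan2(2 * vxy, vx - vy)
  ev <- sort(eigen(matrix(c(vx, vxy, vxy, vy), 2), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  smin_px <- (0.4 * rf$pixel_size)^2
  sx0 <- sqrt(max(ev[1], smin_px))
  sy0 <- sqrt(max(ev[2], smin_px))
  if (sx0 / sy0 < 1.05) {
    # an exactly isotropic seed makes the orientation gradient singular
    sx0 <- 1.1 * sx0
  }
  start <- list(amp = ctr$value - stats::median(m), x0 = ctr$x, y0 = ctr$y,
                sx = sx0, sy = sy0,
                theta = th0, offset = stats::median(m))
  if (!is.null(init)) start[names(init)] <- init
  zv <- as.vector(m); xv <- as.vector(xg); yv <- as.vector(yg)
  lo <- c(amp = -Inf, x0 = min(co$x), y0 = min(co$y),
          sx = 0.25 * rf$pixel_size / sqrt(2 * log(2)),
          sy = 0.25 * rf$pixel_size / sqrt(2 * log(2)),
          theta = -pi, offset = -Inf)
  hi <- c(amp = Inf, x0 = max(co$x), y0 = max(co$y),
          sx = n * rf$pixel_size, sy = n * rf$pixel_size,
          theta = pi, offset = Inf)
  resid_fn <- function(par)
    zv - .gauss2d(xv, yv, par[1], par[2], par[3], par[4], par[5], par[6],
                  par[7])
  order7 <- c("amp", "x0", "y0", "sx", "sy", "theta", "offset")
  run_fit <- function(st) tryCatch(
    minpack.lm::nls.lm(par = unlist(st[order7]), fn = resid_fn,
                       lower = lo[order7], upper = hi[order7],
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  fit <- run_fit(start)
  if (inherits(fit, "error") || fit$info == 0 || fit$info == 5) {
    # degenerate moment seeds (e.g. streaky reconstructions) can stall the
    # optimiser; retry from an axis-aligned, mildly anisotropic seed
    s0 <- max(start$sx, start$sy, rf$pixel_size)
    start2 <- start
    start2$theta <- 0
    start2$sx <- 1.1 * s0
    start2$sy <- 0.9 * s0
    fit2 <- run_fit(start2)
    if (!inherits(fit2, "error")) fit <- fit2
  }
  if (inherits(fit, "error"))
    stop("2-D Gaussian fit did not converge (start: ",
         paste(sprintf("%s=%.3g", names(start), unlist(start)),
               collapse = ", "), "): ", conditionMessage(fit))
  if (fit$info == 0 || fit$info == 5)
    stop("2-D Gaussian fit did not converge after ", fit$niter,
         " iterations (start: ",
         paste(sprintf("%s=%.3g", names(start), unlist(start)),
               collapse = ", "), ")")
  p <- as.list(stats::setNames(fit$par, order7))
  sx <- abs(p$sx); sy <- abs(p$sy); th <- p$theta
  if (sy > sx) { tmp <- sx; sx <- sy; sy <- tmp; th <- th + pi / 2 }
  th_deg <- (th * 180 / pi) %% 180
  hw <- sqrt(2 * log(2))
  structure(list(
    centre_x = p$x0, centre_y = p$y0, amplitude = p$amp,
    sigma_major = sx, sigma_minor = sy,
    half_width_major = hw * sx, half_width_minor = hw * sy,
    orientation = th_deg, offset = p$offset,
    residual_ss = fit$deviance,
    orientation_identifiable = (sx / sy) >= 1.05,
    fit = fit
  ), class = "rf_gaussian_fit")
}

#' @export
print.rf_gaussian_fit <- function(x, ...) {
  cat("2-D Gaussian fit\n")
  cat(sprintf("  centre (%.2f, %.2f), amplitude %.3g, offset %.3g\n",
              x$centre_x, x$centre_y, x$amplitude, x$offset))
  cat(sprintf("  half-max half-widths: major %.2f, minor %.2f; orientation %.1f deg%s\n",
              x$half_width_major, x$half_width_minor, x$orientation,
              if (!x$orientation_identifiable) " (unidentifiable: near-isotropic)" else ""))
  cat(sprintf("  residual SS %.4g\n", x$residual_ss))
  invisible(x)
}

#' @export
coef.rf_gaussian_fit <- function(object, ...) {
  c(centre_x = object$centre_x, centre_y = object$centre_y,
    amplitude = object$amplitude,
    half_width_major = object$half_width_major,
    half_width_minor = object$half_width_minor,
    orientation = object$orientation, offset = object$offset)
}

#' Signal-to-noise ratio of a reconstructed receptive field
#'
#' `snr = (signal - baseline) / noise`, where the signal is the mean pixel
#' value over the 3 x 3 window centred on the largest-|value| pixel (the RF
#' centre), the noise is the minimum standard deviation found by sliding a
#' 10 x 10 pixel window (stride 1) over all placements that do not overlap
#' the signal window, and the baseline is the mean of that same minimum-SD
#' window.  Restricting the noise window to placements outside the signal
#' region keeps the estimator well defined on small grids.
#'
#' For negative-going (OFF) fields the signed SNR is negative; `snr_abs`
#' reports its magnitude.  The estimator is invariant under affine
#' rescaling `a * values + b` (a > 0) of the image.
#'
#' @param rf an `rf_image` of side >= 13 (so a 10 x 10 window can avoid the
#'   3 x 3 signal window).
#' @param signal_half half-size of the signal window (1 gives 3 x 3).
#' @param noise_size side of the sliding noise window (default 10).
#' @return an object of class `snr_report`: list with `signal`, `baseline`,
#'   `noise`, `snr` (signed), `snr_abs`, `signal_window_centre` (row, col),
#'   `noise_window_origin` (row, col of the top-left corner).
#' @export
snr <- function(rf, signal_half = 1L, noise_size = 10L) {
  m <- rf$values
  n <- nrow(m)
  if (n < noise_size + 2 * signal_half + 1)
    stop(sprintf("image must be at least %d x %d for snr()",
                 noise_size + 2 * signal_half + 1, noise_size + 2 * signal_half + 1))
  ctr <- find_centre(rf)
  si <- max(1L, ctr$row - signal_half):min(n, ctr$row + signal_half)
  sj <- max(1L, ctr$col - signal_half):min(n, ctr$col + signal_half)
  signal <- mean(m[si, sj])
  best_sd <- Inf; best_mean <- NA_real_; best_org <- c(NA_integer_, NA_integer_)
  for (i in seq_len(n - noise_size + 1L)) {
    ii <- i:(i + noise_size - 1L)
    if (max(ii) >= min(si) && min(ii) <= max(si)) row_overlap <- TRUE else row_overlap <- FALSE
    for (j in seq_len(n - noise_size + 1L)) {
      jj <- j:(j + noise_size - 1L)
      if (row_overlap && max(jj) >= min(sj) && min(jj) <= max(sj)) next
      block <- m[ii, jj]
      s <- stats::sd(block)
      if (s < best_sd) { best_sd <- s; best_mean <- mean(block); best_org <- c(i, j) }
    }
  }
  if (!is.finite(best_sd) || best_sd == 0)
    stop("noise estimate is zero or undefined (constant region); snr undefined")
  val <- (signal - best_mean) / best_sd
  structure(list(signal = signal, baseline = best_mean, noise = best_sd,
                 snr = val, snr_abs = abs(val),
                 signal_window_centre = c(ctr$row, ctr$col),
                 noise_window_origin = best_org),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR = (signal %.3g - baseline %.3g) / noise %.3g = %.2f (|%.2f|)\n",
              x$signal, x$baseline, x$noise, x$snr, x$snr_abs))
  invisible(x)
}

#' Tabulate RF metrics for a set of reconstructions
#'
#' Builds the per-unit comparison table (centre, axes, orientation, SNR)
#' used to contrast mapping methods.
#'
#' @param rfs named list of `rf_image` objects (names = unit ids).
#' @param component component label recorded in the table.
#' @return data frame with one row per RF.
#' @export
rf_metrics_table <- function(rfs, component = "OFF") {
  rows <- lapply(names(rfs), function(id) {
    rf <- rfs[[id]]
    ctr <- find_centre(rf)
    fit <- tryCatch(fit_gaussian2d(rf), error = function(e) NULL)
    sn <- tryCatch(snr(rf), error = function(e) NULL)
    data.frame(unit_id = id, component = component,
               centre_x = ctr$x, centre_y = ctr$y, centre_value = ctr$value,
               fit_centre_x = if (is.null(fit)) NA else fit$centre_x,
               fit_centre_y = if (is.null(fit)) NA else fit$centre_y,
               half_width_major = if (is.null(fit)) NA else fit$half_width_major,
               half_width_minor = if (is.null(fit)) NA else fit$half_width_minor,
               orientation = if (is.null(fit)) NA else fit$orientation,
               snr = if (is.null(sn)) NA else sn$snr_abs)
  })
  do.call(rbind, rows)
}
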