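#' Sinogram (estimated Radon transform) of a receptive field
#'
#' Internal constructor.  `values` is an angle x position matrix of response
#' strengths R(z, phi): the line-integral projection of the receptive field
#' along bars at projection angle phi and perpendicular offset z.  `z` is
#' centred so that the middle of the position range is 0, which places the
#' rotation centre of the reconstruction at the grid centre.
#'
#' @keywords internal
new_sinogram <- function(values, angles, z, spacing, component = "total",
                         window = c(NA_real_, NA_real_), length_unit = "micrometre") {
  stopifnot(nrow(values) == length(angles), ncol(values) == length(z))
  structure(list(values = values, angles = angles, z = z, spacing = spacing,
                 component = component, window = window,
                 length_unit = length_unit),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram (%s component): %d angles x %d positions, spacing %g %s\n",
              x$component, length(x$angles), length(x$z), x$spacing,
              if (x$length_unit == "micrometre") "um" else "deg"))
  if (!anyNA(x$window))
    cat(sprintf("  response window [%g, %g) s\n", x$window[1], x$window[2]))
  invisible(x)
}

#' Collapse a spike PSTH stack into a sinogram by counting in a time window
#'
#' Sums PSTH bins inside `window` for every (angle, position), producing one
#' row of the Radon-transform estimate per projection angle.  The defaults
#' follow the convention of separating response components by latency:
#' OFF responses of dark-bar protocols are counted in `[0, 0.150)` s after
#' onset and ON responses (to bar offset) in `[0.150, 0.300)` s, which
#' allows for the roughly 50 ms delay inherent to phototransduction.
#'
#' Raw counts are used by default; optionally a spontaneous `baseline_rate`
#' (spikes/s) times window length times repeat count is subtracted from every
#' entry.  Negative values after subtraction are retained, not clipped.
#'
#' @param psth a `psth_stack` (spike modality).
#' @param window `c(start, stop)` seconds relative to onset; if the edges do
#'   not align with PSTH bin edges they are snapped outward with a warning.
#' @param component label stored on the sinogram (`"OFF"`, `"ON"`,
#'   `"total"`, ...).
#' @param baseline_rate optional spontaneous rate (spikes/s) to subtract.
#' @return a `sinogram`.
#' @export
count_window <- function(psth, window = c(0, 0.150), component = "OFF",
                         baseline_rate = NULL) {
  bw <- psth$bin_width
  if (window[1] < psth$window[1] - 1e-12 || window[2] > psth$window[2] + 1e-12)
    stop("count window lies outside the PSTH span")
  b0 <- (window[1] - psth$window[1]) / bw
  b1 <- (window[2] - psth$window[1]) / bw
  if (abs(b0 - round(b0)) > 1e-9 || abs(b1 - round(b1)) > 1e-9) {
    warning("window not aligned to PSTH bin edges; snapping outward")
    b0 <- floor(b0 + 1e-9); b1 <- ceiling(b1 - 1e-9)
  } else { b0 <- round(b0); b1 <- round(b1) }
  bins <- (b0 + 1L):b1
  vals <- apply(psth$values[, , bins, drop = FALSE], c(1, 2), sum)
  if (!is.null(baseline_rate))
    vals <- vals - baseline_rate * (window[2] - window[1]) * psth$n_repeats_averaged
  n <- dim(psth$values)[2]
  z <- ((seq_len(n) - 1L) - (n - 1) / 2) * psth$spacing
  new_sinogram(vals, psth$angles, z, psth$spacing, component, window,
               psth$length_unit)
}

#' Collapse a fluorescence PSTH stack into a sinogram by response integration
#'
#' Integrates the repeat-mean fluorescence response over `window` by the
#' trapezoidal rule (units: fluorescence x seconds).  Because slow calcium
#' indicators integrate spiking activity, the response integral is the
#' imaging analogue of the spike count and estimates the same Radon
#' transform.
#'
#' @param psth a `psth_stack` with `modality == "fluorescence"`.
#' @param window `c(start, stop)` seconds relative to onset; defaults to the
#'   full PSTH window.
#' @param component label stored on the sinogram.
#' @return a `sinogram`.
#' @export
fluorescence_integral <- function(psth, window = psth$window,
                                  component = "total") {
  if (psth$modality != "fluorescence")
    stop("fluorescence_integral expects a fluorescence psth_stack; use count_window for spikes")
  bw <- psth$bin_width
  tt <- psth$window[1] + (seq_len(dim(psth$values)[3]) - 0.5) * bw
  keep <- which(tt >= window[1] & tt < window[2])
  if (length(keep) < 2) stop("window must contain at least two frames")
  d <- dim(psth$values)
  vals <- matrix(0, d[1], d[2])
  for (a in seq_len(d[1])) for (p in seq_len(d[2])) {
    y <- psth$values[a, p, keep]
    vals[a, p] <- sum((y[-1] + y[-length(y)]) / 2) * bw
  }
  n <- d[2]
  z <- ((seq_len(n) - 1L) - (n - 1) / 2) * psth$spacing
  new_sinogram(vals, psth$angles, z, psth$spacing, component, window,
               psth$length_unit)
}

#' Orientation tuning from a sinogram
#'
#' Orientation selectivity is visible directly in the Radon transform: an
#' elongated receptive field projects to a taller, narrower profile when the
#' bar's long axis is aligned with the field's long axis.  The peak response
#' of each sinogram row (max over positions) is therefore a tuning curve
#' over bar orientations.
#'
#' Note on angle convention: the sinogram stores projection angles phi (the
#' direction bars are translated along); the long axis of a bar at
#' projection angle phi lies along `(phi + 90) mod 180`.  The tuning curve
#' and `preferred_angle` are reported on the bar-axis scale, so an
#' elliptical field with its long axis at 90 degrees has
#' `preferred_angle = 90`.
#'
#' @param s a `sinogram` with at least 2 angles.
#' @return an object of class `orientation_tuning`: list with `bar_angles`,
#'   `projection_angles`, `peak_response`, `preferred_angle`,
#'   `selectivity_index` (`(max - min)/(max + min)`, in `[0, 1]` for
#'   non-negative responses) and `degenerate` (TRUE when the sinogram is
#'   all zero, in which case the selectivity index is reported as 0).
#' @export
orientation_tuning <- function(s) {
  if (length(s$angles) < 2) stop("need at least 2 angles for orientation tuning")
  peak <- apply(s$values, 1, max)
  bar_angles <- (s$angles + 90) %% 180
  degenerate <- all(abs(s$values) < .Machine$double.eps)
  if (degenerate) {
    si <- 0
    pref <- bar_angles[1]
  } else {
    mx <- max(peak); mn <- min(peak)
    si <- if (mx + mn > 0) (mx - mn) / (mx + mn) else 0
    pref <- bar_angles[which.max(peak)]
  }
  structure(list(bar_angles = bar_angles, projection_angles = s$angles,
                 peak_response = peak, preferred_angle = pref,
                 selectivity_index = si, degenerate = degenerate),
            class = "orientation_tuning")
}

#' @export
print.orientation_tuning <- function(x, ...) {
  cat("Orientation tuning (bar long-axis angles)\n")
  cat(sprintf("  preferred angle %g deg, selectivity index %.3f%s\n",
              x$preferred_angle, x$selectivity_index,
              if (x$degenerate) " (degenerate: all-zero sinogram)" else ""))
  invisible(x)
}

#' Write and read a sinogram as CSV
#'
#' Long format: `angle_deg, position_index, z, value, component`.
#'
#' @param s a `sinogram`; `path` the file.
#' @export
write_sinogram <- function(s, path) {
  df <- expand.grid(position_index = seq_along(s$z) - 1L,
                    angle_deg = s$angles)
  df <- df[, c("angle_deg", "position_index")]
  df$z <- s$z[df$position_index + 1L]
  df$value <- unlist(lapply(seq_along(s$angles), function(a) s$values[a, ]))
  df$component <- s$component
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram
#' @param spacing,length_unit grid metadata not carried by the CSV.
#' @export
read_sinogram <- function(path, spacing = NULL, length_unit = "micrometre") {
  df <- utils::read.csv(path)
  angles <- sort(unique(df$angle_deg))
  pos <- sort(unique(df$position_index))
  vals <- matrix(0, length(angles), length(pos))
  for (i in seq_len(nrow(df)))
    vals[match(df$angle_deg[i], angles), df$position_index[i] + 1L] <- df$value[i]
  z <- df$z[match(pos, df$position_index)]
  if (is.null(spacing)) spacing <- if (length(z) > 1) stats::median(diff(sort(z))) else 1
  new_sinogram(vals, angles, sort(z), spacing, df$component[1],
               length_unit = length_unit)
}
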