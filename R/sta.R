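#' Generate a binary white-noise checkerboard movie
#'
#' Each square of the checkerboard is an independent Bernoulli(0.5) sequence
#' across frames (displayed as 0 / 256 luminance levels; stored as 0 / 1).
#' The movie is a deterministic function of the seed, so it can be stored by
#' (seed, parameters) and regenerated on demand rather than saved as pixels.
#'
#' @param n_frames number of movie frames (e.g. 60000 for a ~33 min run at
#'   30 Hz).
#' @param grid squares per side, `c(rows, cols)` or a single number.
#' @param refresh_rate display refresh rate in Hz (default 30).
#' @param seed integer seed.
#' @param block_size physical size of one square in length units (default
#'   40, matching a 40 um resolution on the retina).
#' @return an object of class `checkerboard`: list with the parameters and
#'   `values`, a `frame x row x col` binary array.
#' @export
generate_checkerboard <- function(n_frames, grid, refresh_rate = 30, seed,
                                  block_size = 40) {
  if (missing(seed)) stop("'seed' must be given")
  if (length(grid) == 1) grid <- c(grid, grid)
  set.seed(as.integer(seed))
  vals <- array(stats::rbinom(n_frames * grid[1] * grid[2], 1, 0.5),
                dim = c(n_frames, grid[1], grid[2]))
  structure(list(n_frames = as.integer(n_frames), grid = as.integer(grid),
                 refresh_rate = refresh_rate, seed = as.integer(seed),
                 block_size = block_size, values = vals),
            class = "checkerboard")
}

#' @export
print.checkerboard <- function(x, ...) {
  cat(sprintf("Checkerboard movie: %d frames of %d x %d squares at %g Hz (seed %d)\n",
              x$n_frames, x$grid[1], x$grid[2], x$refresh_rate, x$seed))
  invisible(x)
}

#' Compute the spike-triggered average stimulus
#'
#' The STA is the mean stimulus history preceding a spike: for each spike,
#' the `depth_frames` movie frames at and before the frame being displayed
#' at the spike time are collected, and all histories are averaged.  The
#' movie is recentred to zero mean (values - 0.5) before averaging so the
#' STA of stimulus-independent spiking is zero.  A spike is attributed to
#' the frame on screen at its time (`floor(t * refresh_rate)`); spikes
#' earlier than `depth_frames` frames into the movie, or after its end, are
#' dropped.
#'
#' The temporal resolution of the STA is the movie frame interval (33.3 ms
#' at 30 Hz) -- it cannot resolve structure faster than the display refresh.
#'
#' @param spike_times numeric vector of spike times in seconds.
#' @param movie a `checkerboard`.
#' @param depth_frames depth of the history stack (default 10 frames = a
#'   300 ms STA at 30 Hz).
#' @return an object of class `sta_stack`: list with `frames`
#'   (`depth x row x col` array, index 1 = spike frame, increasing lag),
#'   `frame_interval` (s), `n_spikes` (spikes used).
#' @export
compute_sta <- function(spike_times, movie, depth_frames = 10L) {
  depth_frames <- as.integer(depth_frames)
  if (depth_frames < 1) stop("depth_frames must be >= 1")
  fr_idx <- floor(as.numeric(spike_times) * movie$refresh_rate) + 1L
  usable <- fr_idx >= depth_frames & fr_idx <= movie$n_frames
  fr_idx <- fr_idx[usable]
  if (length(fr_idx) == 0) stop("no usable spikes within the movie span")
  acc <- array(0, dim = c(depth_frames, movie$grid[1], movie$grid[2]))
  # counts per frame index avoid looping over every spike
  tab <- table(fr_idx)
  idxs <- as.integer(names(tab)); wts <- as.numeric(tab)
  for (k in seq_along(idxs)) {
    hist_idx <- idxs[k] - (seq_len(depth_frames) - 1L)  # lag 0, 1, ...
    acc <- acc + wts[k] * (movie$values[hist_idx, , , drop = FALSE] - 0.5)
  }
  structure(list(frames = acc / length(fr_idx),
                 frame_interval = 1 / movie$refresh_rate,
                 n_spikes = length(fr_idx),
                 block_size = movie$block_size),
            class = "sta_stack")
}

#' @export
print.sta_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("STA stack: %d frames (%g ms interval) of %d x %d squares, %d spikes\n",
              d[1], 1000 * x$frame_interval, d[2], d[3], x$n_spikes))
  invisible(x)
}

# small separable Gaussian blur used only for STA frame selection
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m2 <- t(apply(m, 1, pad_conv))
  t(apply(t(m2), 1, pad_conv))
}

#' Extract the spatial receptive field from an STA stack
#'
#' Each frame of the stack is Gaussian-smoothed and the frame containing
#' the global maximum-|value| smoothed pixel is selected; the unsmoothed
#' values of that frame are returned as the spatial RF (smoothing is used
#' only for frame selection).  On a tie the earliest (shortest-lag) frame is
#' taken.  When the winning pixel's z-score across the whole smoothed stack
#' is below `z_threshold` the selection is flagged low-confidence (pure
#' noise stacks have no dominant frame).
#'
#' @param sta an `sta_stack`.
#' @param smoothing_width Gaussian sigma in squares (default 1).
#' @param z_threshold z-score below which the selection is flagged.
#' @return list with `rf` (an `rf_image` with `pixel_size` = block size),
#'   `frame_index` (1 = spike frame), `lag_s`, `peak_z`, `low_confidence`.
#' @export
sta_spatial_rf <- function(sta, smoothing_width = 1, z_threshold = 4) {
  d <- dim(sta$frames)
  sm <- array(0, dim = d)
  for (f in seq_len(d[1]))
    sm[f, , ] <- .gauss_blur(sta$frames[f, , ], smoothing_width)
  mu <- mean(sm); sdv <- stats::sd(as.vector(sm))
  best <- which.max(apply(abs(sm), 1, max))
  peak <- max(abs(sm[best, , ]))
  z <- if (sdv > 0) (peak - abs(mu)) / sdv else 0
  rf <- rf_image(sta$frames[best, , ], pixel_size = sta$block_size,
                 component = "STA")
  list(rf = rf, frame_index = best, lag_s = (best - 1) * sta$frame_interval,
       peak_z = z, low_confidence = z < z_threshold)
}
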