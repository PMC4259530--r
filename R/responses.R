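#' Peri-stimulus time histogram stack
#'
#' Internal constructor for the `psth_stack` class: an
#' angle x position x time-bin array of responses aligned to flash onset,
#' aggregated over repeats.  For spikes the values are summed counts across
#' repeats (with `n_repeats_averaged` stored so rates can be recovered);
#' for fluorescence they are repeat-mean, baseline-subtracted responses.
#'
#' @keywords internal
new_psth_stack <- function(values, bin_width, window, n_repeats_averaged,
                           modality, angles, spacing, length_unit) {
  structure(list(values = values, bin_width = bin_width, window = window,
                 n_repeats_averaged = n_repeats_averaged, modality = modality,
                 angles = angles, spacing = spacing, length_unit = length_unit),
            class = "psth_stack")
}

#' @export
print.psth_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("PSTH stack (%s): %d angles x %d positions x %d bins of %g ms\n",
              x$modality, d[1], d[2], d[3], 1000 * x$bin_width))
  cat(sprintf("  window [%g, %g) s relative to flash onset, %d repeats aggregated\n",
              x$window[1], x$window[2], x$n_repeats_averaged))
  invisible(x)
}

#' Build a PSTH stack from sorted spike times
#'
#' Parses and deshuffles a spike train against the stimulus log: for each
#' (angle, position) pair, spikes falling in `[onset + window[1],
#' onset + window[2])` around every repeat of that flash are binned at
#' `bin_width` and summed across repeats.  Because spikes are assigned by
#' flash identity rather than presentation order, the output is invariant to
#' the pseudo-random ordering of the protocol.
#'
#' @param spike_times numeric vector of spike times in seconds (one sorted
#'   unit), or a data frame with a `time_s` column as returned by
#'   [read_spikes()].
#' @param protocol the `stim_protocol` that was presented.
#' @param bin_width PSTH bin width in seconds.  The default 2 ms divides
#'   both the 150 ms component windows and the 8 ms temporal-analysis bins,
#'   so all downstream windowing falls on bin edges.
#' @param window analysis window `c(start, stop)` in seconds relative to
#'   flash onset; must start at >= 0 and be an integer number of bins.  The
#'   default `[0, 0.3)` covers both the OFF (0--150 ms) and ON (150--300 ms)
#'   response components.
#'
#' @return a `psth_stack` with `modality = "spikes"`; values are summed
#'   spike counts per bin.
#' @examples
#' p <- generate_protocol(seed = 1)
#' nrn <- make_model_rf("gaussian", grid = 29, spacing = 40)
#' sp <- simulate_spikes(nrn, p, seed = 2)
#' psth <- build_psth(sp, p)
#' psth
#' @export
build_psth <- function(spike_times, protocol, bin_width = 0.002,
                       window = c(0, 0.3)) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$time_s
  spike_times <- sort(as.numeric(spike_times))
  if (window[1] < 0) stop("window must start at or after flash onset")
  wlen <- window[2] - window[1]
  n_bins <- round(wlen / bin_width)
  if (abs(n_bins * bin_width - wlen) > 1e-9)
    stop("bin_width must divide the window length")
  fl <- protocol$flashes
  angles <- protocol$angles
  n_pos <- protocol$n_positions
  vals <- array(0, dim = c(length(angles), n_pos, n_bins))
  a_idx <- match(fl$angle_deg, angles)
  if (anyNA(a_idx)) stop("stimulus log contains angles not in the protocol angle set")
  covered <- table(factor(a_idx, seq_along(angles)),
                   factor(fl$position_index, seq_len(n_pos) - 1L))
  if (any(covered == 0))
    stop("protocol does not cover every (angle, position) pair")
  for (i in seq_len(nrow(fl))) {
    t0 <- fl$onset_s[i] + window[1]
    lo <- findInterval(t0, spike_times) + 1L
    hi <- findInterval(t0 + wlen - 1e-12, spike_times)
    if (hi < lo) next
    rel <- spike_times[lo:hi] - t0
    b <- pmin(floor(rel / bin_width) + 1L, n_bins)
    tb <- tabulate(b, nbins = n_bins)
    vals[a_idx[i], fl$position_index[i] + 1L, ] <-
      vals[a_idx[i], fl$position_index[i] + 1L, ] + tb
  }
  new_psth_stack(vals, bin_width, window, protocol$n_repeats, "spikes",
                 angles, protocol$position_spacing, protocol$length_unit)
}

#' Build a fluorescence PSTH stack from ROI traces
#'
#' For imaging data the analogue of the spike PSTH is the repeat-averaged,
#' baseline-subtracted fluorescence segment following each flash.  A frame is
#' assigned to the analysis window when its acquisition midpoint falls inside
#' it; the baseline is the mean over a pre-onset interval
#' (`baseline_window`, default the 0.5 s preceding onset).  Repeats whose
#' window extends past the end of the recording are dropped with a warning.
#'
#' @param traces a `roi_trace_set` as returned by [read_roi_traces()] or
#'   [simulate_calcium()]: list with `roi_ids`, `frame_rate` (Hz) and
#'   `traces` (ROI x frame matrix).
#' @param roi the ROI identifier to analyse.
#' @param protocol the `stim_protocol` presented.
#' @param window response window `c(start, stop)` seconds relative to onset.
#' @param baseline_window pre-onset interval `c(start, stop)` (negative
#'   times) whose mean is subtracted per repeat.
#' @return a `psth_stack` with `modality = "fluorescence"`; values are
#'   repeat means sampled at the frame interval (`bin_width = 1/frame_rate`).
#' @export
build_fluorescence_psth <- function(traces, roi, protocol,
                                    window = c(0, 2),
                                    baseline_window = c(-0.5, 0)) {
  ri <- match(roi, traces$roi_ids)
  if (is.na(ri)) stop("unknown ROI id: ", roi)
  y <- traces$traces[ri, ]
  fr <- traces$frame_rate
  mid <- (seq_along(y) - 0.5) / fr       # frame acquisition midpoints
  n_bins <- floor((window[2] - window[1]) * fr)
  if (n_bins < 1) stop("window shorter than one frame interval")
  fl <- protocol$flashes
  angles <- protocol$angles
  n_pos <- protocol$n_positions
  vals <- array(0, dim = c(length(angles), n_pos, n_bins))
  nrep <- array(0L, dim = c(length(angles), n_pos))
  a_idx <- match(fl$angle_deg, angles)
  dropped <- 0L
  for (i in seq_len(nrow(fl))) {
    first <- which(mid >= fl$onset_s[i] + window[1])[1]
    if (is.na(first) || first + n_bins - 1L > length(y)) { dropped <- dropped + 1L; next }
    seg <- y[first:(first + n_bins - 1L)]
    base_idx <- which(mid >= fl$onset_s[i] + baseline_window[1] &
                      mid <  fl$onset_s[i] + baseline_window[2])
    base <- if (length(base_idx)) mean(y[base_idx]) else 0
    ai <- a_idx[i]; pi <- fl$position_index[i] + 1L
    vals[ai, pi, ] <- vals[ai, pi, ] + (seg - base)
    nrep[ai, pi] <- nrep[ai, pi] + 1L
  }
  if (dropped > 0)
    warning(dropped, " repeat(s) dropped: response window extends past the trace end")
  if (any(nrep == 0))
    stop("some (angle, position) pairs have no usable repeats")
  for (a in seq_along(angles)) for (p in seq_len(n_pos))
    vals[a, p, ] <- vals[a, p, ] / nrep[a, p]
  new_psth_stack(vals, 1 / fr, c(window[1], window[1] + n_bins / fr),
                 as.integer(round(mean(nrep))), "fluorescence",
                 angles, protocol$position_spacing, protocol$length_unit)
}

#' Read spike times from CSV
#'
#' Expects columns `unit_id` and `time_s` (seconds).  Returns either the
#' full data frame or, if `unit` is given, the sorted numeric time vector of
#' that unit.
#'
#' @param path CSV file.
#' @param unit optional unit identifier to extract.
#' @export
read_spikes <- function(path, unit = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("spike CSV must have columns unit_id, time_s")
  if (is.null(unit)) return(df)
  sort(df$time_s[df$unit_id == unit])
}

#' Write spike times to CSV
#'
#' @param spike_times numeric vector of spike times (seconds).
#' @param unit_id identifier stored in the `unit_id` column.
#' @param path CSV file to write.
#' @export
write_spikes <- function(spike_times, unit_id, path) {
  utils::write.csv(data.frame(unit_id = unit_id, time_s = as.numeric(spike_times)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read ROI fluorescence traces from long-format CSV
#'
#' Expects columns `roi`, `frame` (1-based) and `value`; the frame rate is
#' read from a `frame_rate_hz` column if present, otherwise it must be given.
#'
#' @param path CSV file.
#' @param frame_rate acquisition rate in Hz (overrides any file value).
#' @return a `roi_trace_set`: list with `roi_ids`, `frame_rate`, `traces`
#'   (ROI x frame matrix).
#' @export
read_roi_traces <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("roi", "frame", "value") %in% names(df)))
    stop("trace CSV must have columns roi, frame, value")
  if (is.null(frame_rate)) {
    if (!"frame_rate_hz" %in% names(df))
      stop("frame_rate must be given (no frame_rate_hz column)")
    frame_rate <- df$frame_rate_hz[1]
  }
  ids <- unique(df$roi)
  n_frames <- max(df$frame)
  tr <- matrix(0, length(ids), n_frames)
  for (k in seq_along(ids)) {
    sub <- df[df$roi == ids[k], ]
    tr[k, sub$frame] <- sub$value
  }
  structure(list(roi_ids = ids, frame_rate = frame_rate, traces = tr),
            class = "roi_trace_set")
}

#' @rdname read_roi_traces
#' @param traces a `roi_trace_set` to write.
#' @export
write_roi_traces <- function(traces, path) {
  n <- ncol(traces$traces)
  df <- do.call(rbind, lapply(seq_along(traces$roi_ids), function(k)
    data.frame(roi = traces$roi_ids[k], frame = seq_len(n),
               value = traces$traces[k, ],
               frame_rate_hz = traces$frame_rate)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
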