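#' Generate a flashed-bar stimulation protocol
#'
#' Builds the ordered sequence of bar flashes used to acquire the Radon
#' transform of a receptive field.  Bars are presented at `n_angles` evenly
#' spaced projection angles (`angle_k = k * 180 / n_angles` degrees); at each
#' angle every one of `n_positions` parallel locations is flashed
#' `n_repeats` times in a seeded pseudo-random order.  Consecutive flashes at
#' the same angle never occupy overlapping or index-adjacent positions, which
#' limits local adaptation of the retina.
#'
#' The stored angle is the projection angle phi: the direction along which
#' bars are translated, i.e. the normal to the bar's long axis.  A bar at
#' angle phi and position index `p` covers the band
#' `|x cos(phi) + y sin(phi) - z_p| <= bar_width / 2`, where
#' `z_p = (p - (n_positions - 1) / 2) * position_spacing` so that the central
#' position index maps to the rotation centre `z = 0`.
#'
#' Angle blocks are presented sequentially: all flashes of angle `k` precede
#' those of angle `k + 1`.  Flash onsets are spaced at `duty_cycle`
#' (onset-to-onset), so the total protocol duration is
#' `n_angles * n_positions * n_repeats * duty_cycle` seconds.
#'
#' The ordering within each angle block is obtained by rejection sampling:
#' random permutations of the position multiset are drawn until none of the
#' consecutive pairs are closer than 2 position indices; after `max_tries`
#' failures the constraint is declared infeasible and an error is raised
#' (e.g. 3 positions can never be ordered non-adjacently).
#'
#' @param n_angles number of evenly spaced projection angles (>= 2).
#' @param n_positions number of bar positions per angle (>= 3).
#' @param bar_width bar width, in `length_unit`.
#' @param position_spacing centre-to-centre spacing of adjacent positions,
#'   in `length_unit`.  This sets the pixel pitch of the final reconstruction.
#' @param flash_duration duration each bar is displayed, seconds.
#' @param duty_cycle onset-to-onset interval, seconds (>= `flash_duration`).
#' @param n_repeats number of presentations of each (angle, position) pair.
#' @param contrast Weber contrast of the bar in `[-1, 1]`; negative values
#'   are dark bars on a mean-luminance background.
#' @param seed integer seed; the protocol is a deterministic function of the
#'   seed and the other arguments.
#' @param length_unit `"micrometre"` (retina) or `"degree"` (visual angle).
#' @param max_tries permutations attempted per angle block before declaring
#'   the non-adjacency constraint infeasible.
#'
#' @return An object of class `"stim_protocol"`: a list with the protocol
#'   parameters and `$flashes`, a data frame with columns `onset_s`,
#'   `angle_deg`, `position_index` (0-based), `contrast`, `duration_s`.
#' @seealso [validate_protocol()], [write_protocol()], [build_psth()]
#' @examples
#' p <- generate_protocol(n_angles = 5, n_positions = 29, seed = 1)
#' p
#' @export
generate_protocol <- function(n_angles = 5L, n_positions = 29L,
                              bar_width = 80, position_spacing = 40,
                              flash_duration = 0.1, duty_cycle = 0.5,
                              n_repeats = 3L, contrast = -1,
                              seed, length_unit = c("micrometre", "degree"),
                              max_tries = 10000L) {
  length_unit <- match.arg(length_unit)
  if (missing(seed)) stop("'seed' must be given: protocols are reproducible by construction")
  n_angles <- as.integer(n_angles); n_positions <- as.integer(n_positions)
  n_repeats <- as.integer(n_repeats)
  if (n_angles < 2L) stop("need at least 2 projection angles")
  if (n_positions < 3L) stop("need at least 3 bar positions")
  if (duty_cycle < flash_duration) stop("duty_cycle must be >= flash_duration")
  if (abs(contrast) > 1) stop("contrast must lie in [-1, 1]")
  if (bar_width <= 0 || position_spacing <= 0) stop("lengths must be positive")

  angles <- (seq_len(n_angles) - 1L) * 180 / n_angles

  set.seed(as.integer(seed))
  # one seeded permutation of all positions per repeat, chained so the
  # constraint also holds across repeat boundaries
  order_block <- function() {
    out <- integer(0)
    last <- NA_integer_
    for (r in seq_len(n_repeats)) {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        perm <- sample(seq_len(n_positions) - 1L)
        if (all(abs(diff(perm)) >= 2L) &&
            (is.na(last) || abs(perm[1] - last) >= 2L)) {
          out <- c(out, perm); last <- perm[n_positions]; done <- TRUE
          break
        }
      }
      if (!done)
        stop(sprintf(paste0("could not order %d positions without adjacent ",
                            "consecutive presentations after %d tries; the ",
                            "non-adjacency constraint is infeasible for this geometry"),
                     n_positions, max_tries))
    }
    out
  }

  per_angle <- lapply(seq_len(n_angles), function(k) order_block())
  position_index <- unlist(per_angle)
  angle_deg <- rep(angles, each = n_positions * n_repeats)
  n_flashes <- n_angles * n_positions * n_repeats
  # one blank duty cycle of padding precedes the first flash, so that
  # baseline intervals exist for every presentation
  flashes <- data.frame(
    onset_s = seq_len(n_flashes) * duty_cycle,
    angle_deg = angle_deg,
    position_index = position_index,
    contrast = contrast,
    duration_s = flash_duration
  )

  structure(list(
    angles = angles, n_positions = n_positions,
    bar_width = bar_width, position_spacing = position_spacing,
    flash_duration = flash_duration, duty_cycle = duty_cycle,
    n_repeats = n_repeats, contrast = contrast,
    length_unit = length_unit, seed = as.integer(seed),
    flashes = flashes
  ), class = "stim_protocol")
}

#' Physical position coordinates of a protocol's bar locations
#'
#' Maps 0-based position indices to the perpendicular offset `z` (in the
#' protocol's length unit), centred so the middle of the position range is
#' `z = 0`.
#'
#' @param protocol a `stim_protocol`.
#' @return numeric vector of length `n_positions`.
#' @export
protocol_z <- function(protocol) {
  n <- protocol$n_positions
  ((seq_len(n) - 1L) - (n - 1) / 2) * protocol$position_spacing
}

#' Check a stimulation protocol against its design invariants
#'
#' Verifies that (i) onsets are strictly increasing, (ii) angles are the
#' evenly spaced set `k * 180 / n_angles`, (iii) every (angle, position) pair
#' occurs exactly `n_repeats` times, and (iv) no two consecutive same-angle
#' flashes are at overlapping or index-adjacent positions
#' (`|p_i - p_{i+1}| >= 2`).
#'
#' @param protocol a `stim_protocol`.
#' @return character vector of human-readable violation descriptions,
#'   empty when the protocol is well formed.  Each adjacency violation names
#'   the flash indices involved.
#' @export
validate_protocol <- function(protocol) {
  fl <- protocol$flashes
  out <- character(0)
  if (any(diff(fl$onset_s) <= 0))
    out <- c(out, "onset times are not strictly increasing")
  expected <- (seq_along(protocol$angles) - 1L) * 180 / length(protocol$angles)
  if (!isTRUE(all.equal(sort(protocol$angles), expected, tolerance = 1e-9)))
    out <- c(out, "angles are not evenly spaced over [0, 180)")
  if (any(fl$position_index < 0L | fl$position_index >= protocol$n_positions))
    out <- c(out, "position_index out of range")
  tab <- table(factor(fl$angle_deg, levels = protocol$angles),
               factor(fl$position_index, levels = seq_len(protocol$n_positions) - 1L))
  bad <- which(tab != protocol$n_repeats, arr.ind = TRUE)
  if (nrow(bad) > 0)
    out <- c(out, sprintf("coverage violation: %d (angle, position) pairs do not occur exactly %d times",
                          nrow(bad), protocol$n_repeats))
  same <- which(diff(fl$angle_deg) == 0)
  adj <- same[abs(fl$position_index[same + 1L] - fl$position_index[same]) < 2L]
  if (length(adj) > 0)
    out <- c(out, sprintf("adjacency violation between flashes %d and %d (positions %d, %d)",
                          adj, adj + 1L,
                          fl$position_index[adj], fl$position_index[adj + 1L]))
  out
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Flashed-bar stimulation protocol\n")
  cat(sprintf("  %d angles (%s deg) x %d positions x %d repeats = %d flashes\n",
              length(x$angles), paste(format(x$angles, trim = TRUE), collapse = ", "),
              x$n_positions, x$n_repeats, nrow(x$flashes)))
  unit <- if (x$length_unit == "micrometre") "um" else "deg"
  cat(sprintf("  bar width %g %s, spacing %g %s (reconstruction resolution)\n",
              x$bar_width, unit, x$position_spacing, unit))
  cat(sprintf("  flash %g s, duty cycle %g s, contrast %+g; total duration %g s\n",
              x$flash_duration, x$duty_cycle, x$contrast,
              nrow(x$flashes) * x$duty_cycle))
  invisible(x)
}

#' Write and read protocol files
#'
#' A protocol is serialised as a JSON file (parameter header + flash table)
#' for exact round-tripping, and can additionally be exported as a flat CSV
#' stimulus log (`onset_s, angle_deg, position_index, contrast, duration_s`)
#' for synchronising with acquisition systems.
#'
#' @param protocol a `stim_protocol`.
#' @param path file to write.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  obj <- unclass(protocol)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$flashes <- as.data.frame(obj$flashes)
  obj$n_positions <- as.integer(obj$n_positions)
  obj$n_repeats <- as.integer(obj$n_repeats)
  obj$seed <- as.integer(obj$seed)
  obj$flashes$position_index <- as.integer(obj$flashes$position_index)
  structure(obj, class = "stim_protocol")
}

#' @rdname write_protocol
#' @export
write_stimulus_log <- function(protocol, path) {
  utils::write.csv(protocol$flashes, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat CSV stimulus log
#'
#' Reads a stimulus log (`onset_s, angle_deg, position_index, contrast,
#' duration_s`) as written by [write_stimulus_log()] or by acquisition
#' software, and wraps it as a `stim_protocol`.  Geometry that the flat log
#' does not carry (bar width, spacing, unit) must be supplied.
#'
#' @param path CSV file.
#' @inheritParams generate_protocol
#' @return a `stim_protocol`.
#' @export
read_stimulus_log <- function(path, bar_width, position_spacing,
                              length_unit = c("micrometre", "degree")) {
  length_unit <- match.arg(length_unit)
  fl <- utils::read.csv(path)
  need <- c("onset_s", "angle_deg", "position_index", "contrast", "duration_s")
  if (!all(need %in% names(fl)))
    stop("stimulus log must have columns: ", paste(need, collapse = ", "))
  fl$position_index <- as.integer(fl$position_index)
  angles <- sort(unique(fl$angle_deg))
  n_positions <- max(fl$position_index) + 1L
  reps <- table(fl$angle_deg, fl$position_index)
  n_repeats <- as.integer(round(stats::median(reps)))
  onsets <- sort(fl$onset_s)
  duty <- if (length(onsets) > 1) stats::median(diff(onsets)) else fl$duration_s[1]
  structure(list(
    angles = angles, n_positions = n_positions,
    bar_width = bar_width, position_spacing = position_spacing,
    flash_duration = fl$duration_s[1], duty_cycle = duty,
    n_repeats = n_repeats, contrast = fl$contrast[1],
    length_unit = length_unit, seed = NA_integer_,
    flashes = fl[order(fl$onset_s), need]
  ), class = "stim_protocol")
}
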