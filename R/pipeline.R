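#' Run the full mapping workflow from a configuration
#'
#' Executes the end-to-end pipeline for every unit (or ROI) in the input
#' files: load stimulus log -> PSTH -> component sinograms -> filtered back
#' projections -> metrics; optionally the spatiotemporal stack.  All
#' outputs are written under `out_dir` along with a JSON run manifest
#' (parameters, seeds, package version, per-unit warnings) sufficient to
#' reproduce the run.
#'
#' @param config either a path to a JSON configuration file or an
#'   equivalent named list, with entries:
#'   \describe{
#'     \item{stimulus_log}{CSV stimulus log (see [read_stimulus_log()]).}
#'     \item{spikes / traces}{CSV of spike times (`unit_id, time_s`) or of
#'       ROI traces (`roi, frame, value`); exactly one of the two.}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{bar_width, position_spacing, length_unit}{stimulus geometry.}
#'     \item{windows}{named list of analysis windows, e.g.
#'       `list(OFF = c(0, 0.15), ON = c(0.15, 0.3))`.}
#'     \item{filter, cutoff}{reconstruction settings (defaults
#'       `"ramp-hamming"`, 0.6).}
#'     \item{bin_width}{native PSTH bin, s (default 0.002).}
#'     \item{temporal}{logical, write spatiotemporal stacks.}
#'     \item{frame_rate}{Hz, for trace inputs.}
#'   }
#' @return invisibly, a list with the metrics table and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("stimulus_log", "out_dir", "bar_width", "position_spacing")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  has_spikes <- !is.null(config$spikes); has_traces <- !is.null(config$traces)
  if (has_spikes == has_traces)
    stop("config must name exactly one of 'spikes' or 'traces'")
  windows <- config$windows %||% list(OFF = c(0, 0.15), ON = c(0.15, 0.3))
  windows <- lapply(windows, as.numeric)
  ws <- do.call(rbind, windows)
  if (nrow(ws) > 1) {
    o <- order(ws[, 1])
    if (any(ws[o, 1][-1] < ws[o, 2][-nrow(ws)] - 1e-12))
      stop("validation error: analysis windows overlap")
  }
  cfg <- recon_config(filter = config$filter %||% "ramp-hamming",
                      cutoff = config$cutoff %||% 0.6)
  bin_width <- config$bin_width %||% 0.002
  protocol <- read_stimulus_log(config$stimulus_log,
                                bar_width = config$bar_width,
                                position_spacing = config$position_spacing,
                                length_unit = config$length_unit %||% "micrometre")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- list()
  results <- list()
  units <- character(0)

  run_unit <- function(id, input, is_trace) {
    withCallingHandlers({
      if (is_trace)
        fbp_rf(input, protocol, windows = windows, config = cfg, roi = id,
               temporal = isTRUE(config$temporal))
      else
        fbp_rf(input, protocol, windows = windows, config = cfg,
               bin_width = bin_width, temporal = isTRUE(config$temporal))
    }, warning = function(w) {
      warn_log[[id]] <<- c(warn_log[[id]], conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (has_spikes) {
    sp <- read_spikes(config$spikes)
    units <- as.character(unique(sp$unit_id))
    for (id in units) {
      message("unit ", id, ": ", sum(sp$unit_id == id), " spikes")
      results[[id]] <- tryCatch(
        run_unit(id, sort(sp$time_s[sp$unit_id == id]), FALSE),
        error = function(e) stop("stage failure for unit ", id, ": ",
                                 conditionMessage(e)))
    }
  } else {
    tr <- read_roi_traces(config$traces, frame_rate = config$frame_rate)
    units <- as.character(tr$roi_ids)
    for (id in units) {
      message("roi ", id)
      results[[id]] <- tryCatch(
        run_unit(id, tr, TRUE),
        error = function(e) stop("stage failure for roi ", id, ": ",
                                 conditionMessage(e)))
    }
  }

  paths <- character(0)
  metrics <- list()
  for (id in units) {
    fit <- results[[id]]
    for (nm in names(fit$images)) {
      pth <- file.path(config$out_dir, sprintf("rf_%s_%s.csv", id, nm))
      write_rf_csv(fit$images[[nm]], pth)
      paths <- c(paths, pth)
      pth <- file.path(config$out_dir, sprintf("sinogram_%s_%s.csv", id, nm))
      write_sinogram(fit$sinograms[[nm]], pth)
      paths <- c(paths, pth)
    }
    for (nm in names(fit$images))
      metrics[[paste(id, nm)]] <- {
        ctr <- fit$centres[[nm]]; f <- fit$fits[[nm]]; sn <- fit$snr[[nm]]
        data.frame(unit_id = id, component = nm,
                   centre_x = ctr$x, centre_y = ctr$y,
                   half_width_major = if (is.null(f)) NA else f$half_width_major,
                   half_width_minor = if (is.null(f)) NA else f$half_width_minor,
                   orientation = if (is.null(f)) NA else f$orientation,
                   snr = if (is.null(sn)) NA else sn$snr_abs)
      }
  }
  metrics <- do.call(rbind, metrics)
  mpath <- file.path(config$out_dir, "metrics.csv")
  utils::write.csv(metrics, mpath, row.names = FALSE)
  paths <- c(paths, mpath)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fbpmap")),
    r_version = R.version.string,
    config = config, windows = windows,
    units = units, warnings = warn_log,
    outputs = paths)
  manpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(metrics = metrics, paths = c(paths, manpath),
                 results = results))
}
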