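#' Raw RF channel data for one acquisition
#'
#' Container for multi-transmit RF channel data: a real-valued array indexed
#' `(transmit, element, time sample)` plus the time of sample 0 relative to
#' the transmit event, the sampling rate, and one steering angle per transmit.
#'
#' @param samples numeric array `[n_transmits, n_elements, n_time]`.
#' @param start_time time of sample 0 relative to transmit t = 0, s.
#' @param sampling_frequency Hz.
#' @param steering_angles numeric vector of steering angles, rad, one per
#'   transmit index.
#' @return an object of class `channel_data`.
#' @export
channel_data <- function(samples, start_time, sampling_frequency, steering_angles) {
  if (length(dim(samples)) != 3) {
    stop("channel_data: samples must be a 3-D array [transmit, element, time]")
  }
  if (dim(samples)[1] != length(steering_angles)) {
    stop("channel_data: number of transmit indices must equal length(steering_angles)")
  }
  stopifnot(sampling_frequency > 0)
  structure(list(samples = samples, start_time = start_time,
                 sampling_frequency = sampling_frequency,
                 steering_angles = steering_angles),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<channel data: %d transmits x %d elements x %d samples @ %.1f MHz>\n",
              d[1], d[2], d[3], x$sampling_frequency / 1e6))
  invisible(x)
}

#' Write / read a rotational-scan container
#'
#' A rotational scan is stored as a directory: `manifest.json` holds geometry,
#' medium, pulse, rotation angles and the ground-truth record (when the scan
#' is simulated); `rf_###.rds` holds one [channel_data()] payload per rotation
#' angle. The layout round-trips losslessly and is deterministic for a fixed
#' input object.
#'
#' @param scan a `bti_scan` object (see [simulate_rotational_scan()]).
#' @param path directory to create/read.
#' @return `read_scan()` returns the `bti_scan`; `write_scan()` returns `path`
#'   invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "bti_scan"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    theta_deg = scan$theta_deg,
    geometry = unclass(scan$geometry),
    medium = unclass(scan$medium),
    pulse = unclass(scan$pulse),
    slab_bottom = scan$slab_bottom,
    truth = scan$truth,
    rotations = sprintf("rf_%03d.rds", seq_along(scan$channels) - 1L)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(scan$channels)) {
    saveRDS(scan$channels[[i]], file.path(path, manifest$rotations[i]))
  }
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  geometry <- manifest$geometry
  geometry <- linear_array(geometry$n_elements, geometry$pitch,
                           geometry$center_frequency, geometry$sampling_frequency)
  medium <- layered_medium(manifest$medium$c1, manifest$medium$c2,
                           manifest$medium$z1)
  pulse <- ultrasound_pulse(manifest$pulse$center_frequency,
                            manifest$pulse$n_cycles,
                            manifest$pulse$sampling_frequency,
                            manifest$pulse$envelope_shape)
  channels <- lapply(file.path(path, manifest$rotations), readRDS)
  truth <- manifest$truth
  if (!is.null(truth$fiber_angle)) {
    truth$fiber_angle <- as.data.frame(truth$fiber_angle)
  }
  structure(list(channels = channels, theta_deg = manifest$theta_deg,
                 geometry = geometry, medium = medium, pulse = pulse,
                 slab_bottom = manifest$slab_bottom, truth = truth),
            class = "bti_scan")
}
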