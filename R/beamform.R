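#' Rectangular pixel grid for beamforming
#'
#' @param x lateral pixel positions, m.
#' @param z depth pixel positions, m.
#' @return data.frame of all (x, z) combinations (z varies fastest).
#' @export
pixel_grid <- function(x, z) {
  g <- expand.grid(z = z, x = x)
  data.frame(x = g$x, z = g$z)
}

select_aperture <- function(geometry, pixels, aperture, f_number, n_fixed) {
  if (is.numeric(aperture)) return(as.integer(aperture))
  switch(aperture,
         full = seq_len(geometry$n_elements),
         fixed = {
           ctr <- which.min(abs(geometry$element_x - mean(range(pixels$x))))
           half <- floor(n_fixed / 2)
           idx <- (ctr - half):(ctr + half)
           idx[idx >= 1 & idx <= geometry$n_elements][seq_len(min(n_fixed, geometry$n_elements))]
         },
         fnumber = {
           zc <- median(pixels$z)
           xc <- mean(range(pixels$x))
           half_width <- zc / (2 * f_number)
           idx <- which(abs(geometry$element_x - xc) <= half_width)
           if (length(idx) < 2) idx <- seq_len(geometry$n_elements)
           idx
         },
         stop("das_focus: unknown aperture rule '", aperture, "'"))
}

#' Delay-and-sum focusing with per-element output
#'
#' Delays the RF channel data of every plane-wave transmit to each pixel with
#' the two-layer (or homogeneous) round-trip delays and compounds over
#' transmits, retaining the per-receive-element signals in a short temporal
#' window around the pixel's focal time — the form required by the spatial
#' coherence factor. Sub-sample delays use linear interpolation; samples
#' falling outside the recorded span contribute zero and are counted, and a
#' pixel is flagged invalid when more than half of its contributions are out
#' of range.
#'
#' @param channels a [channel_data()].
#' @param geometry a [linear_array()].
#' @param medium a [layered_medium()] used for the delays (the refraction
#'   correction when `c1 != c2`).
#' @param pixels data.frame with columns `x`, `z` (m).
#' @param aperture `"fnumber"` (default; elements within `z_c / (2 f_number)`
#'   of the strip center, evaluated at the median pixel depth), `"full"`,
#'   `"fixed"` (centered `n_fixed` elements), or an explicit integer vector of
#'   element indices.
#' @param f_number receive f-number for the `"fnumber"` rule.
#' @param n_fixed aperture size for the `"fixed"` rule.
#' @param window_length temporal window length `T2 - T1`, s (default 0.19 us,
#'   about 3.4 cycles at 18 MHz).
#' @param offsets optional explicit vector of in-window time offsets, s,
#'   relative to the focal time (overrides `window_length`).
#' @return an object of class `focused_channel_data`: `s` (array
#'   `[pixel, element, offset]`), `aperture_elements`, `focal_times` (on-axis
#'   round-trip time per pixel), `window` (`c(T1, T2)`), `offsets`, `pixels`,
#'   `valid` (logical per pixel), `n_out_of_range`.
#' @export
das_focus <- function(channels, geometry, medium, pixels,
                      aperture = "fnumber", f_number = 1, n_fixed = 64L,
                      window_length = 0.19e-6, offsets = NULL) {
  stopifnot(inherits(channels, "channel_data"),
            inherits(geometry, "array_geometry"),
            inherits(medium, "layered_medium"))
  if (dim(channels$samples)[2] != geometry$n_elements) {
    stop("das_focus: channel data element count does not match geometry")
  }
  ap <- select_aperture(geometry, pixels, aperture, f_number, n_fixed)
  if (length(ap) < 1) stop("das_focus: empty receive aperture")
  fs <- channels$sampling_frequency
  if (is.null(offsets)) {
    n_w <- max(1L, round(window_length * fs))
    offsets <- (seq_len(n_w) - (n_w + 1) / 2) / fs
  }
  delays <- das_delay_tables(geometry, medium, pixels,
                             channels$steering_angles, ap)
  das_apply(channels, geometry, delays, ap, offsets, pixels)
}

## Pixel-to-element and pixel-to-transmit delay tables (reusable across the
## rotations of a scan, which share geometry, medium and pixel grid).
das_delay_tables <- function(geometry, medium, pixels, steering_angles, ap) {
  npix <- nrow(pixels)
  txdel <- vapply(steering_angles, function(a) {
    transmit_delay(medium, a, pixels$x, pixels$z)
  }, numeric(npix))
  rxdel <- vapply(geometry$element_x[ap], function(x0) {
    receive_delay(medium, x0, pixels$x, pixels$z)
  }, numeric(npix))
  list(txdel = matrix(txdel, nrow = npix),
       rxdel = matrix(rxdel, nrow = npix),
       focal_times = total_delay(medium, 0, pixels$x, pixels$x, pixels$z))
}

das_apply <- function(channels, geometry, delays, ap, offsets, pixels) {
  fs <- channels$sampling_frequency
  res <- das_focus_cpp(channels$samples, dim(channels$samples)[1],
                       geometry$n_elements, dim(channels$samples)[3],
                       delays$txdel, delays$rxdel,
                       as.integer(ap - 1L), channels$start_time, fs, offsets)
  structure(list(s = res$s, aperture_elements = ap,
                 focal_times = delays$focal_times,
                 window = range(offsets), offsets = offsets,
                 pixels = pixels,
                 valid = res$n_out <= 0.5 * res$n_total,
                 n_out_of_range = res$n_out,
                 sampling_frequency = fs),
            class = "focused_channel_data")
}

#' @export
print.focused_channel_data <- function(x, ...) {
  d <- dim(x$s)
  cat(sprintf("<focused channel data: %d pixels x %d elements x %d window samples (%d invalid)>\n",
              d[1], d[2], d[3], sum(!x$valid)))
  invisible(x)
}

#' Receive-aperture sum at the focal instant
#'
#' Sums the focused per-element signals over the receive aperture at the
#' in-window offset closest to the focal time, yielding the beamformed RF
#' value per pixel (linear in the input channel data).
#'
#' @param fcd a [das_focus()] result.
#' @return numeric vector, one value per pixel.
#' @export
compound_image <- function(fcd) {
  stopifnot(inherits(fcd, "focused_channel_data"))
  i0 <- which.min(abs(fcd$offsets))
  m <- fcd$s[, , i0, drop = FALSE]
  dim(m) <- dim(fcd$s)[1:2]
  rowSums(m)
}

#' Beamformed A-line at a fixed lateral position
#'
#' Delay-and-sum beamforms a single pixel column at lateral position `x`
#' (default the imaging axis x = 0) with an assumed constant sound speed, and
#' returns the envelope of the compounded RF against the on-axis round-trip
#' focal time. The axial pixel step is `c/(2 fs)`, so the A-line is uniformly
#' sampled in time at the RF sampling interval.
#'
#' @param channels a [channel_data()].
#' @param geometry a [linear_array()].
#' @param c_assumed assumed sound speed, m/s (1540 by default).
#' @param z_range depth span `c(z_min, z_max)`, m.
#' @param x lateral position of the A-line, m.
#' @param f_number receive f-number; the aperture grows with depth
#'   (dynamic aperture), which keeps echo timing tight when the assumed
#'   speed differs from the true fluid speed — with a wide aperture the
#'   speed mismatch smears specular echoes toward early times.
#' @param aperture optional override passed to [das_focus()] (disables the
#'   dynamic aperture).
#' @return list with `time` (s), `envelope`, `rf`, `depth` (m, at the assumed
#'   speed).
#' @export
a_line <- function(channels, geometry, c_assumed = 1540, z_range, x = 0,
                   f_number = 2, aperture = NULL) {
  fs <- channels$sampling_frequency
  dz <- c_assumed / (2 * fs)
  z <- seq(z_range[1], z_range[2], by = dz)
  px <- data.frame(x = rep(x, length(z)), z = z)
  med <- homogeneous_medium(c_assumed)
  if (!is.null(aperture)) {
    fcd <- das_focus(channels, geometry, med, px,
                     aperture = aperture, offsets = 0)
    rf <- compound_image(fcd)
    return(list(time = fcd$focal_times, envelope = envelope(rf),
                rf = rf, depth = z))
  }
  ## dynamic aperture: beamform in depth blocks, each with its own f-number
  ## aperture evaluated at the block center
  rf <- numeric(length(z))
  tf <- numeric(length(z))
  block <- 32L
  starts <- seq(1L, length(z), by = block)
  for (s0 in starts) {
    idx <- s0:min(s0 + block - 1L, length(z))
    pxb <- px[idx, , drop = FALSE]
    fcd <- das_focus(channels, geometry, med, pxb,
                     aperture = "fnumber", f_number = f_number, offsets = 0)
    rf[idx] <- compound_image(fcd)
    tf[idx] <- fcd$focal_times
  }
  list(time = tf, envelope = envelope(rf), rf = rf, depth = z)
}
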