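## Synthetic RF channel-data generator: reference-reflector and fibrous
## two-layer phantoms under rotational scanning, with ground truth for every
## downstream estimate. Travel times here are computed by routines independent
## of the beamformer's delay code (golden-section Fermat minimization and
## slowness shooting in C++; refracted-plane-wave phase accumulation in R) so
## that end-to-end tests do not commit an inverse crime.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Transmitted tone-burst description
#'
#' Defaults mirror the acquisition this toolkit targets: a four-cycle pulse at
#' 18 MHz center frequency sampled at 62.5 MHz. The gaussian envelope has
#' standard deviation `duration/4` and is truncated at `+/- duration/2`.
#'
#' @param center_frequency Hz.
#' @param n_cycles burst length in cycles (duration = n_cycles/center_frequency).
#' @param sampling_frequency Hz; must be at least twice the center frequency.
#' @param envelope_shape `"gaussian"` (default) or `"hann"`.
#' @return an object of class `ultrasound_pulse`.
#' @export
ultrasound_pulse <- function(center_frequency = 18e6, n_cycles = 4,
                             sampling_frequency = 62.5e6,
                             envelope_shape = c("gaussian", "hann")) {
  envelope_shape <- match.arg(envelope_shape)
  if (n_cycles < 1) stop("ultrasound_pulse: n_cycles must be >= 1")
  if (sampling_frequency < 2 * center_frequency) {
    stop(sprintf("ultrasound_pulse: sampling at %.3g Hz undersamples a %.3g Hz pulse",
                 sampling_frequency, center_frequency))
  }
  duration <- n_cycles / center_frequency
  structure(list(center_frequency = center_frequency, n_cycles = n_cycles,
                 sampling_frequency = sampling_frequency,
                 envelope_shape = envelope_shape,
                 duration = duration, sigma = duration / 4),
            class = "ultrasound_pulse")
}

pulse_envelope_fun <- function(pulse) {
  half <- pulse$duration / 2
  switch(pulse$envelope_shape,
         gaussian = function(t) ifelse(abs(t) <= half,
                                       exp(-t^2 / (2 * pulse$sigma^2)), 0),
         hann = function(t) ifelse(abs(t) <= half,
                                   0.5 * (1 + cos(pi * t / half)), 0))
}

#' Sample the transmitted waveform
#'
#' Zero-phase-centered tone burst with unit peak amplitude, sampled at the
#' pulse's sampling rate.
#'
#' @param pulse an [ultrasound_pulse()].
#' @return list with `time` (s, centered on 0) and `amplitude`.
#' @export
make_pulse <- function(pulse) {
  stopifnot(inherits(pulse, "ultrasound_pulse"))
  fs <- pulse$sampling_frequency
  half <- pulse$duration / 2
  idx <- seq.int(ceiling(-half * fs), floor(half * fs))
  t <- idx / fs
  env <- pulse_envelope_fun(pulse)
  list(time = t, amplitude = env(t) * cos(2 * pi * pulse$center_frequency * t))
}

#' Envelope rise offset of the clean pulse
#'
#' Time from the earliest point at which the pulse envelope reaches
#' `fraction` of its peak to the envelope peak itself. Adding this to a
#' detected threshold-crossing time converts it to the geometric arrival
#' time of the echo center, removing the systematic envelope-rise offset
#' (identical for all echoes sharing the pulse shape).
#'
#' @param pulse an [ultrasound_pulse()].
#' @param fraction threshold fraction in (0, 1).
#' @return offset, s (nonnegative).
#' @export
pulse_rise_offset <- function(pulse, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  half <- pulse$duration / 2
  tt <- seq(-half, 0, length.out = 20001L)
  ev <- pulse_envelope_fun(pulse)(tt)
  i <- which(ev >= fraction)[1]
  if (is.na(i)) return(half)
  if (i == 1) return(half)
  frac <- (fraction - ev[i - 1]) / (ev[i] - ev[i - 1])
  -(tt[i - 1] + frac * (tt[i] - tt[i - 1]))
}

#' Fibrous slab phantom description
#'
#' Point scatterers arranged along parallel "fiber" line segments in
#' horizontal planes inside the tissue layer; the in-plane fiber direction at
#' each depth stratum follows `fiber_angle_profile`. Defaults are chosen at
#' the scale of myocardial fiber bundles relative to an 18 MHz wavelength
#' (~85 um in tissue): fibers laterally unresolved along their length, with
#' inter-fiber spacing a few wavelengths.
#'
#' @param z_top,z_bottom slab bounds, m (inside layer 2; `z_top >= z1`).
#' @param fiber_angle_profile function of depth z (m) returning the in-plane
#'   fiber angle in degrees (axial, i.e., modulo 180), or a single number for
#'   a constant profile.
#' @param fiber_spacing mean spacing between fiber lines within a stratum, m
#'   (individual fibers are randomly offset by up to a quarter spacing, so
#'   the arrangement is not a regular grating).
#' @param scatterer_spacing spacing of scatterers along each fiber, m; must
#'   be well below the wavelength for the fibers to scatter as continuous
#'   lines rather than rows of resolvable points.
#' @param stratum_spacing vertical spacing of fiber planes, m.
#' @param jitter in-plane positional jitter (std), m.
#' @param jitter_z within-fiber axial jitter (std), m; kept far below a
#'   wavelength so each fiber stays phase-coherent along its length (10 um
#'   of axial jitter is already a quarter wavelength of round-trip phase at
#'   18 MHz).
#' @param fiber_z_sd fiber-to-fiber axial offset (std), m; spreads the
#'   fibers of a stratum over a thin band so the stratum does not scatter
#'   as a single specular sheet (which would smear axially under steered
#'   transmits), while each fiber keeps its own axial alignment.
#' @param amp_sd std of the per-fiber scattering amplitude about 1
#'   (scatterers within one fiber share it, with 10% point-to-point
#'   variation).
#' @param extent lateral radius of the phantom footprint, m (the footprint
#'   is a disk: a square would break rotation invariance and imprint a
#'   lab-frame angular modulation on the coherence).
#' @param seed integer; regenerating with the same seed reproduces the
#'   scatterer set bit-for-bit.
#' @return an object of class `fibrous_phantom`.
#' @export
fibrous_phantom <- function(z_top, z_bottom, fiber_angle_profile,
                            fiber_spacing = 0.12e-3,
                            scatterer_spacing = 40e-6,
                            stratum_spacing = 0.15e-3,
                            jitter = 10e-6, jitter_z = 2e-6,
                            fiber_z_sd = 15e-6, amp_sd = 1.0,
                            extent = 1.3e-3, seed = 1L) {
  if (z_bottom <= z_top) stop("fibrous_phantom: empty slab (z_bottom <= z_top)")
  if (is.numeric(fiber_angle_profile)) {
    a <- fiber_angle_profile[1]
    fiber_angle_profile <- function(z) rep(a, length(z))
  }
  stopifnot(is.function(fiber_angle_profile), extent > 0)
  structure(list(z_top = z_top, z_bottom = z_bottom,
                 fiber_angle_profile = fiber_angle_profile,
                 fiber_spacing = fiber_spacing,
                 scatterer_spacing = scatterer_spacing,
                 stratum_spacing = stratum_spacing,
                 jitter = jitter, jitter_z = jitter_z,
                 fiber_z_sd = fiber_z_sd, amp_sd = amp_sd,
                 extent = extent, seed = as.integer(seed)),
            class = "fibrous_phantom")
}

#' Linear transmural twist profile
#'
#' @param z_top,z_bottom slab bounds, m.
#' @param angle_top,angle_bottom fiber angles (deg) at the two bounds.
#' @return function of depth z returning the interpolated angle, deg.
#' @export
twist_profile <- function(z_top, z_bottom, angle_top = 60, angle_bottom = -60) {
  force(z_top); force(z_bottom); force(angle_top); force(angle_bottom)
  function(z) angle_top + (angle_bottom - angle_top) * (z - z_top) / (z_bottom - z_top)
}

#' Generate the scatterer set of a fibrous phantom
#'
#' @param phantom a [fibrous_phantom()].
#' @return data.frame with columns `x`, `y`, `z` (m) and `amp`.
#' @export
make_fibrous_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "fibrous_phantom"))
  p <- phantom
  with_seed(p$seed, {
    z_levels <- seq(p$z_top + p$stratum_spacing / 2, p$z_bottom - 1e-12,
                    by = p$stratum_spacing)
    out <- vector("list", length(z_levels))
    span <- p$extent * sqrt(2) + p$fiber_spacing  # cover the square after rotation
    s_grid <- seq(-span, span, by = p$scatterer_spacing)
    for (j in seq_along(z_levels)) {
      zj <- z_levels[j]
      phi <- deg2rad(p$fiber_angle_profile(zj))
      u <- c(cos(phi), sin(phi))    # along-fiber direction
      v <- c(-sin(phi), cos(phi))   # across-fiber direction
      d0 <- seq(-span, span, by = p$fiber_spacing) + runif(1, 0, p$fiber_spacing)
      ## de-grate the fiber lattice and give each fiber its own amplitude
      d <- d0 + runif(length(d0), -0.25, 0.25) * p$fiber_spacing
      fiber_amp <- rnorm(length(d), 1, p$amp_sd)
      fiber_dz <- rnorm(length(d), 0, p$fiber_z_sd)
      s_off <- runif(length(d), 0, p$scatterer_spacing)
      ns <- length(s_grid)
      s <- rep(s_grid, times = length(d)) + rep(s_off, each = ns)
      dd <- rep(d, each = ns)
      aa <- rep(fiber_amp, each = ns)
      zz <- rep(fiber_dz, each = ns)
      x <- s * u[1] + dd * v[1]
      y <- s * u[2] + dd * v[2]
      keep <- x^2 + y^2 <= p$extent^2
      n <- sum(keep)
      out[[j]] <- data.frame(
        x = x[keep] + rnorm(n, 0, p$jitter),
        y = y[keep] + rnorm(n, 0, p$jitter),
        z = zj + zz[keep] + rnorm(n, 0, p$jitter_z),
        amp = aa[keep] * (1 + rnorm(n, 0, 0.1)))
    }
    do.call(rbind, out)
  })
}

#' Reference-reflector pair description
#'
#' Two flat specular reflectors separated by a caliper-measured distance `L`
#' (default 6.34 mm), modeled as dense disks of identical point scatterers
#' (concentric rings) that produce flat coherent echoes for the timing
#' pipeline.
#'
#' @param near_depth depth of the near reflector, m.
#' @param separation reflector separation L, m.
#' @param amplitude scatterer amplitude of the reflector points.
#' @param radius lateral radius of the modeled reflector patch, m.
#' @param spacing in-plane scatterer spacing, m.
#' @return an object of class `reference_phantom`.
#' @export
reference_phantom <- function(near_depth = 10e-3, separation = 6.34e-3,
                              amplitude = 4, radius = 1.8e-3, spacing = 70e-6) {
  stopifnot(separation > 0, near_depth > 0)
  structure(list(near_depth = near_depth, separation = separation,
                 far_depth = near_depth + separation,
                 amplitude = amplitude, radius = radius, spacing = spacing),
            class = "reference_phantom")
}

## Concentric-ring disk of scatterers at a given depth (approximately
## rotation-invariant, as a physical flat interface is). `roughness` is an
## axial position std: zero keeps the disk specular (a machined reflector);
## a fraction of a wavelength makes it a dense diffuse sheet (a tissue
## surface), whose echoes compound without the specular smearing artifact of
## steered plane-wave transmits.
ring_disk <- function(depth, radius, spacing, amplitude, roughness = 0) {
  pts <- list(data.frame(x = 0, y = 0, z = depth, amp = amplitude))
  radii <- seq(spacing, radius, by = spacing)
  for (i in seq_along(radii)) {
    rho <- radii[i]
    n <- max(6L, round(2 * pi * rho / spacing))
    a <- 2 * pi * (seq_len(n) - 1) / n + runif(1, 0, 2 * pi)
    pts[[i + 1]] <- data.frame(x = rho * cos(a), y = rho * sin(a),
                               z = depth, amp = amplitude)
  }
  out <- do.call(rbind, pts)
  if (roughness > 0) out$z <- out$z + rnorm(nrow(out), 0, roughness)
  out
}

#' Scatterer set for the reference reflectors
#'
#' @param ref a [reference_phantom()].
#' @param which `"both"`, `"near"` or `"far"`.
#' @param seed integer seed for the (tiny) angular randomization of the rings.
#' @return data.frame with `x`, `y`, `z`, `amp`.
#' @export
make_reference_scatterers <- function(ref, which = c("both", "near", "far"),
                                      seed = 1L) {
  which <- match.arg(which)
  with_seed(seed, {
    out <- list()
    if (which %in% c("both", "near")) {
      out <- c(out, list(ring_disk(ref$near_depth, ref$radius, ref$spacing,
                                   ref$amplitude)))
    }
    if (which %in% c("both", "far")) {
      out <- c(out, list(ring_disk(ref$far_depth, ref$radius, ref$spacing,
                                   ref$amplitude)))
    }
    do.call(rbind, out)
  })
}

## Plane-wave transmit phase delay to scatterers, by refracted-angle
## accumulation (independent of raytrace::transmit_delay): the wave refracts
## at z1 with sin(a')/c2 = sin(a)/c1 and, when a slab bottom is given,
## resumes angle a in the fluid below it.
pw_transit_time <- function(x, z, alpha, c1, c2, z1, slab_bottom = NULL) {
  sa <- sin(alpha); ca <- cos(alpha)
  t <- (x * sa + pmin(z, z1) * ca) / c1
  below_if <- z > z1
  if (any(below_if)) {
    sa2 <- sa * c2 / c1
    if (abs(sa2) >= 1) stop("pw_transit_time: steering angle beyond critical angle")
    ca2 <- sqrt(1 - sa2^2)
    zb <- if (is.null(slab_bottom)) Inf else slab_bottom
    t[below_if] <- t[below_if] +
      (pmin(z[below_if], zb) - z1) * ca2 / c2
    deep <- z > zb
    if (any(deep)) t[deep] <- t[deep] + (z[deep] - zb) * ca / c1
  }
  t
}

#' Synthesize RF channel data for a scatterer set
#'
#' Each scatterer contributes, for each transmit and element, a copy of the
#' pulse at the plane-wave transit time plus the Fermat receive time, scaled
#' by its amplitude and a spherical-spreading factor `r_ref/path` (reference
#' range 5 mm). Receive times use the simulator's own golden-section Fermat
#' routine (and slowness shooting through the slab for scatterers below
#' `slab_bottom`), not the beamformer's delay code. The array frame is rotated
#' by `rotation_theta` about the z axis; steering is in the array's x-z plane.
#'
#' @param scatterers data.frame with `x`, `y`, `z`, `amp` (lab frame).
#' @param geometry a [linear_array()].
#' @param medium a [layered_medium()] (layer 2 = tissue below `z1`).
#' @param steering_angles rad, one per transmit.
#' @param pulse an [ultrasound_pulse()].
#' @param rotation_theta array rotation about z, degrees.
#' @param noise_std additive white gaussian noise std (0 = none).
#' @param record_time record length, s; an error states the required length
#'   when the latest echo does not fit.
#' @param start_time time of sample 0, s.
#' @param slab_bottom depth of the tissue lower surface, m, when scatterers
#'   exist below the tissue (default `NULL`: layer 2 extends downward).
#' @param seed integer seed for the noise draw (ignored when `noise_std` = 0).
#' @return a [channel_data()].
#' @export
synthesize_channel_data <- function(scatterers, geometry, medium,
                                    steering_angles, pulse,
                                    rotation_theta = 0, noise_std = 0,
                                    record_time, start_time = 0,
                                    slab_bottom = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(medium, "layered_medium"),
            inherits(pulse, "ultrasound_pulse"))
  th <- deg2rad(rotation_theta)
  xs <- cos(th) * scatterers$x + sin(th) * scatterers$y
  ys <- -sin(th) * scatterers$x + cos(th) * scatterers$y
  zs <- scatterers$z
  nscat <- length(xs)
  ne <- geometry$n_elements
  fs <- pulse$sampling_frequency
  ntime <- round(record_time * fs)
  if (nscat == 0) {
    rf <- array(0, c(length(steering_angles), ne, ntime))
    if (noise_std > 0) {
      rf <- rf + with_seed(seed, array(rnorm(length(rf), 0, noise_std), dim(rf)))
    }
    return(channel_data(rf, start_time, fs, steering_angles))
  }

  ## receive times (nscat x nelem)
  r <- sqrt(outer(xs, geometry$element_x, "-")^2 + ys^2)
  zrep <- rep(zs, times = ne)
  rx <- matrix(0, nscat, ne)
  if (!is.null(slab_bottom) && any(zs > slab_bottom)) {
    deep <- zs > slab_bottom
    h <- slab_bottom - medium$z1
    rx[deep, ] <- slab_rx_time_cpp(as.vector(r[deep, , drop = FALSE]),
                                   rep(zs[deep], times = ne),
                                   medium$z1, h, medium$c1, medium$c2)
    if (any(!deep)) {
      rx[!deep, ] <- fermat_rx_time_cpp(as.vector(r[!deep, , drop = FALSE]),
                                        rep(zs[!deep], times = ne),
                                        medium$z1, medium$c1, medium$c2)
    }
  } else {
    rx[] <- fermat_rx_time_cpp(as.vector(r), zrep,
                               medium$z1, medium$c1, medium$c2)
  }

  ## transmit times (nscat x ntx)
  tx <- vapply(steering_angles, function(a) {
    pw_transit_time(xs, zs, a, medium$c1, medium$c2, medium$z1, slab_bottom)
  }, numeric(nscat))
  tx <- matrix(tx, nrow = nscat)

  latest <- max(tx) + max(rx) + pulse$duration / 2
  if (latest > start_time + record_time) {
    stop(sprintf("synthesize_channel_data: record_time %.3g s too short; latest echo needs %.3g s",
                 record_time, latest - start_time))
  }

  amps <- scatterers$amp * (5e-3 / sqrt(r^2 + zs^2))  # spreading per element
  ## pulse lookup table at 64x the RF sampling rate (waveform interpolation
  ## error ~1e-4 relative; echo-center times remain exact)
  half <- pulse$duration / 2
  tt <- seq(-half, half, length.out = 2L * ceiling(64 * fs * half) + 1L)
  tab <- pulse_envelope_fun(pulse)(tt) * cos(2 * pi * pulse$center_frequency * tt)
  rf <- accumulate_echoes_cpp(tx, rx, matrix(amps, nscat, ne), tab,
                              half, start_time, fs, ntime)
  if (noise_std > 0) {
    rf <- rf + with_seed(seed, array(rnorm(length(rf), 0, noise_std), dim(rf)))
  }
  channel_data(rf, start_time, fs, steering_angles)
}

#' Single-plane-wave reference acquisition
#'
#' Simulates the reference configuration: both reflectors submerged in fluid
#' (sound speed `c1`), insonified by one unsteered plane wave.
#'
#' @param ref a [reference_phantom()].
#' @param geometry a [linear_array()].
#' @param c1 fluid sound speed, m/s.
#' @param pulse an [ultrasound_pulse()].
#' @inheritParams synthesize_channel_data
#' @return a [channel_data()] with a single transmit.
#' @export
simulate_reference_acquisition <- function(ref, geometry, c1, pulse,
                                           noise_std = 0, seed = 1L) {
  sc <- make_reference_scatterers(ref, "both", seed = seed)
  record_time <- 2 * (ref$far_depth + ref$radius) / c1 + pulse$duration + 1e-6
  synthesize_channel_data(sc, geometry, homogeneous_medium(c1), 0, pulse,
                          rotation_theta = 0, noise_std = noise_std,
                          record_time = record_time, seed = seed + 101L)
}

#' Simulate a rotational BTI scan with ground truth
#'
#' Builds the full scene — fibrous tissue slab between two specular surface
#' disks, optional reference reflector below — and synthesizes one
#' [channel_data()] per rotation angle. The returned ground-truth record
#' carries the medium speeds, interface depth, slab bounds and the programmed
#' fiber-angle profile for downstream scoring.
#'
#' @param phantom a [fibrous_phantom()] (its `z_top` is the fluid/tissue
#'   interface `z1`; pass `NULL` for an isotropic check without fibers).
#' @param geometry a [linear_array()].
#' @param medium true [layered_medium()]; `medium$z1` must equal the phantom's
#'   `z_top`.
#' @param theta_list rotation angles, degrees.
#' @param steering_angles rad.
#' @param pulse an [ultrasound_pulse()].
#' @param reflector optional [reference_phantom()] recorded through the tissue.
#' @param surface_amp scatterer amplitude of the surface disks.
#' @param surface_radius,surface_spacing surface-disk extent and density, m.
#' @param surface_roughness axial roughness (std) of the tissue surfaces, m;
#'   tissue surfaces are diffuse sheets, not mirrors.
#' @param noise_std additive noise std.
#' @param seed master seed; the scatterer sets and per-rotation noise draws
#'   are all derived from it.
#' @return an object of class `bti_scan`: `channels` (list of
#'   [channel_data()]), `theta_deg`, `geometry`, `medium`, `pulse`,
#'   `slab_bottom`, and `truth` (list incl. a `fiber_angle` table on a
#'   percent-thickness axis).
#' @export
simulate_rotational_scan <- function(phantom, geometry, medium, theta_list,
                                     steering_angles, pulse,
                                     reflector = NULL,
                                     surface_amp = 5,
                                     surface_radius = 1.8e-3,
                                     surface_spacing = 70e-6,
                                     surface_roughness = 3e-6,
                                     noise_std = 3, seed = 1L) {
  stopifnot(length(theta_list) >= 1)
  z1 <- medium$z1
  sc <- list()
  if (!is.null(phantom)) {
    stopifnot(abs(phantom$z_top - z1) < 1e-9)
    ph <- phantom
    ph$seed <- seed
    sc$fibers <- make_fibrous_phantom(ph)
    slab_bottom <- phantom$z_bottom
  } else {
    slab_bottom <- z1
  }
  sc$top <- with_seed(seed + 11L,
                      ring_disk(z1, surface_radius, surface_spacing,
                                surface_amp, surface_roughness))
  if (slab_bottom > z1) {
    sc$bottom <- with_seed(seed + 12L,
                           ring_disk(slab_bottom, surface_radius,
                                     surface_spacing, surface_amp,
                                     surface_roughness))
  }
  if (!is.null(reflector)) {
    sc$refl <- with_seed(seed + 13L,
                         make_reference_scatterers(reflector, "near", seed + 13L))
  }
  scatterers <- do.call(rbind, sc)

  max_depth <- max(scatterers$z) + surface_radius
  record_time <- 2 * max_depth / min(medium$c1, medium$c2) +
    abs(max(scatterers$x, scatterers$y)) * max(abs(sin(steering_angles))) / medium$c1 +
    pulse$duration + 1e-6
  channels <- vector("list", length(theta_list))
  for (i in seq_along(theta_list)) {
    channels[[i]] <- synthesize_channel_data(
      scatterers, geometry, medium, steering_angles, pulse,
      rotation_theta = theta_list[i], noise_std = noise_std,
      record_time = record_time,
      slab_bottom = if (!is.null(reflector)) slab_bottom else NULL,
      seed = seed + 7919L + i)
  }

  truth <- list(c1 = medium$c1, c2 = medium$c2, z1 = z1,
                h = slab_bottom - z1, z_top = z1, z_bottom = slab_bottom,
                reflector_depth = if (!is.null(reflector)) reflector$near_depth else NULL,
                reflector_separation = if (!is.null(reflector)) reflector$separation else NULL)
  if (!is.null(phantom)) {
    pct <- seq(0, 100, by = 1)
    zq <- z1 + pct / 100 * (slab_bottom - z1)
    truth$fiber_angle <- data.frame(pct_thickness = pct,
                                    angle_deg = axial_mod(phantom$fiber_angle_profile(zq)))
  }
  structure(list(channels = channels, theta_deg = theta_list,
                 geometry = geometry, medium = medium, pulse = pulse,
                 slab_bottom = slab_bottom, truth = truth),
            class = "bti_scan")
}
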