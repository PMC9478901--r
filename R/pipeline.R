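## Orchestration: configuration, simulation, sound-speed estimation,
## per-mode beamforming + coherence mapping, fiber-profile extraction and
## mode comparison, with reproducible artifact output.

#' Default run configuration
#'
#' Nested configuration for [run_pipeline()]. The default is the reduced
#' desk-scale study: a 64-element array, 11 steering angles (-20..20 degrees
#' in steps of 4) and a rotational scan in steps of 15 degrees over 360, on a
#' two-layer phantom (fluid 1480 m/s over a 2 mm tissue slab at 1540 m/s with
#' a linear transmural twist from +60 to -60 degrees). `full_scale = TRUE`
#' switches to the acquisition-scale constants (128 elements, 41 transmits in
#' steps of 1 degree, rotation step 5 degrees).
#'
#' @param seed master seed.
#' @param full_scale logical.
#' @return nested list of class `bti_config`.
#' @export
default_config <- function(seed = 1L, full_scale = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    acquisition = list(
      n_elements = if (full_scale) 128L else 64L,
      pitch = 0.10e-3,
      center_frequency = 18e6,
      sampling_frequency = 62.5e6,
      n_cycles = 4,
      envelope_shape = "gaussian",
      steering_deg = if (full_scale) seq(-20, 20, by = 1) else seq(-20, 20, by = 4),
      theta_deg = if (full_scale) seq(0, 355, by = 5) else seq(0, 345, by = 15)
    ),
    medium = list(c1 = 1480, c2 = 1540, z1 = 4.0e-3, source = "measured"),
    phantom = list(
      thickness = 2.0e-3,
      twist = c(60, -60),
      fiber_spacing = 0.12e-3,
      scatterer_spacing = 40e-6,
      stratum_spacing = 0.15e-3,
      jitter = 10e-6,
      jitter_z = 2e-6,
      fiber_z_sd = 15e-6,
      amp_sd = 1.0,
      extent = 1.3e-3,
      noise_std = 3,
      surface_amp = 5,
      surface_radius = 1.8e-3,
      surface_spacing = 70e-6,
      surface_roughness = 3e-6
    ),
    reference = list(near_depth = 10e-3, separation = 6.34e-3,
                     amplitude = 4, radius = 1.8e-3, spacing = 70e-6),
    beamform = list(modes = c("two_layer", "baseline"),
                    assumed_speed = 1540,
                    aperture = "fnumber", f_number = 1,
                    window_length = 0.19e-6,
                    pixel_dx = 0.10e-3),
    bti = list(window_x = 1.5e-3, window_z = 0.25e-3,
               pct_step = 5, epicardial_exclusion = NULL),
    timing = list(gate_half_width = 0.35e-6, rise_correction = TRUE,
                  group_fractions = c(0.39, 0.86))
  )
  class(cfg) <- c("bti_config", "list")
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' @param config a `bti_config`.
#' @param path YAML file path.
#' @return `read_config()` returns the `bti_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("bti_config", "list")
  cfg
}

config_geometry <- function(cfg) {
  a <- cfg$acquisition
  linear_array(a$n_elements, a$pitch, a$center_frequency, a$sampling_frequency)
}

config_pulse <- function(cfg) {
  a <- cfg$acquisition
  ultrasound_pulse(a$center_frequency, a$n_cycles, a$sampling_frequency,
                   a$envelope_shape)
}

config_phantom <- function(cfg) {
  m <- cfg$medium; p <- cfg$phantom
  z_bot <- m$z1 + p$thickness
  fibrous_phantom(m$z1, z_bot,
                  twist_profile(m$z1, z_bot, p$twist[1], p$twist[2]),
                  fiber_spacing = p$fiber_spacing,
                  scatterer_spacing = p$scatterer_spacing,
                  stratum_spacing = p$stratum_spacing,
                  jitter = p$jitter, jitter_z = p$jitter_z,
                  fiber_z_sd = p$fiber_z_sd, amp_sd = p$amp_sd,
                  extent = p$extent, seed = cfg$seed)
}

#' Beamform one rotation scan in one mode and map its coherence
#'
#' For mode `"two_layer"` the supplied layered medium (measured or known) is
#' used for the delays; for `"baseline"` a homogeneous medium at the assumed
#' speed (1540 m/s by default). The pixel strip covers the lateral averaging
#' window; the axial step is `c/(2 fs)`. Depths are mapped to percent
#' thickness through the focal-time axis using the surface times `tB`, `tC`.
#'
#' @param scan a `bti_scan`.
#' @param geometry a [linear_array()].
#' @param medium the two-layer [layered_medium()] for the corrected mode.
#' @param mode `"two_layer"` or `"baseline"`.
#' @param tB,tC upper/lower tissue-surface times, s (from
#'   [estimate_sound_speeds()] or ground truth).
#' @param cfg a `bti_config` (beamforming and window options).
#' @return a `coherence_map` with a `pct_thickness` axis.
#' @export
beamform_scan_mode <- function(scan, geometry, medium, mode, tB, tC, cfg) {
  fs <- scan$channels[[1]]$sampling_frequency
  bf <- cfg$beamform
  if (mode == "baseline") {
    c_a <- bf$assumed_speed
    med <- homogeneous_medium(c_a)
    z_top <- c_a * tB / 2
    z_bot <- c_a * tC / 2
    dz <- c_a / (2 * fs)
  } else {
    med <- medium
    z_top <- medium$z1
    z_bot <- medium$z1 + medium$c2 * (tC - tB) / 2
    dz <- medium$c2 / (2 * fs)
  }
  pct <- seq(cfg$bti$pct_step / 2, 100 - cfg$bti$pct_step / 2,
             by = cfg$bti$pct_step)
  depth_centers <- z_top + pct / 100 * (z_bot - z_top)
  xs <- seq(-cfg$bti$window_x / 2, cfg$bti$window_x / 2, by = bf$pixel_dx)
  zs <- seq(z_top, z_bot, by = dz)
  px <- pixel_grid(xs, zs)
  ap <- select_aperture(geometry, px, bf$aperture, bf$f_number, 64L)
  n_w <- max(1L, round(bf$window_length * fs))
  offsets <- (seq_len(n_w) - (n_w + 1) / 2) / fs
  delays <- das_delay_tables(geometry, med, px,
                             scan$channels[[1]]$steering_angles, ap)
  fcds <- lapply(scan$channels, function(ch) {
    das_apply(ch, geometry, delays, ap, offsets, px)
  })
  coherence_profile(fcds, scan$theta_deg, depth_centers,
                    window_x = cfg$bti$window_x, window_z = cfg$bti$window_z,
                    pct_thickness = pct)
}

profile_means <- function(profile, range_pct) {
  keep <- !profile$flagged & profile$pct_thickness >= range_pct[1] &
    profile$pct_thickness <= range_pct[2]
  list(mean_A0 = mean(profile$A0[keep], na.rm = TRUE),
       mean_R2 = mean(profile$R2[keep], na.rm = TRUE),
       mean_FA = mean(profile$FA[keep], na.rm = TRUE),
       n_depths = sum(keep),
       n_skipped = sum(!keep))
}

#' Run the full BTI pipeline on a simulated two-layer phantom
#'
#' Simulates the reference acquisition and the rotational scan, estimates the
#' sound speeds/thickness/interface by time of flight, beamforms every
#' rotation in the refraction-corrected two-layer mode and the homogeneous
#' baseline mode, maps spatial coherence, extracts per-depth fiber profiles,
#' and scores both modes against the programmed twist.
#'
#' @param config a `bti_config` (see [default_config()]).
#' @param out_dir optional directory; when given, fiber-profile CSVs, a
#'   summary JSON and the fully resolved config YAML are written there.
#' @return list: `speeds` (time-of-flight estimates), `profiles` (per mode),
#'   `maps` (coherence maps per mode), `summary` (per-mode mean A0/R2/FA and
#'   fiber-angle RMSE), `truth`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  geometry <- config_geometry(config)
  pulse <- config_pulse(config)
  m <- config$medium
  medium_true <- layered_medium(m$c1, m$c2, m$z1)
  phantom <- config_phantom(config)
  refl <- do.call(reference_phantom, config$reference)
  steering <- deg2rad(config$acquisition$steering_deg)

  reference <- simulate_reference_acquisition(refl, geometry, m$c1, pulse,
                                              noise_std = config$phantom$noise_std,
                                              seed = config$seed + 211L)
  scan <- simulate_rotational_scan(phantom, geometry, medium_true,
                                   config$acquisition$theta_deg, steering,
                                   pulse, reflector = refl,
                                   surface_amp = config$phantom$surface_amp,
                                   surface_radius = config$phantom$surface_radius,
                                   surface_spacing = config$phantom$surface_spacing,
                                   surface_roughness = config$phantom$surface_roughness,
                                   noise_std = config$phantom$noise_std,
                                   seed = config$seed)

  gates <- timing_gates(scan$truth, config$timing$gate_half_width)
  speeds <- estimate_sound_speeds(
    reference, scan, geometry, gates, refl$separation,
    pulse = if (isTRUE(config$timing$rise_correction)) pulse else NULL,
    c_nominal = config$beamform$assumed_speed,
    group_fractions = config$timing$group_fractions)

  if (identical(m$source, "known")) {
    medium_bf <- medium_true
    tB <- 2 * m$z1 / m$c1
    tC <- tB + 2 * (scan$slab_bottom - m$z1) / m$c2
  } else {
    medium_bf <- layered_medium(speeds$c1_mean, speeds$c2_mean, speeds$z1)
    tB <- speeds$tB
    tC <- speeds$tC
  }

  maps <- list(); profiles <- list(); summary <- list()
  margin_pct <- 100 * cfg_margin(config, tB, tC, medium_bf)
  avg_range <- c(margin_pct, 100 - margin_pct)
  if (!is.null(config$bti$epicardial_exclusion)) {
    avg_range[2] <- min(avg_range[2], config$bti$epicardial_exclusion[1])
  }
  for (mode in config$beamform$modes) {
    key <- mode
    maps[[key]] <- beamform_scan_mode(scan, geometry, medium_bf, mode,
                                      tB, tC, config)
    profiles[[key]] <- fiber_profile(maps[[key]])
    sm <- profile_means(profiles[[key]], avg_range)
    rm_ <- angle_rmse(profiles[[key]], scan$truth$fiber_angle,
                      by = "pct_thickness", range = avg_range)
    sm$rmse_deg <- rm_$rmse_deg
    sm$rmse_n <- rm_$n_used
    summary[[key]] <- sm
  }

  out <- list(speeds = speeds, profiles = profiles, maps = maps,
              summary = summary, truth = scan$truth, config = config,
              avg_range_pct = avg_range)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(profiles)) {
      utils::write.csv(profiles[[key]],
                       file.path(out_dir, paste0("fiber_profile_", key, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(list(speeds = speeds[c("c1_mean", "c1_sd", "c2_mean",
                                                "c2_sd", "h", "z1",
                                                "n_pairs_retained")],
                              summary = summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

## Boundary margin (fraction of thickness): one axial averaging window.
cfg_margin <- function(config, tB, tC, medium_bf) {
  h <- medium_bf$c2 * (tC - tB) / 2
  min(0.25, config$bti$window_z / h)
}
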