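## Time-of-flight estimation of fluid and tissue sound speeds, tissue
## thickness and interface depth from reference-reflector and tissue-surface
## echoes. Threshold-crossing times are detected on envelopes with sub-sample
## linear interpolation; systematic envelope-rise offsets cancel in the time
## differences the estimators use.

#' Threshold-crossing echo arrival time
#'
#' Earliest time inside a search window at which an envelope crosses a given
#' fraction of a reference maximum (the window-local maximum by default, or
#' the global trace maximum), with linear sub-sample interpolation of the
#' crossing. An optional rise offset (see [pulse_rise_offset()]) is added
#' to convert the crossing to the geometric arrival of the echo center
#' (the crossing precedes the envelope peak by the pulse's own rise time).
#'
#' @param env nonnegative envelope samples.
#' @param time sample times, s (same length as `env`).
#' @param window `c(start, end)`, s; must lie within the trace span.
#' @param threshold_fraction fraction in (0, 1).
#' @param reference `"window-local-max"` or `"global-pulse-max"`.
#' @param rise_offset s, added to the detected crossing (default 0).
#' @param edge `"first"` returns the earliest crossing in the window;
#'   `"peak"` walks backward from the window maximum to the rising edge of
#'   the dominant echo itself, which is robust to low-level sidelobe
#'   pedestals ahead of the echo (imperfectly cancelled off-axis energy when
#'   few transmits are compounded).
#' @return arrival time, s.
#' @export
echo_arrival_time <- function(env, time, window,
                              threshold_fraction = 0.5,
                              reference = c("window-local-max", "global-pulse-max"),
                              rise_offset = 0,
                              edge = c("first", "peak")) {
  reference <- match.arg(reference)
  edge <- match.arg(edge)
  stopifnot(length(env) == length(time), length(window) == 2)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("echo_arrival_time: threshold_fraction must be in (0, 1)")
  }
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 2) {
    stop(sprintf("echo_arrival_time: search window [%.3g, %.3g] s outside trace span",
                 window[1], window[2]))
  }
  ref_max <- if (reference == "window-local-max") max(env[idx]) else max(env)
  if (ref_max <= 0 || max(env[idx]) == min(env[idx])) {
    stop("echo_arrival_time: degenerate (flat) envelope in the search window")
  }
  thr <- threshold_fraction * ref_max
  above <- env[idx] >= thr
  if (!any(above)) {
    stop(sprintf("echo_arrival_time: no crossing of %.0f%% threshold in window [%.3g, %.3g] s",
                 100 * threshold_fraction, window[1], window[2]))
  }
  if (edge == "peak") {
    j <- which.max(env[idx])
    while (j > 1 && env[idx[j - 1]] >= thr) j <- j - 1
    i <- idx[j]
  } else {
    i <- idx[which(above)[1]]
  }
  if (i == idx[1] || env[i - 1] >= thr) {
    t_cross <- time[i]
  } else {
    f <- (thr - env[i - 1]) / (env[i] - env[i - 1])
    t_cross <- time[i - 1] + f * (time[i] - time[i - 1])
  }
  t_cross + rise_offset
}

#' Fluid sound speed from reference-reflector pairs
#'
#' Evaluates `c1 = 2 L / (t0 - tA)` for each supplied (near, far) arrival-time
#' pair and returns the mean and standard deviation over pairs.
#'
#' @param L reflector separation, m (scalar or per-pair).
#' @param t0 far-reflector arrival times, s.
#' @param tA near-reflector arrival times, s (same length as `t0`).
#' @return list with `mean`, `sd`, `n` and the per-pair `values` (m/s).
#' @export
fluid_speed <- function(L, t0, tA) {
  stopifnot(length(t0) == length(tA), length(t0) >= 1, all(L > 0))
  if (any(t0 <= tA)) {
    stop("fluid_speed: far-reflector time t0 must exceed near-reflector time tA")
  }
  v <- 2 * L / (t0 - tA)
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n = length(v), values = v)
}

#' All near/far arrival-time pairs with optional outlier rejection
#'
#' Forms every (tA, t0) combination from two per-element arrival-time groups
#' and evaluates [fluid_speed()] on them. Pairs whose speed falls outside
#' median +/- 3 MAD are optionally rejected; the retained count is reported.
#'
#' @param tA_times near-reflector arrivals (one per element in the group), s.
#' @param t0_times far-reflector arrivals, s.
#' @param L separation, m.
#' @param reject_outliers logical.
#' @return list as [fluid_speed()] plus `n_pairs_retained`, `n_pairs_total`.
#' @export
reference_pair_speed <- function(tA_times, t0_times, L, reject_outliers = TRUE) {
  g <- expand.grid(tA = tA_times, t0 = t0_times)
  est <- fluid_speed(L, g$t0, g$tA)
  keep <- rep(TRUE, est$n)
  if (reject_outliers && est$n > 4) {
    med <- median(est$values)
    madv <- mad(est$values)
    if (madv > 0) keep <- abs(est$values - med) <= 3 * madv
  }
  out <- fluid_speed(L, g$t0[keep], g$tA[keep])
  out$n_pairs_total <- est$n
  out$n_pairs_retained <- sum(keep)
  out
}

#' Tissue sound speed from substitution timing
#'
#' `c2 = c1 (1 + (tA - tD) / (tC - tB))`: the advance of the reference-
#' reflector echo when the tissue is present (`tA - tD`), normalized by the
#' round-trip transit time through the tissue (`tC - tB`), measures how much
#' faster the tissue is than the fluid.
#'
#' @param c1 fluid speed, m/s.
#' @param tA reference-reflector arrival without tissue, s.
#' @param tD reference-reflector arrival with tissue present, s.
#' @param tB,tC upper/lower tissue-surface arrivals, s (`tC > tB`).
#' @return tissue sound speed `c2`, m/s.
#' @export
tissue_speed <- function(c1, tA, tD, tB, tC) {
  if (any(tC <= tB)) stop("tissue_speed: zero or negative tissue transit (tC <= tB)")
  c1 * (1 + (tA - tD) / (tC - tB))
}

#' Tissue thickness from surface-echo timing
#'
#' @param c2 tissue speed, m/s.
#' @inheritParams tissue_speed
#' @return thickness `h = (c2/2)(tC - tB)`, m.
#' @export
tissue_thickness <- function(c2, tB, tC) {
  if (any(tC <= tB)) stop("tissue_thickness: zero or negative tissue transit (tC <= tB)")
  (c2 / 2) * (tC - tB)
}

#' Fluid/tissue interface depth from the upper-surface echo
#'
#' @param c1 fluid speed, m/s.
#' @param tB upper-surface arrival, s (> 0).
#' @return interface depth `z1 = c1 tB / 2`, m.
#' @export
interface_depth <- function(c1, tB) {
  if (any(tB <= 0)) stop("interface_depth: tB must be positive")
  c1 * tB / 2
}

#' @importFrom stats mad approx
NULL

#' Full time-of-flight sound-speed pipeline
#'
#' Estimates the fluid speed from the per-element reference acquisition
#' (all near/far pairs over two symmetric lateral element groups), then the
#' tissue speed, thickness and interface depth from A-lines at x = 0
#' beamformed at a fixed nominal speed, averaged over all rotation angles of
#' the scan.
#'
#' @param reference a single-transmit [channel_data()] of the reference
#'   configuration (both reflectors in fluid).
#' @param scan a `bti_scan` with the tissue present.
#' @param geometry a [linear_array()].
#' @param gates list of search windows, s: `tA`, `t0` (reference config),
#'   `tB`, `tC`, `tD` (tissue config), each `c(start, end)`.
#' @param L reflector separation, m.
#' @param pulse the transmitted [ultrasound_pulse()]; when supplied, detected
#'   crossings are corrected by the pulse's envelope-rise offset.
#' @param c_nominal assumed beamforming speed for the A-lines (1540 m/s).
#' @param group_fractions lateral element groups for the reference pairs, as
#'   fractions `c(inner, outer)` of the half-aperture (defaults matching
#'   2.5-5.5 mm on a 6.4 mm half-aperture).
#' @param reject_outliers passed to [reference_pair_speed()].
#' @param timing_max_steer only transmits with |steering angle| below this
#'   (rad) enter the timing A-lines. Surfaces and reflectors are specular:
#'   a steered plane wave maps a flat interface to an apparently shallower
#'   depth, so compounding steered transmits smears the echo's rising edge
#'   and biases threshold crossings early. Near-normal transmits carry all
#'   the usable specular timing information.
#' @return list: `c1_mean`, `c1_sd`, `c2_mean`, `c2_sd`, `h`, `z1`,
#'   `n_pairs_retained`, `n_pairs_total`, and the mean timings `tA`, `tB`,
#'   `tC`, `tD` (s).
#' @export
estimate_sound_speeds <- function(reference, scan, geometry, gates, L,
                                  pulse = NULL, c_nominal = 1540,
                                  group_fractions = c(0.39, 0.86),
                                  reject_outliers = TRUE,
                                  timing_max_steer = deg2rad(4.5)) {
  fs <- reference$sampling_frequency
  nt <- dim(reference$samples)[3]
  tax <- reference$start_time + (seq_len(nt) - 1) / fs
  rise50 <- if (is.null(pulse)) 0 else pulse_rise_offset(pulse, 0.5)
  rise25 <- if (is.null(pulse)) 0 else pulse_rise_offset(pulse, 0.25)

  half_ap <- max(abs(geometry$element_x))
  xg <- geometry$element_x
  grp_lo <- group_fractions[1] * half_ap
  grp_hi <- group_fractions[2] * half_ap
  left <- which(xg >= -grp_hi & xg <= -grp_lo)
  right <- which(xg >= grp_lo & xg <= grp_hi)
  if (length(left) < 1 || length(right) < 1) {
    stop("estimate_sound_speeds: element groups are empty; adjust group_fractions")
  }
  elem_time <- function(elems, window) {
    vapply(elems, function(e) {
      tr <- reference$samples[1, e, ]
      echo_arrival_time(envelope(tr), tax, window, 0.5,
                        "window-local-max", rise50, edge = "peak")
    }, numeric(1))
  }
  tA_times <- elem_time(left, gates$tA)
  t0_times <- elem_time(right, gates$t0)
  ref_est <- reference_pair_speed(tA_times, t0_times, L, reject_outliers)
  c1 <- ref_est$mean

  ## A-lines at x = 0 for each rotation, beamformed at the nominal speed
  z_lo <- max(1e-4, c_nominal * min(gates$tB[1], gates$tD[1]) / 2 - 1e-3)
  z_hi <- c_nominal * max(gates$tC[2], gates$tD[2]) / 2 + 1e-3
  n_rot <- length(scan$channels)
  tB <- tC <- tD <- numeric(n_rot)
  for (i in seq_len(n_rot)) {
    ch <- scan$channels[[i]]
    sel <- which(abs(ch$steering_angles) <= timing_max_steer)
    if (length(sel) > 0 && length(sel) < length(ch$steering_angles)) {
      ch <- channel_data(ch$samples[sel, , , drop = FALSE], ch$start_time,
                         ch$sampling_frequency, ch$steering_angles[sel])
    }
    al <- a_line(ch, geometry, c_nominal, c(z_lo, z_hi))
    tB[i] <- echo_arrival_time(al$envelope, al$time, gates$tB, 0.25,
                               "window-local-max", rise25, edge = "peak")
    tC[i] <- echo_arrival_time(al$envelope, al$time, gates$tC, 0.25,
                               "window-local-max", rise25, edge = "peak")
    tD[i] <- echo_arrival_time(al$envelope, al$time, gates$tD, 0.5,
                               "window-local-max", rise50, edge = "peak")
  }
  tA <- mean(tA_times)
  c2_rot <- tissue_speed(c1, tA, tD, tB, tC)
  c2 <- tissue_speed(c1, tA, mean(tD), mean(tB), mean(tC))
  list(c1_mean = c1, c1_sd = ref_est$sd,
       c2_mean = c2, c2_sd = if (n_rot > 1) sd(c2_rot) else 0,
       h = tissue_thickness(c2, mean(tB), mean(tC)),
       z1 = interface_depth(c1, mean(tB)),
       n_pairs_retained = ref_est$n_pairs_retained,
       n_pairs_total = ref_est$n_pairs_total,
       tA = tA, tB = mean(tB), tC = mean(tC), tD = mean(tD))
}

#' Suggested timing gates from a simulated scan's ground truth
#'
#' When the scan is simulated the true geometry is known, so search windows
#' corresponding to the surfaces and reflectors (the manual "by inspection"
#' step on measured data) can be derived automatically.
#'
#' @param truth the `truth` record of a simulated `bti_scan` (and reference
#'   configuration: `reflector_depth`, `reflector_separation`).
#' @param half_width gate half-width, s.
#' @return list of gates `tA`, `t0`, `tB`, `tC`, `tD`.
#' @export
timing_gates <- function(truth, half_width = 0.35e-6) {
  c1 <- truth$c1; c2 <- truth$c2
  tB <- 2 * truth$z1 / c1
  tC <- tB + 2 * truth$h / c2
  dR <- truth$reflector_depth
  tA <- 2 * dR / c1
  tD <- 2 * ((dR - truth$h) / c1 + truth$h / c2)
  t0 <- 2 * (dR + truth$reflector_separation) / c1
  w <- c(-half_width, half_width)
  list(tA = tA + w, t0 = t0 + w, tB = tB + w, tC = tC + w, tD = tD + w)
}
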