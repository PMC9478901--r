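## Independent oracles used by the tests. These deliberately avoid the code
## paths they check: travel times by dense grid search over candidate
## interface crossings (Fermat), transmit delays by explicit Snell refraction
## of the plane-wave direction, and the cosine fit by brute-force search over
## the fiber-angle candidate grid.

## Two-segment travel time through a candidate crossing at lateral q.
two_segment_time <- function(q, x0, x, z, z1, c1, c2) {
  sqrt(z1^2 + (x0 - q)^2) / c1 + sqrt((z - z1)^2 + (x - q)^2) / c2
}

## Dense-grid Fermat minimization (two refinement stages; final resolution
## well below 1 um for intervals of a few cm).
grid_fermat <- function(medium, x0, x, z, n_grid = 4001L) {
  lo <- min(x0, x); hi <- max(x0, x)
  for (stage in 1:3) {
    q <- seq(lo, hi, length.out = n_grid)
    tt <- two_segment_time(q, x0, x, z, medium$z1, medium$c1, medium$c2)
    i <- which.min(tt)
    step <- (hi - lo) / (n_grid - 1)
    lo <- max(min(x0, x), q[i] - 2 * step)
    hi <- min(max(x0, x), q[i] + 2 * step)
  }
  q <- seq(lo, hi, length.out = n_grid)
  tt <- two_segment_time(q, x0, x, z, medium$z1, medium$c1, medium$c2)
  i <- which.min(tt)
  list(x1 = q[i], time = tt[i])
}

## Signed Snell residual (slowness units) for an oracle-independent check.
oracle_snell_residual <- function(x1, x0, x, z, z1, c1, c2) {
  sin1 <- (x1 - x0) / sqrt(z1^2 + (x0 - x1)^2)
  sin2 <- (x - x1) / sqrt((z - z1)^2 + (x - x1)^2)
  sin1 / c1 - sin2 / c2
}

## Plane-wave transmit time by refracting the propagation direction at the
## interface (Snell) and accumulating phase per layer geometrically.
oracle_transmit_time <- function(medium, alpha, x, z) {
  c1 <- medium$c1; c2 <- medium$c2; z1 <- medium$z1
  if (z <= z1) return((x * sin(alpha) + z * cos(alpha)) / c1)
  sin2 <- sin(alpha) * c2 / c1
  stopifnot(abs(sin2) < 1)
  (x * sin(alpha) + z1 * cos(alpha)) / c1 + (z - z1) * sqrt(1 - sin2^2) / c2
}

## Brute-force cosine fit: grid over fiber-angle candidates with a
## 2-parameter (offset, nonnegative amplitude) linear fit per candidate,
## via sufficient statistics (O(1) per candidate).
brute_cosine_fit <- function(theta_deg, C, step_deg = 0.01) {
  th <- theta_deg * pi / 180
  y <- C
  n <- length(y)
  C2 <- cos(2 * th); S2 <- sin(2 * th)
  sC <- sum(C2); sS <- sum(S2)
  sCC <- sum(C2^2); sSS <- sum(S2^2); sCS <- sum(C2 * S2)
  syC <- sum(y * C2); syS <- sum(y * S2); sy <- sum(y)
  cand <- seq(0, 180 - step_deg, by = step_deg)
  c2c <- cos(2 * cand * pi / 180); s2c <- sin(2 * cand * pi / 180)
  su <- c2c * sC + s2c * sS
  suu <- c2c^2 * sCC + 2 * c2c * s2c * sCS + s2c^2 * sSS
  syu <- c2c * syC + s2c * syS
  Suu <- suu - su^2 / n
  Syu <- syu - sy * su / n
  b <- Syu / Suu
  ss_expl <- b^2 * Suu
  ss_expl[b <= 0] <- -Inf
  i <- which.max(ss_expl)
  list(A0 = (sy - b[i] * su[i]) / n, A1 = b[i], theta_fib_deg = cand[i])
}

## Random timing phantom (surfaces + reflector + sparse interior speckle):
## draws medium parameters, simulates the reference acquisition and a short
## rotational scan, runs the full time-of-flight pipeline and returns
## relative recovery errors.
run_timing_phantom <- function(seed, n_rot = 6L) {
  set.seed(seed)
  c1 <- runif(1, 1470, 1500)
  c2 <- runif(1, 1500, 1580)
  h <- runif(1, 2e-3, 5e-3)
  z1 <- runif(1, 3e-3, 4.5e-3)
  geom <- linear_array(64L)
  pulse <- ultrasound_pulse()
  med <- layered_medium(c1, c2, z1)
  refl <- reference_phantom(near_depth = 11e-3)
  ph <- fibrous_phantom(z1, z1 + h, 30,
                        fiber_spacing = 0.4e-3, scatterer_spacing = 60e-6,
                        stratum_spacing = 0.3e-3, extent = 1.0e-3,
                        seed = seed)
  thetas <- seq(0, 359, by = 360 / n_rot)
  scan <- simulate_rotational_scan(ph, geom, med, thetas,
                                   deg2rad_vec(seq(-20, 20, by = 4)),
                                   pulse, reflector = refl,
                                   noise_std = 3, seed = seed)
  reference <- simulate_reference_acquisition(refl, geom, c1, pulse,
                                              noise_std = 3, seed = seed + 1L)
  est <- estimate_sound_speeds(reference, scan, geom,
                               timing_gates(scan$truth), refl$separation,
                               pulse = pulse)
  c(c1_rel = abs(est$c1_mean - c1) / c1,
    c2_rel = abs(est$c2_mean - c2) / c2,
    h_rel = abs(est$h - h) / h,
    z1_rel = abs(est$z1 - z1) / z1)
}

deg2rad_vec <- function(x) x * pi / 180

## Small shared acquisition constants for beamforming-level tests.
test_geometry <- function(n = 64L) linear_array(n)
test_pulse <- function() ultrasound_pulse()
test_steering <- function() deg2rad_vec(seq(-20, 20, by = 4))
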