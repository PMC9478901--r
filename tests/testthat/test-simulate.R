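test_that("the default pulse has the stated duration and spectrum", {
  p <- test_pulse()
  w <- make_pulse(p)
  expect_equal(p$duration, 4 / 18e6)
  expect_equal(length(w$time), 13L)           # ~13.9 samples at 62.5 MHz
  expect_equal(max(abs(w$amplitude)), 1)      # unit peak, zero-phase center
  expect_equal(w$amplitude[w$time == 0], 1)
  p2 <- ultrasound_pulse(n_cycles = 8)
  expect_equal(p2$duration, 2 * p$duration)
  ## spectral peak within 0.5 MHz of the center frequency
  n <- 4096
  tr <- numeric(n)
  tr[200 + seq_along(w$amplitude)] <- w$amplitude
  spec <- Mod(fft(tr))[1:(n / 2)]
  f <- (seq_len(n / 2) - 1) * 62.5e6 / n
  expect_lt(abs(f[which.max(spec)] - 18e6), 0.5e6)
  expect_error(ultrasound_pulse(sampling_frequency = 30e6), "undersamples")
})

test_that("rise offsets are positive and ordered by threshold", {
  p <- test_pulse()
  r25 <- pulse_rise_offset(p, 0.25)
  r50 <- pulse_rise_offset(p, 0.5)
  expect_gt(r25, r50)
  expect_gt(r50, 0)
  ## gaussian envelope: closed form sigma * sqrt(-2 log f)
  expect_lt(abs(r50 - p$sigma * sqrt(-2 * log(0.5))), 1e-11)
  expect_lt(abs(r25 - p$sigma * sqrt(-2 * log(0.25))), 1e-11)
})

test_that("phantom generation is deterministic and disk-shaped", {
  ph <- fibrous_phantom(4e-3, 5e-3, 30, seed = 17)
  a <- make_fibrous_phantom(ph)
  b <- make_fibrous_phantom(ph)
  expect_identical(a, b)
  expect_true(all(sqrt(a$x^2 + a$y^2) <= ph$extent + 5 * ph$jitter))
  expect_true(all(a$z > 4e-3 - 1e-4 & a$z < 5e-3 + 1e-4))
  ph2 <- ph; ph2$seed <- 18L
  expect_false(identical(make_fibrous_phantom(ph2), a))
  expect_error(fibrous_phantom(5e-3, 4e-3, 30), "empty slab")
})

test_that("stratum scatterers align with the programmed fiber direction", {
  ## scatterers are far denser along fibers (40 um) than across (120 um),
  ## so nearest-neighbor displacement directions concentrate on the fiber
  ## axis; their axial circular mean must match the profile per stratum
  tw <- twist_profile(4e-3, 6e-3, 60, -60)
  ph <- fibrous_phantom(4e-3, 6e-3, tw, jitter = 5e-6, seed = 23)
  sc <- make_fibrous_phantom(ph)
  zl <- sort(unique(round(sc$z / ph$stratum_spacing)))
  for (j in seq(1, length(zl), by = 4)) {
    sel <- which(round(sc$z / ph$stratum_spacing) == zl[j])
    xy <- cbind(sc$x[sel], sc$y[sel])
    sub <- seq(1, nrow(xy), by = 7)
    nn_angle <- vapply(sub, function(i) {
      d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
      d2[i] <- Inf
      k <- which.min(d2)
      atan2(xy[k, 2] - xy[i, 2], xy[k, 1] - xy[i, 1]) * 180 / pi
    }, numeric(1))
    got <- axial_circular_stats(nn_angle)$mean_deg
    want <- tw(mean(sc$z[sel])) %% 180
    d <- abs(got - want)
    expect_lt(min(d, 180 - d), 3)
  }
})

test_that("a single on-axis scatterer echoes at the round-trip time", {
  geom <- test_geometry()
  sc <- data.frame(x = 0, y = 0, z = 6e-3, amp = 1)
  ch <- synthesize_channel_data(sc, geom, homogeneous_medium(1540), 0,
                                test_pulse(), record_time = 12e-6)
  ce <- which.min(abs(geom$element_x))
  env <- envelope(ch$samples[1, ce, ])
  fs <- ch$sampling_frequency
  t_peak <- (which.max(env) - 1) / fs
  x_e <- geom$element_x[ce]
  expect_lt(abs(t_peak - (2 * 6e-3 / 1540 + x_e^2 / (2 * 6e-3 * 1540))),
            1.5 / fs)
})

test_that("empty scenes and short records are handled explicitly", {
  geom <- test_geometry()
  sc <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   amp = numeric(0))
  ch <- synthesize_channel_data(sc, geom, homogeneous_medium(1540), 0,
                                test_pulse(), record_time = 5e-6)
  expect_true(all(ch$samples == 0))
  sc2 <- data.frame(x = 0, y = 0, z = 6e-3, amp = 1)
  expect_error(synthesize_channel_data(sc2, geom, homogeneous_medium(1540), 0,
                                       test_pulse(), record_time = 2e-6),
               "record_time")
})

test_that("channel synthesis is deterministic under a fixed seed", {
  geom <- test_geometry()
  sc <- data.frame(x = c(0, 1e-3), y = c(0, 0), z = c(5e-3, 6e-3),
                   amp = c(1, 0.5))
  args <- list(sc, geom, layered_medium(1480, 1540, 4e-3), c(-0.1, 0, 0.1),
               test_pulse(), rotation_theta = 30, noise_std = 1,
               record_time = 12e-6, seed = 99)
  expect_identical(do.call(synthesize_channel_data, args),
                   do.call(synthesize_channel_data, args))
})

test_that("simulator and beamformer travel-time routes agree without sharing code", {
  ## inverse-crime guard: the C++ golden-section Fermat time must agree with
  ## the R bisection Snell route only through the physics
  set.seed(63)
  for (i in 1:25) {
    m <- layered_medium(runif(1, 1430, 1540), runif(1, 1470, 1620),
                        runif(1, 1e-3, 5e-3))
    r <- runif(1, 0, 6e-3)
    z <- m$z1 + runif(1, 0.3e-3, 6e-3)
    via_sim <- btikit:::fermat_rx_time_cpp(r, z, m$z1, m$c1, m$c2)
    via_bf <- receive_delay(m, 0, r, z)
    expect_lt(abs(via_sim - via_bf), 1e-12)
  }
})

test_that("received energy scales with scatterer count in sparse scenes", {
  geom <- test_geometry()
  med <- homogeneous_medium(1540)
  energy <- function(n, seed) {
    set.seed(seed)
    sc <- data.frame(x = runif(n, -2e-3, 2e-3), y = runif(n, -2e-3, 2e-3),
                     z = runif(n, 4e-3, 7e-3), amp = 1)
    ch <- synthesize_channel_data(sc, geom, med, 0, test_pulse(),
                                  record_time = 12e-6)
    sum(ch$samples^2)
  }
  e1 <- mean(sapply(1:4, function(s) energy(40, s)))
  e2 <- mean(sapply(5:8, function(s) energy(80, s)))
  expect_gt(e2 / e1, 2 * 0.8)
  expect_lt(e2 / e1, 2 * 1.2)
})

test_that("a two-layer scatterer localizes correctly only with two-layer delays", {
  geom <- test_geometry()
  med <- layered_medium(1480, 1540, 4e-3)
  sc <- data.frame(x = 0, y = 0, z = 6e-3, amp = 1)
  ch <- synthesize_channel_data(sc, geom, med, test_steering(), test_pulse(),
                                record_time = 12e-6)
  px <- pixel_grid(0, seq(5.5e-3, 6.5e-3, by = 1540 / (2 * 62.5e6)))
  img_tl <- abs(compound_image(das_focus(ch, geom, med, px)))
  img_h <- abs(compound_image(das_focus(ch, geom, homogeneous_medium(1540), px)))
  dz <- 1540 / (2 * 62.5e6)
  expect_lt(abs(px$z[which.max(img_tl)] - 6e-3), 1.5 * dz)
  ## homogeneous-1540 in slower fluid maps the scatterer too deep
  expect_gt(px$z[which.max(img_h)] - 6e-3, 3 * dz)
})

test_that("a rotational scan round-trips through the container losslessly", {
  geom <- linear_array(16L)
  med <- layered_medium(1480, 1540, 4e-3)
  ph <- fibrous_phantom(4e-3, 4.6e-3, 20, fiber_spacing = 0.4e-3,
                        scatterer_spacing = 0.1e-3, stratum_spacing = 0.3e-3,
                        extent = 0.6e-3, seed = 5)
  scan <- simulate_rotational_scan(ph, geom, med, c(0, 90), test_steering(),
                                   test_pulse(), surface_radius = 0.8e-3,
                                   surface_spacing = 0.15e-3, seed = 5)
  dir <- file.path(tempdir(), "scan_rt")
  write_scan(scan, dir)
  back <- read_scan(dir)
  expect_equal(back$theta_deg, scan$theta_deg)
  expect_equal(back$geometry$element_x, scan$geometry$element_x)
  expect_equal(back$medium, scan$medium)
  expect_identical(back$channels[[1]]$samples, scan$channels[[1]]$samples)
  expect_identical(back$channels[[2]]$samples, scan$channels[[2]]$samples)
  expect_equal(back$truth$fiber_angle, scan$truth$fiber_angle)
  unlink(dir, recursive = TRUE)
})

test_that("a single-angle scan reduces to one synthesis call", {
  geom <- linear_array(16L)
  med <- layered_medium(1480, 1540, 4e-3)
  ph <- fibrous_phantom(4e-3, 4.6e-3, 20, fiber_spacing = 0.4e-3,
                        scatterer_spacing = 0.1e-3, stratum_spacing = 0.3e-3,
                        extent = 0.6e-3, seed = 5)
  scan <- simulate_rotational_scan(ph, geom, med, 0, test_steering(),
                                   test_pulse(), surface_radius = 0.8e-3,
                                   surface_spacing = 0.15e-3, seed = 5)
  expect_length(scan$channels, 1)
  expect_equal(scan$truth$h, 0.6e-3)
  expect_equal(scan$truth$fiber_angle$angle_deg, rep(20, 101))
})
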