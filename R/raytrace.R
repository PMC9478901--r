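## Exact travel times for steered plane waves and point-to-element rays in a
## homogeneous or two-layer medium, with refraction at the horizontal
## interface. All operations are vectorized over (alpha, element_x, x, z);
## arguments are recycled to a common length. Angles are radians, lengths
## meters, times seconds.

recycle_args <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 1L))
  lapply(args, rep_len, n)
}

#' Plane-wave transmit delay in a two-layer medium
#'
#' Time of flight of a steered plane wave from the array plane (its phase
#' reference at the origin at t = 0) to an image point. For points beyond the
#' interface the wave refracts: the phase accumulates at the layer-1 slowness
#' down to `z1` and at the refracted vertical slowness
#' `sqrt(1/c2^2 - sin(alpha)^2/c1^2)` below it.
#'
#' @param medium a [layered_medium()].
#' @param alpha steering angle, rad, measured from the z (depth) axis in the
#'   x-z plane.
#' @param x,z image-point coordinates, m (`z >= 0`).
#' @return transmit time of flight, s (vectorized).
#' @export
transmit_delay <- function(medium, alpha, x, z) {
  a <- recycle_args(alpha = alpha, x = x, z = z)
  alpha <- a$alpha; x <- a$x; z <- a$z
  if (any(z < 0)) stop("transmit_delay: image point depth z must be >= 0")
  c1 <- medium$c1; c2 <- medium$c2; z1 <- medium$z1
  below <- z > z1
  if (any(below)) {
    crit <- abs(sin(alpha[below])) >= c1 / c2
    if (any(crit)) {
      bad <- which(below)[which(crit)[1]]
      stop(sprintf(paste0("transmit_delay: steering angle %.4f rad exceeds the ",
                          "critical angle for c1 = %.1f, c2 = %.1f m/s ",
                          "(total internal reflection)"),
                   alpha[bad], c1, c2))
    }
  }
  tau <- (x * sin(alpha) + z * cos(alpha)) / c1
  if (any(below)) {
    sl2 <- 1 / c2^2 - sin(alpha[below])^2 / c1^2
    tau[below] <- (x[below] * sin(alpha[below]) + z1 * cos(alpha[below])) / c1 +
      (z[below] - z1) * sqrt(sl2)
  }
  tau
}

## Signed Snell residual at a candidate interface crossing x1 for the ray
## element (x0, 0) -> (x1, z1) -> (x, z). Zero at the Fermat path; strictly
## increasing in x1, which makes bisection exact and unconditionally stable.
snell_residual <- function(x1, x0, x, z, z1, c1, c2) {
  (x1 - x0) / (c1 * sqrt(z1^2 + (x0 - x1)^2)) -
    (x - x1) / (c2 * sqrt((z - z1)^2 + (x - x1)^2))
}

#' Refracted-ray interface crossing
#'
#' Lateral coordinate `x1` at which the receive ray from an image point below
#' the interface to an array element crosses the interface, satisfying Snell's
#' law (equivalently, minimizing the two-segment travel time; Fermat's
#' principle). Solved by bisection on the monotone Snell residual over
#' `[min(x0, x), max(x0, x)]`.
#'
#' @param medium a [layered_medium()].
#' @param element_x lateral element position `x0`, m.
#' @param x,z image-point coordinates, m; requires `z > medium$z1`.
#' @return crossing coordinate `x1`, m (vectorized).
#' @export
interface_crossing <- function(medium, element_x, x, z) {
  a <- recycle_args(x0 = element_x, x = x, z = z)
  x0 <- a$x0; x <- a$x; z <- a$z
  z1 <- medium$z1; c1 <- medium$c1; c2 <- medium$c2
  if (any(z <= z1)) {
    stop(sprintf("interface_crossing: point depth z = %.6g m does not exceed the interface z1 = %.6g m (no crossing exists)",
                 z[which(z <= z1)[1]], z1))
  }
  if (z1 == 0) return(x0)
  lo <- pmin(x0, x)
  hi <- pmax(x0, x)
  for (i in seq_len(72L)) {
    mid <- 0.5 * (lo + hi)
    g <- snell_residual(mid, x0, x, z, z1, c1, c2)
    up <- g < 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  x1 <- 0.5 * (lo + hi)
  res <- snell_residual(x1, x0, x, z, z1, c1, c2)
  if (any(!is.finite(res))) {
    stop("interface_crossing: non-finite Snell residual (degenerate geometry)")
  }
  ## residual scale: slowness 1/c; demand near machine-level stationarity
  if (any(abs(res) > 1e-6 / c1)) {
    stop(sprintf("interface_crossing: bisection failed to converge (residual %.3e s/m)",
                 max(abs(res))))
  }
  x1
}

#' Receive (echo) delay from an image point to an array element
#'
#' Time of flight of a spherically spreading echo from `(x, y, z)` to the
#' element at `(element_x, 0, 0)`. Below the interface the Fermat refracted
#' path is used: layer-1 and layer-2 segment lengths each divided by their
#' sound speed. Points with `y != 0` reduce to the 2-D problem in the vertical
#' plane containing element and point (lateral separation
#' `sqrt((x - x0)^2 + y^2)`).
#'
#' @inheritParams interface_crossing
#' @param y elevational coordinate, m (default 0; used by the simulator).
#' @return receive time of flight, s (vectorized).
#' @export
receive_delay <- function(medium, element_x, x, z, y = 0) {
  a <- recycle_args(x0 = element_x, x = x, z = z, y = y)
  x0 <- a$x0; x <- a$x; z <- a$z; y <- a$y
  if (any(z < 0)) stop("receive_delay: image point depth z must be >= 0")
  c1 <- medium$c1; c2 <- medium$c2; z1 <- medium$z1
  r <- sqrt((x - x0)^2 + y^2)     # lateral separation in the ray plane
  tau <- numeric(length(z))
  above <- z <= z1
  tau[above] <- sqrt(r[above]^2 + z[above]^2) / c1
  if (any(!above)) {
    rb <- r[!above]; zb <- z[!above]
    q <- interface_crossing(medium, rep(0, length(rb)), rb, zb)
    tau[!above] <- sqrt(z1^2 + q^2) / c1 +
      sqrt((zb - z1)^2 + (rb - q)^2) / c2
  }
  tau
}

#' Round-trip delay-and-sum delay
#'
#' Total delay used by delay-and-sum coherent plane-wave compounding:
#' [transmit_delay()] of the steered plane wave to the point plus
#' [receive_delay()] of the echo back to the element. In a homogeneous medium
#' this reduces to the single-speed compounding delay
#' `(x sin a + z cos a)/c + sqrt(z^2 + (x - x0)^2)/c`.
#'
#' @inheritParams transmit_delay
#' @param element_x lateral element position, m.
#' @return total time of flight, s (vectorized).
#' @export
total_delay <- function(medium, alpha, element_x, x, z) {
  transmit_delay(medium, alpha, x, z) + receive_delay(medium, element_x, x, z)
}
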