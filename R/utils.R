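#' @useDynLib btikit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median rnorm runif sd
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Analytic-signal envelope of an RF trace
#'
#' Magnitude of the analytic signal (FFT construction): the positive-frequency
#' half of the spectrum is doubled, the negative half zeroed, and the inverse
#' transform's modulus returned. For a tone burst this recovers the amplitude
#' profile up to edge ripple.
#'
#' @param trace numeric vector, real RF samples (length >= 2).
#' @return nonnegative numeric vector of the same length.
#' @export
envelope <- function(trace) {
  if (length(trace) < 2) stop("envelope: trace must have length >= 2")
  if (!is.numeric(trace)) stop("envelope: trace must be numeric")
  n <- length(trace)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(trace) * h, inverse = TRUE) / n)
}

## Wrap an axial (period-180 deg) angle difference into (-90, 90].
wrap_axial <- function(d) {
  w <- (d + 90) %% 180 - 90
  ifelse(w == -90, 90, w)
}

## Map an axial angle into [0, 180).
axial_mod <- function(a) a %% 180

## Unwrap a sequence of axial angles (degrees) so successive differences lie
## in (-90, 90]; used before interpolating orientation profiles.
unwrap_axial <- function(a) {
  if (length(a) <= 1) return(a)
  d <- wrap_axial(diff(a))
  a[1] + cumsum(c(0, d))
}
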