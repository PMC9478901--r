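#' Two-layer acoustic medium
#'
#' Describes an imaging region made of a fluid layer (sound speed `c1`) above
#' a horizontal interface at depth `z1`, with tissue (sound speed `c2`) below.
#' Array elements lie on the `z = 0` line along the x axis; `z` increases away
#' from the array into the medium.
#'
#' @param c1 sound speed in layer 1 (fluid), m/s.
#' @param c2 sound speed in layer 2 (tissue), m/s.
#' @param z1 interface depth below the array plane, m (>= 0).
#' @return an object of class `layered_medium` with fields `c1`, `c2`, `z1`.
#' @examples
#' layered_medium(1480, 1540, 4e-3)
#' homogeneous_medium(1540)
#' @export
layered_medium <- function(c1, c2, z1) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(z1),
            length(c1) == 1, length(c2) == 1, length(z1) == 1)
  if (c1 <= 0 || c2 <= 0) stop("layered_medium: sound speeds must be positive")
  if (z1 < 0) stop("layered_medium: interface depth z1 must be >= 0")
  structure(list(c1 = c1, c2 = c2, z1 = z1), class = "layered_medium")
}

#' @rdname layered_medium
#' @param c sound speed of the single medium, m/s.
#' @details `homogeneous_medium()` sets `c1 == c2`; all delay computations are
#'   then independent of `z1`.
#' @export
homogeneous_medium <- function(c, z1 = 0) layered_medium(c, c, z1)

is_homogeneous <- function(medium) medium$c1 == medium$c2

#' @export
print.layered_medium <- function(x, ...) {
  if (is_homogeneous(x)) {
    cat(sprintf("<homogeneous medium: c = %.1f m/s>\n", x$c1))
  } else {
    cat(sprintf("<layered medium: c1 = %.1f m/s | z1 = %.3f mm | c2 = %.1f m/s>\n",
                x$c1, x$z1 * 1e3, x$c2))
  }
  invisible(x)
}

#' Linear-array geometry
#'
#' Element centers are uniformly spaced along x and centered on the origin
#' (`mean(element_x) == 0`). Defaults correspond to a 128-element, 0.10 mm
#' pitch high-frequency array driven with an 18 MHz pulse sampled at 62.5 MHz.
#'
#' @param n_elements number of elements.
#' @param pitch element spacing, m.
#' @param center_frequency transmit center frequency, Hz.
#' @param sampling_frequency RF sampling rate, Hz.
#' @return an object of class `array_geometry` with fields `element_x`,
#'   `n_elements`, `pitch`, `center_frequency`, `sampling_frequency`.
#' @export
linear_array <- function(n_elements = 128L, pitch = 0.10e-3,
                         center_frequency = 18e6, sampling_frequency = 62.5e6) {
  stopifnot(n_elements >= 2, pitch > 0, center_frequency > 0,
            sampling_frequency > 0)
  n_elements <- as.integer(n_elements)
  element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(element_x = element_x, n_elements = n_elements, pitch = pitch,
                 center_frequency = center_frequency,
                 sampling_frequency = sampling_frequency),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<linear array: %d elements, pitch %.3f mm, fc %.1f MHz, fs %.1f MHz>\n",
              x$n_elements, x$pitch * 1e3, x$center_frequency / 1e6,
              x$sampling_frequency / 1e6))
  invisible(x)
}
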