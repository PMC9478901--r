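#' Spatial coherence factor of focused channel data
#'
#' Ratio of coherently to incoherently summed receive-aperture energy over a
#' short temporal window centered at the focal time:
#' `C = sum_t |sum_k s(k,t)|^2 / (N sum_t sum_k |s(k,t)|^2)`.
#' `C` is 1 for perfectly aligned (identical) channels, `1/N` for a single
#' active channel, and approaches `1/N` in expectation for incoherent noise.
#'
#' @param x either a numeric matrix `s` with one row per aperture element and
#'   one column per in-window time sample, or a [das_focus()] result.
#' @param pixel optional pixel index when `x` is focused channel data; when
#'   omitted, coherence is returned for every pixel.
#' @return coherence value(s) in `[0, 1]`; `NA` where the window energy is
#'   zero (undefined coherence, excluded from downstream averaging) or the
#'   pixel is flagged invalid.
#' @export
coherence_factor <- function(x, pixel = NULL) {
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("coherence_factor: need at least 2 aperture elements")
    num <- sum(colSums(x)^2)
    den <- nrow(x) * sum(x^2)
    if (den == 0) return(NA_real_)
    return(num / den)
  }
  stopifnot(inherits(x, "focused_channel_data"))
  if (!is.null(pixel)) {
    m <- x$s[pixel, , , drop = FALSE]
    dim(m) <- dim(x$s)[2:3]
    if (!x$valid[pixel]) return(NA_real_)
    return(coherence_factor(m))
  }
  d <- dim(x$s)
  N <- d[2]
  sk <- colSums(aperm(x$s, c(2, 1, 3)))          # [pixel, time]: aperture sum
  num <- rowSums(matrix(sk^2, d[1], d[3]))
  den <- N * rowSums(matrix(x$s^2, d[1], d[2] * d[3]))
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!x$valid] <- NA_real_
  out
}

#' Coherence map over a rotational scan
#'
#' Averages per-pixel coherence over a moving spatial window centered on the
#' imaging axis x = 0 (default 1.5 mm laterally by 0.25 mm axially, to
#' suppress specular heterogeneities unrelated to fiber direction), for each
#' rotation angle and each requested depth.
#'
#' @param fcd_list list of [das_focus()] results, one per rotation angle
#'   (each over the same lateral strip).
#' @param theta_deg rotation angles, degrees, one per list entry.
#' @param depths depth-axis sample points, m (window centers).
#' @param window_x,window_z averaging window size, m.
#' @param pct_thickness optional vector, same length as `depths`, carried
#'   through as the percent-thickness axis.
#' @return an object of class `coherence_map`: matrix `C` `[theta, depth]`,
#'   `theta_deg`, `depths`, optional `pct_thickness`.
#' @export
coherence_profile <- function(fcd_list, theta_deg, depths,
                              window_x = 1.5e-3, window_z = 0.25e-3,
                              pct_thickness = NULL) {
  stopifnot(length(fcd_list) == length(theta_deg))
  px <- fcd_list[[1]]$pixels
  if (window_x / 2 > diff(range(px$x)) / 2 + 1e-9 + max(abs(px$x))) {
    stop("coherence_profile: averaging window wider than the beamformed strip")
  }
  C <- matrix(NA_real_, length(theta_deg), length(depths))
  for (i in seq_along(fcd_list)) {
    ci <- coherence_factor(fcd_list[[i]])
    pxi <- fcd_list[[i]]$pixels
    in_x <- abs(pxi$x) <= window_x / 2 + 1e-12
    for (j in seq_along(depths)) {
      sel <- in_x & abs(pxi$z - depths[j]) <= window_z / 2 + 1e-12
      v <- ci[sel]
      v <- v[is.finite(v)]
      if (length(v) > 0) C[i, j] <- mean(v)
    }
  }
  structure(list(C = C, theta_deg = theta_deg, depths = depths,
                 pct_thickness = pct_thickness),
            class = "coherence_map")
}

#' Cosine fit of coherence versus array rotation angle
#'
#' Linear least-squares fit of `C ~ A0 + A1 cos(2 (theta - theta_fib))` via
#' the basis `(1, cos 2 theta, sin 2 theta)`. The period-180 model reflects
#' the axial nature of fiber orientation; the fit is invariant under
#' relabeling `theta -> theta + 180`.
#'
#' @param theta_deg rotation angles, degrees; at least 4 distinct angles
#'   spanning at least half a turn.
#' @param C coherence values (NA entries are dropped).
#' @return list: `A0`, `A1` (>= 0), `theta_fib_deg` in `[0, 180)` (`NA` when
#'   the modulation is below the numerical noise floor — a uniform coherence
#'   carries no orientation), `R2` (`NA` when the total sum of squares
#'   vanishes), `n_used`.
#' @export
cosine_fit <- function(theta_deg, C) {
  keep <- is.finite(C) & is.finite(theta_deg)
  th <- deg2rad(theta_deg[keep]); y <- C[keep]
  thu <- unique(round(theta_deg[keep] %% 360, 9))
  if (length(thu) < 4 || diff(range(theta_deg[keep])) < 180 - 1e-9) {
    stop("cosine_fit: need >= 4 distinct angles spanning >= 180 degrees")
  }
  X <- cbind(1, cos(2 * th), sin(2 * th))
  beta <- qr.solve(X, y)
  fitted <- drop(X %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  A0 <- beta[1]
  A1 <- sqrt(beta[2]^2 + beta[3]^2)
  eps <- .Machine$double.eps^0.5 * max(abs(y), 1e-300)
  theta_fib <- if (A1 <= eps) NA_real_ else axial_mod(rad2deg(0.5 * atan2(beta[3], beta[2])))
  R2 <- if (ss_tot <= eps^2) NA_real_ else 1 - ss_res / ss_tot
  list(A0 = unname(A0), A1 = unname(A1), theta_fib_deg = theta_fib,
       R2 = R2, n_used = sum(keep))
}

#' Fractional anisotropy of the coherence modulation
#'
#' `FA = A1 / sqrt((A0^2 + A1^2)/2)`: normalized modulation depth of
#' coherence versus array angle. 0 for isotropic coherence, 1 when the
#' modulation amplitude equals the mean; strictly increasing in `A1/A0`.
#'
#' @param A0 mean coherence (> 0).
#' @param A1 modulation amplitude (>= 0).
#' @return FA, dimensionless (vectorized).
#' @export
fractional_anisotropy <- function(A0, A1) {
  if (any(A0 <= 0, na.rm = TRUE)) {
    stop("fractional_anisotropy: mean coherence A0 must be positive")
  }
  A1 / sqrt((A0^2 + A1^2) / 2)
}

#' Per-depth fiber profile from a coherence map
#'
#' Applies [cosine_fit()] and [fractional_anisotropy()] at each depth of a
#' [coherence_profile()] map. Depths whose coherence row is entirely
#' undefined are flagged and carried through without fabricating angles.
#'
#' @param map a `coherence_map`.
#' @return data.frame with one row per depth: `depth`, `pct_thickness`
#'   (if present), `A0`, `A1`, `theta_fib_deg`, `R2`, `FA`, `n_theta`,
#'   `flagged`.
#' @export
fiber_profile <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  n <- length(map$depths)
  out <- data.frame(depth = map$depths,
                    pct_thickness = if (is.null(map$pct_thickness)) NA_real_ else map$pct_thickness,
                    A0 = NA_real_, A1 = NA_real_, theta_fib_deg = NA_real_,
                    R2 = NA_real_, FA = NA_real_, n_theta = 0L, flagged = TRUE)
  for (j in seq_len(n)) {
    Cj <- map$C[, j]
    if (sum(is.finite(Cj)) < 4) next
    fit <- cosine_fit(map$theta_deg, Cj)
    out$A0[j] <- fit$A0; out$A1[j] <- fit$A1
    out$theta_fib_deg[j] <- fit$theta_fib_deg
    out$R2[j] <- fit$R2
    out$FA[j] <- if (fit$A0 > 0) fractional_anisotropy(fit$A0, fit$A1) else NA_real_
    out$n_theta[j] <- fit$n_used
    out$flagged[j] <- FALSE
  }
  out
}

#' Normalized coherence map C/A0
#'
#' @param map a `coherence_map`.
#' @param profile optional precomputed [fiber_profile()] of `map`.
#' @return the map with each depth column divided by its fitted `A0`.
#' @export
normalize_coherence <- function(map, profile = fiber_profile(map)) {
  out <- map
  out$C <- sweep(map$C, 2, profile$A0, "/")
  out
}

#' Circular statistics for axial (period-180) orientation data
#'
#' Angle-doubling statistics: mean `0.5 atan2(mean sin 2a, mean cos 2a)`
#' mapped to `[0, 180)`, and circular standard deviation
#' `0.5 sqrt(-2 ln Rbar)` (degrees) from the mean resultant length of the
#' doubled angles.
#'
#' @param angles_deg orientation angles, degrees (a fiber at `a` and
#'   `a + 180` is the same fiber).
#' @return list with `mean_deg` in `[0, 180)` (`NA` when the resultant length
#'   vanishes) and `sd_deg`.
#' @export
axial_circular_stats <- function(angles_deg) {
  if (length(angles_deg) < 1) stop("axial_circular_stats: empty input")
  a2 <- deg2rad(2 * angles_deg)
  S <- mean(sin(a2)); Cc <- mean(cos(a2))
  R <- sqrt(S^2 + Cc^2)
  if (R < .Machine$double.eps^0.75) {
    return(list(mean_deg = NA_real_, sd_deg = rad2deg(0.5 * sqrt(-2 * log(max(R, 1e-300))))))
  }
  list(mean_deg = axial_mod(rad2deg(0.5 * atan2(S, Cc))),
       sd_deg = rad2deg(0.5 * sqrt(-2 * log(min(R, 1)))))
}

#' RMSE between an estimated fiber profile and a ground-truth twist
#'
#' Truth angles are unwrapped on the axial circle, linearly interpolated onto
#' the profile's depth axis, and compared with per-depth differences wrapped
#' to `(-90, 90]`. Flagged depths are skipped; an optional depth-range mask
#' (e.g., excluding a disorganized epicardial band) restricts the comparison.
#'
#' @param profile a [fiber_profile()] data.frame.
#' @param truth data.frame with a depth column matching `by` and
#'   `angle_deg`.
#' @param by `"pct_thickness"` (default) or `"depth"`.
#' @param range optional `c(lo, hi)` mask on the `by` axis.
#' @return list with `rmse_deg`, `n_used`.
#' @export
angle_rmse <- function(profile, truth, by = "pct_thickness", range = NULL) {
  x_est <- profile[[by]]
  keep <- !profile$flagged & is.finite(profile$theta_fib_deg) & is.finite(x_est)
  if (!is.null(range)) keep <- keep & x_est >= range[1] & x_est <= range[2]
  if (!any(keep)) stop("angle_rmse: no overlapping valid depths")
  tru_u <- unwrap_axial(truth$angle_deg)
  est_x <- x_est[keep]
  if (min(est_x) < min(truth[[by]]) - 1e-9 || max(est_x) > max(truth[[by]]) + 1e-9) {
    stop("angle_rmse: profile depths outside the truth table span")
  }
  tru_i <- approx(truth[[by]], tru_u, xout = est_x)$y
  d <- wrap_axial(profile$theta_fib_deg[keep] - tru_i)
  list(rmse_deg = sqrt(mean(d^2)), n_used = sum(keep))
}
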