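#include <Rcpp.h>
using namespace Rcpp;

// Delay-and-sum focusing kernel. For each pixel p, aperture element k and
// window offset t, sums linearly interpolated RF samples over all transmits:
//   s(p, k, t) = sum_tx rf[tx, k, (txdel(p,tx) + rxdel(p,k) + off[t])]
// Samples mapping outside the recorded span contribute zero and are counted
// per pixel so callers can flag unreliable pixels.
//
// rf is the R array [ntx, nelem, ntime] (column-major). ap is 0-based
// indices of the receive-aperture elements. Returns list(s, n_out, n_total).
// [[Rcpp::export]]
List das_focus_cpp(NumericVector rf, int ntx, int nelem, int ntime,
                   NumericMatrix txdel, NumericMatrix rxdel,
                   IntegerVector ap, double start_time, double fs,
                   NumericVector offsets) {
  const int npix = txdel.nrow();
  const int nap = ap.size();
  const int nt = offsets.size();
  NumericVector s(static_cast<R_xlen_t>(npix) * nap * nt);
  IntegerVector n_out(npix);
  const double *prf = rf.begin();
  double *ps = s.begin();
  for (int p = 0; p < npix; ++p) {
    int out = 0;
    for (int k = 0; k < nap; ++k) {
      const int e = ap[k];
      const double rx = rxdel(p, k);
      for (int t = 0; t < nt; ++t) {
        double acc = 0.0;
        for (int tx = 0; tx < ntx; ++tx) {
          const double ti = (txdel(p, tx) + rx + offsets[t] - start_time) * fs;
          const int i0 = static_cast<int>(std::floor(ti));
          if (i0 < 0 || i0 + 1 >= ntime) { ++out; continue; }
          const double fr = ti - i0;
          const double *col = prf + tx + static_cast<R_xlen_t>(nelem) * ntx * i0
            + static_cast<R_xlen_t>(ntx) * e;
          const double lo = *col;
          const double hi = *(col + static_cast<R_xlen_t>(nelem) * ntx);
          acc += lo + fr * (hi - lo);
        }
        ps[p + static_cast<R_xlen_t>(npix) * (k + static_cast<R_xlen_t>(nap) * t)] = acc;
      }
    }
    n_out[p] = out;
  }
  s.attr("dim") = IntegerVector::create(npix, nap, nt);
  return List::create(_["s"] = s, _["n_out"] = n_out,
                      _["n_total"] = nap * nt * ntx);
}

// Golden-section Fermat travel time for the simulator (kept independent of
// the beamformer's bisection Snell solver). Minimizes the two-segment time
//   f(q) = sqrt(z1^2 + q^2)/c1 + sqrt((z - z1)^2 + (r - q)^2)/c2
// over the interface offset q in [0, r]; r >= 0 is the lateral separation in
// the vertical plane containing element and scatterer. Points at or above the
// interface travel straight at c1.
// [[Rcpp::export]]
NumericVector fermat_rx_time_cpp(NumericVector r, NumericVector z,
                                 double z1, double c1, double c2) {
  const int n = r.size();
  NumericVector out(n);
  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;
  for (int i = 0; i < n; ++i) {
    const double ri = r[i], zi = z[i];
    if (zi <= z1 || z1 <= 0.0) {
      out[i] = std::sqrt(ri * ri + zi * zi) / c1;
      if (zi > z1 && z1 <= 0.0) out[i] = std::sqrt(ri * ri + zi * zi) / c2;
      continue;
    }
    const double dz2 = zi - z1;
    auto f = [&](double q) {
      return std::sqrt(z1 * z1 + q * q) / c1 +
        std::sqrt(dz2 * dz2 + (ri - q) * (ri - q)) / c2;
    };
    // interval tolerance 3e-8 m: the travel time is stationary at the
    // minimizer, so the time error is O(curvature * tol^2) < 1e-15 s
    double a = 0.0, b = ri;
    double x1 = b - invphi * (b - a), x2 = a + invphi * (b - a);
    double f1 = f(x1), f2 = f(x2);
    for (int it = 0; it < 120 && (b - a) > 3e-8; ++it) {
      if (f1 < f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - invphi * (b - a); f1 = f(x1);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + invphi * (b - a); f2 = f(x2);
      }
    }
    out[i] = f(0.5 * (a + b));
  }
  return out;
}

// Refracted receive time through a fluid/tissue/fluid slab for scatterers
// below the tissue (reference-reflector echoes recorded through the sample).
// The ray from depth z > z1 + h to an element is found by bisection on the
// horizontal slowness p: the lateral offset
//   X(p) = (z1 + z - z1 - h) * p*c1/sqrt(1-(p*c1)^2) + h * p*c2/sqrt(1-(p*c2)^2)
// increases monotonically with p, so the p matching the element-scatterer
// separation r is unique; the travel time is sum(thickness_i/(c_i*cos(th_i))).
// [[Rcpp::export]]
NumericVector slab_rx_time_cpp(NumericVector r, NumericVector z,
                               double z1, double h, double c1, double c2) {
  const int n = r.size();
  NumericVector out(n);
  const double cmax = std::max(c1, c2);
  for (int i = 0; i < n; ++i) {
    const double ri = std::fabs(r[i]);
    const double zf = z1 + (z[i] - z1 - h);  // total fluid thickness
    if (ri < 1e-15) { out[i] = zf / c1 + h / c2; continue; }
    double plo = 0.0, phi = (1.0 - 1e-12) / cmax;
    for (int it = 0; it < 90; ++it) {
      const double p = 0.5 * (plo + phi);
      const double s1 = p * c1, s2 = p * c2;
      const double X = zf * s1 / std::sqrt(1.0 - s1 * s1) +
        h * s2 / std::sqrt(1.0 - s2 * s2);
      if (X < ri) plo = p; else phi = p;
    }
    const double p = 0.5 * (plo + phi);
    const double s1 = p * c1, s2 = p * c2;
    out[i] = zf / (c1 * std::sqrt(1.0 - s1 * s1)) +
      h / (c2 * std::sqrt(1.0 - s2 * s2));
  }
  return out;
}

// Accumulates echo wavelets into an RF array [ntx, nelem, ntime].
// Each (scatterer, element, transmit) contributes a copy of the pulse
// centered at tx_times(s, tx) + rx_times(s, e) with amplitude amps(s, e)
// (spherical spreading folded in by the caller). The pulse waveform is
// supplied as a finely oversampled lookup table covering [-half_dur,
// half_dur] (the caller controls the oversampling; linear interpolation in
// the table reproduces the continuous waveform without re-gridding the echo
// center itself, which stays exact).
// [[Rcpp::export]]
NumericVector accumulate_echoes_cpp(NumericMatrix tx_times, NumericMatrix rx_times,
                                    NumericMatrix amps, NumericVector pulse_table,
                                    double half_dur, double start_time,
                                    double fs, int ntime) {
  const int nscat = rx_times.nrow();
  const int nelem = rx_times.ncol();
  const int ntx = tx_times.ncol();
  const int ntab = pulse_table.size();
  const double dt_tab = 2.0 * half_dur / (ntab - 1);
  NumericVector rf(static_cast<R_xlen_t>(ntx) * nelem * ntime);
  double *prf = rf.begin();
  const double *ptab = pulse_table.begin();
  for (int s = 0; s < nscat; ++s) {
    for (int e = 0; e < nelem; ++e) {
      const double a = amps(s, e);
      const double rx = rx_times(s, e);
      for (int tx = 0; tx < ntx; ++tx) {
        const double t0 = tx_times(s, tx) + rx;
        const int i_lo = std::max(0, (int)std::ceil((t0 - half_dur - start_time) * fs));
        const int i_hi = std::min(ntime - 1, (int)std::floor((t0 + half_dur - start_time) * fs));
        double *col = prf + tx + static_cast<R_xlen_t>(ntx) * e;
        for (int i = i_lo; i <= i_hi; ++i) {
          const double u = (start_time + i / fs - t0 + half_dur) / dt_tab;
          const int j = static_cast<int>(u);
          if (j < 0 || j + 1 >= ntab) continue;
          const double fr = u - j;
          col[static_cast<R_xlen_t>(ntx) * nelem * i] +=
            a * (ptab[j] + fr * (ptab[j + 1] - ptab[j]));
        }
      }
    }
  }
  rf.attr("dim") = IntegerVector::create(ntx, nelem, ntime);
  return rf;
}
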