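#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Equilibrium occupancy of a 1D lattice by two hard-rod ligand species.
//
// w_net[a] / w_yoyo[a]: linear statistical weight (K * c) of a netropsin /
// YOYO window starting at 0-based bp a (0 = disallowed). Both vectors have
// length L; entries with a + f > L are ignored.
// Returns per-bp coverage probabilities for each species plus log Z.
//
// The partition function grows ~exp(0.5/bp) at typical weights, so the
// forward/backward recursions run in the linear domain on a small ring
// buffer that is rescaled whenever it grows large; log values are stored
// per position (exact, no approximation).
// [[Rcpp::export]]
List occupancy_core(NumericVector w_net, NumericVector w_yoyo,
                    int f_net, int f_yoyo) {
  const int L = w_net.size();
  const int fmax = std::max(f_net, f_yoyo);
  const int ring_n = fmax + 1;
  const double BIG = 1e250;

  std::vector<double> lzf(L + 1);
  {
    // ring[i % ring_n] holds the linear value of index i at current offset
    std::vector<double> ring(ring_n, 0.0);
    double off = 0.0;
    ring[0] = 1.0;
    lzf[0] = 0.0;
    for (int i = 1; i <= L; ++i) {
      double z = ring[(i - 1) % ring_n];
      if (i >= f_net)  z += w_net[i - f_net]   * ring[(i - f_net) % ring_n];
      if (i >= f_yoyo) z += w_yoyo[i - f_yoyo] * ring[(i - f_yoyo) % ring_n];
      ring[i % ring_n] = z;
      lzf[i] = (z > 0) ? std::log(z) + off : R_NegInf;
      if (z > BIG) {
        for (int k = 0; k < ring_n; ++k) ring[k] /= BIG;
        off += std::log(BIG);
      }
    }
  }
  const double lZ = lzf[L];

  // backward pass, streaming window start probabilities
  // lzb[k]: log partition of bases k..L (1-based), lzb[L+1] = 0
  std::vector<double> py(L, 0.0), pn(L, 0.0);
  {
    std::vector<double> ring(ring_n, 0.0);
    double off = 0.0;
    ring[(L + 1) % ring_n] = 1.0;
    std::vector<double> lzb_ring(ring_n, R_NegInf);
    lzb_ring[(L + 1) % ring_n] = 0.0;
    for (int k = L; k >= 1; --k) {
      double z = ring[(k + 1) % ring_n];
      if (k + f_net - 1 <= L)  z += w_net[k - 1]  * ring[(k + f_net) % ring_n];
      if (k + f_yoyo - 1 <= L) z += w_yoyo[k - 1] * ring[(k + f_yoyo) % ring_n];
      ring[k % ring_n] = z;
      lzb_ring[k % ring_n] = (z > 0) ? std::log(z) + off : R_NegInf;
      // probability of a window *starting* at bp k (0-based a = k-1):
      // Zf[k-1] * w * Zb[k+f] / Z
      const int a = k - 1;
      if (a + f_yoyo <= L && w_yoyo[a] > 0) {
        double lzb_end = lzb_ring[(k + f_yoyo) % ring_n];
        py[a] = std::exp(lzf[a] + std::log(w_yoyo[a]) + lzb_end - lZ);
      }
      if (a + f_net <= L && w_net[a] > 0) {
        double lzb_end = lzb_ring[(k + f_net) % ring_n];
        pn[a] = std::exp(lzf[a] + std::log(w_net[a]) + lzb_end - lZ);
      }
      if (z > BIG) {
        for (int j = 0; j < ring_n; ++j) ring[j] /= BIG;
        off += std::log(BIG);
      }
    }
  }

  // per-bp coverage = running sum over the f windows containing each bp
  NumericVector cov_y(L), cov_n(L);
  double ry = 0.0, rn = 0.0;
  for (int j = 0; j < L; ++j) {
    ry += py[j];
    rn += pn[j];
    if (j - f_yoyo >= 0) ry -= py[j - f_yoyo];
    if (j - f_net  >= 0) rn -= pn[j - f_net];
    cov_y[j] = ry;
    cov_n[j] = rn;
  }
  return List::create(_["yoyo"] = cov_y, _["netropsin"] = cov_n,
                      _["log_Z"] = lZ);
}

// Gaussian-blur a per-bp profile and integrate it into pixels of width
// bp_per_pixel (bp; need not be integer). Pixel p covers the continuous
// interval [p*B, (p+1)*B); bp j contributes its kernel mass over that
// interval (erf differences). Returns the raw integrated signal and the
// kernel mass per pixel; value = signal/mass is the truncated-kernel
// renormalized pixel mean used for barcodes.
// [[Rcpp::export]]
List pixelize_profile(NumericVector cov, double bp_per_pixel,
                      double sigma_bp, int n_pixels) {
  const int L = cov.size();
  const double B = bp_per_pixel;
  const double s2 = sigma_bp * std::sqrt(2.0);
  const double reach = (sigma_bp > 0) ? 6.0 * sigma_bp : 0.5;
  NumericVector signal(n_pixels), mass(n_pixels);

  const bool int_B = sigma_bp > 0 && std::fabs(B - std::round(B)) < 1e-9;
  if (int_B) {
    // integer pixel width: the kernel CDF is only ever evaluated at
    // half-integer offsets, so tabulate it once
    const int Bi = (int)std::round(B);
    const int r = (int)std::ceil(reach) + 1;
    // offset d = pixel_edge - j ranges over [-Bi - r - 1, Bi + r + 1]
    const int d0 = -Bi - r - 1, d1 = Bi + r + 1;
    std::vector<double> cdf(d1 - d0 + 1);
    for (int d = d0; d <= d1; ++d)
      cdf[d - d0] = 0.5 * (1.0 + std::erf((d - 0.5) / s2));
    for (int p = 0; p < n_pixels; ++p) {
      const int lo = p * Bi, hi = lo + Bi;
      const int j0 = std::max(0, lo - r);
      const int j1 = std::min(L - 1, hi + r - 1);
      double sig = 0.0, ms = 0.0;
      for (int j = j0; j <= j1; ++j) {
        const double m = cdf[hi - j - d0] - cdf[lo - j - d0];
        sig += cov[j] * m;
        ms += m;
      }
      signal[p] = sig;
      mass[p] = ms;
    }
    return List::create(_["signal"] = signal, _["mass"] = mass);
  }

  for (int p = 0; p < n_pixels; ++p) {
    const double lo = p * B, hi = (p + 1) * B;
    int j0 = std::max(0, (int)std::floor(lo - reach) - 1);
    int j1 = std::min(L - 1, (int)std::ceil(hi + reach));
    double sig = 0.0, ms = 0.0;
    if (sigma_bp > 0) {
      for (int j = j0; j <= j1; ++j) {
        const double c = j + 0.5;
        const double m = 0.5 * (std::erf((hi - c) / s2) - std::erf((lo - c) / s2));
        sig += cov[j] * m;
        ms += m;
      }
    } else {
      for (int j = j0; j <= j1; ++j) {
        const double c = j + 0.5;
        if (c >= lo && c < hi) { sig += cov[j]; ms += 1.0; }
      }
    }
    signal[p] = sig;
    mass[p] = ms;
  }
  return List::create(_["signal"] = signal, _["mass"] = mass);
}
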