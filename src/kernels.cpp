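#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. b, a normalised so a[0] == 1.
// zi is the per-unit-input steady-state filter state (scaled by the first
// sample before use) so a constant input produces no startup transient.
// step = +1 runs forward, -1 backward in place over the same buffers.
static void dfii_filter(const std::vector<double>& b,
                        const std::vector<double>& a,
                        const double* x, double* y, R_xlen_t n,
                        const std::vector<double>& zi, int step) {
  const size_t m = b.size();  // == a.size()
  std::vector<double> z(m - 1);
  R_xlen_t i0 = (step > 0) ? 0 : n - 1;
  double x0 = x[i0];
  for (size_t k = 0; k < m - 1; ++k) z[k] = zi[k] * x0;
  for (R_xlen_t c = 0, i = i0; c < n; ++c, i += step) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (size_t k = 0; k < m - 2; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
}

// Zero-phase forward-backward filtering with odd-reflection padding,
// matching the usual filtfilt construction.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b_, NumericVector a_,
                           NumericVector x, NumericVector zi_,
                           int padlen) {
  R_xlen_t n = x.size();
  size_t m = std::max(b_.size(), a_.size());
  if (n <= (R_xlen_t)(3 * padlen))
    stop("signal too short for filtfilt padding");
  std::vector<double> b(m, 0.0), a(m, 0.0), zi(m - 1, 0.0);
  for (R_xlen_t i = 0; i < b_.size(); ++i) b[i] = b_[i];
  for (R_xlen_t i = 0; i < a_.size(); ++i) a[i] = a_[i];
  for (R_xlen_t i = 0; i < zi_.size(); ++i) zi[i] = zi_[i];

  R_xlen_t ext_n = n + 2 * padlen;
  // grow-only workspace reused across calls (hot path: one call per
  // contiguous span of every recording)
  static std::vector<double> ext, tmp;
  if ((R_xlen_t)ext.size() < ext_n) { ext.resize(ext_n); tmp.resize(ext_n); }
  for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * x[0] - x[padlen - i];
  for (R_xlen_t i = 0; i < n; ++i) ext[padlen + i] = x[i];
  for (int i = 0; i < padlen; ++i)
    ext[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  dfii_filter(b, a, ext.data(), tmp.data(), ext_n, zi, +1);
  dfii_filter(b, a, tmp.data(), ext.data(), ext_n, zi, -1);

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ext[padlen + i];
  return out;
}

// Fused per-sample synthesis of a measured recording: slerp-interpolated
// gravity direction from a 1 Hz orientation table, isotropic Gaussian
// dynamics with per-minute SD, arm-swing sinusoid, and the per-device
// affine sensor model. Samples at or after row `split_row` (1-based;
// pass n+1 for a single-device recording) use the second device's
// gain/offset. Uses R's RNG (3 normal draws per sample).
// [[Rcpp::export]]
NumericMatrix cpp_assemble_measure(NumericVector t, NumericMatrix G,
                                   NumericVector sd_tab,
                                   NumericVector amp_tab,
                                   NumericVector u, double omega,
                                   double phase0, NumericMatrix gain,
                                   NumericMatrix offset_g,
                                   double split_row) {
  R_xlen_t n = t.size();
  R_xlen_t nsec = G.nrow();
  R_xlen_t nmin = sd_tab.size();
  NumericMatrix out(n, 3);
  const double* Gx = &G(0, 0);
  const double* Gy = &G(0, 1);
  const double* Gz = &G(0, 2);
  double* ox = &out(0, 0);
  double* oy = &out(0, 1);
  double* oz = &out(0, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double ti = t[i];
    R_xlen_t s = (R_xlen_t)ti;
    if (s > nsec - 2) s = nsec - 2;
    double f = ti - s;
    double gx = Gx[s] + f * (Gx[s + 1] - Gx[s]);
    double gy = Gy[s] + f * (Gy[s + 1] - Gy[s]);
    double gz = Gz[s] + f * (Gz[s + 1] - Gz[s]);
    double inv = 1.0 / std::sqrt(gx * gx + gy * gy + gz * gz);
    gx *= inv; gy *= inv; gz *= inv;
    R_xlen_t m = (R_xlen_t)(ti / 60.0);
    if (m > nmin - 1) m = nmin - 1;
    double sd = sd_tab[m];
    double sw = amp_tab[m];
    if (sw != 0.0) sw *= std::sin(omega * ti + phase0);
    int dev = (i + 1 >= split_row) ? 1 : 0;
    double x = gx + sd * norm_rand() + u[0] * sw;
    double y = gy + sd * norm_rand() + u[1] * sw;
    double z = gz + sd * norm_rand() + u[2] * sw;
    ox[i] = x * gain(dev, 0) + offset_g(dev, 0);
    oy[i] = y * gain(dev, 1) + offset_g(dev, 1);
    oz[i] = z * gain(dev, 2) + offset_g(dev, 2);
  }
  return out;
}

// Euclidean row magnitude of a 3-column matrix, scaled, in one pass
// (NA rows propagate).
// [[Rcpp::export]]
NumericVector cpp_magnitude(NumericMatrix X, double scale) {
  R_xlen_t n = X.nrow();
  NumericVector out(n);
  const double* x = &X(0, 0);
  const double* y = &X(0, 1);
  const double* z = &X(0, 2);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]) * scale;
  return out;
}

// Per-axis count / sum / sum-of-squares of a 3-column matrix binned by a
// 0-based index, in a single pass (used for still-window statistics).
// Columns: n, sum_x, ssq_x, sum_y, ssq_y, sum_z, ssq_z.
// [[Rcpp::export]]
NumericMatrix cpp_bin_moments_xyz(NumericMatrix X, IntegerVector idx,
                                  int nbins) {
  R_xlen_t n = X.nrow();
  if (idx.size() != n) stop("X and idx lengths differ");
  NumericMatrix out(nbins, 7);
  const double* x = &X(0, 0);
  const double* y = &X(0, 1);
  const double* z = &X(0, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = idx[i];
    if (b < 0 || b >= nbins) continue;
    out(b, 0) += 1.0;
    out(b, 1) += x[i]; out(b, 2) += x[i] * x[i];
    out(b, 3) += y[i]; out(b, 4) += y[i] * y[i];
    out(b, 5) += z[i]; out(b, 6) += z[i] * z[i];
  }
  return out;
}

// Bin index of uniformly spaced samples on an absolute clock: sample i
// (0-based) sits at off0 + i / rate seconds; bins are `width` seconds,
// numbered from the bin containing the first sample.
// [[Rcpp::export]]
IntegerVector cpp_seq_bins(double n, double off0, double rate,
                           double width) {
  R_xlen_t nn = (R_xlen_t)n;
  IntegerVector out(nn);
  double inv = 1.0 / rate;
  int b0 = (int)std::floor(off0 / width);
  for (R_xlen_t i = 0; i < nn; ++i)
    out[i] = (int)std::floor((off0 + i * inv) / width) - b0;
  return out;
}

// One-pass binned statistics: for a 0-based bin index per sample,
// returns per-bin count, sum, sum of squares and sum of absolute
// values, skipping NA. Bin indices outside [0, nbins) are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_bin_moments(NumericVector x, IntegerVector idx,
                              int nbins) {
  R_xlen_t n = x.size();
  if (idx.size() != n) stop("x and idx lengths differ");
  NumericMatrix out(nbins, 4);
  double* cnt = &out(0, 0);
  double* sum = &out(0, 1);
  double* ssq = &out(0, 2);
  double* sab = &out(0, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    int b = idx[i];
    if (ISNAN(v) || b < 0 || b >= nbins) continue;
    cnt[b] += 1.0;
    sum[b] += v;
    ssq[b] += v * v;
    sab[b] += std::fabs(v);
  }
  colnames(out) = CharacterVector::create("n", "sum", "sumsq", "sumabs");
  return out;
}

// Five-point least-squares slope magnitudes binned on the fly:
// d_i = (2 x[i+2] + x[i+1] - x[i-1] - 2 x[i-2]) * scale, valid when the
// whole window is finite. Returns per-bin count and sum of |d|.
// [[Rcpp::export]]
NumericMatrix cpp_jerk_bins(NumericVector x, IntegerVector idx, int nbins,
                            double scale) {
  R_xlen_t n = x.size();
  NumericMatrix out(nbins, 2);
  if (n < 5) return out;
  for (R_xlen_t i = 2; i < n - 2; ++i) {
    double a = x[i - 2], b = x[i - 1], c = x[i + 1], d = x[i + 2];
    if (ISNAN(a) || ISNAN(b) || ISNAN(x[i]) || ISNAN(c) || ISNAN(d))
      continue;
    int g = idx[i];
    if (g < 0 || g >= nbins) continue;
    double slope = (2.0 * d + c - b - 2.0 * a) * scale;
    out(g, 0) += 1.0;
    out(g, 1) += std::fabs(slope);
  }
  return out;
}

// Histogram counts per time bin: value bins are `nb` fixed-width bins
// from `lo`, clamped at the edges. Returns an nb x nbins matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_entropy_counts(NumericVector x, IntegerVector idx,
                                 int nbins, int nb, double lo,
                                 double width) {
  R_xlen_t n = x.size();
  IntegerMatrix out(nb, nbins);
  double invw = 1.0 / width;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (ISNAN(v)) continue;
    int g = idx[i];
    if (g < 0 || g >= nbins) continue;
    int b = (int)std::floor((v - lo) * invw);
    if (b < 0) b = 0;
    if (b > nb - 1) b = nb - 1;
    ++out(b, g);
  }
  return out;
}

// Cubic interpolating spline with not-a-knot boundary conditions
// (reproduces cubic polynomials exactly), evaluated at sorted query
// points. The tridiagonal system for the interior second derivatives
// M_1..M_{n-2} is solved with the Thomas algorithm, building the row
// coefficients on the fly (the not-a-knot rows are folded into the
// first and last equations via M0 = (1+r0) M1 - r0 M2 and its mirror)
// to keep the workspace at four arrays.
static void spline_fill(const double* t, const double* y, R_xlen_t n,
                        const double* tq, double* out, R_xlen_t nq,
                        std::vector<double>& h, std::vector<double>& invh,
                        std::vector<double>& cp, std::vector<double>& dp,
                        std::vector<double>& M) {
  R_xlen_t nn = n - 2;
  double r0 = h[0] * invh[1];
  double s0 = h[n - 2] * invh[n - 3];
  for (R_xlen_t i = 1; i <= nn; ++i) {
    double dl, dm, du;
    double rhs = 6.0 * ((y[i + 1] - y[i]) * invh[i] -
                        (y[i] - y[i - 1]) * invh[i - 1]);
    if (i == 1) {
      dl = 0.0;
      dm = 2.0 * (h[0] + h[1]) + h[0] * (1.0 + r0);
      du = h[1] - h[0] * r0;
    } else if (i == nn) {
      dl = h[n - 3] - h[n - 2] * s0;
      dm = 2.0 * (h[n - 3] + h[n - 2]) + h[n - 2] * (1.0 + s0);
      du = 0.0;
    } else {
      dl = h[i - 1];
      dm = 2.0 * (h[i - 1] + h[i]);
      du = h[i];
    }
    if (i == 1) {
      double invm = 1.0 / dm;
      cp[0] = du * invm;
      dp[0] = rhs * invm;
    } else {
      double invm = 1.0 / (dm - dl * cp[i - 2]);
      cp[i - 1] = du * invm;
      dp[i - 1] = (rhs - dl * dp[i - 2]) * invm;
    }
  }
  M[n - 2] = dp[nn - 1];
  for (R_xlen_t i = nn - 1; i >= 1; --i)
    M[i] = dp[i - 1] - cp[i - 1] * M[i + 1];
  M[0] = (1.0 + r0) * M[1] - r0 * M[2];
  M[n - 1] = (1.0 + s0) * M[n - 2] - s0 * M[n - 3];

  // Horner evaluation with per-interval cached coefficients (queries are
  // sorted, so each interval's cubic is set up once).
  R_xlen_t j = -1;
  double c0 = 0, c1 = 0, c2 = 0, c3 = 0, tj = 0;
  R_xlen_t jq = 0;
  for (R_xlen_t q = 0; q < nq; ++q) {
    double x = tq[q];
    if (j < 0 || (jq < n - 2 && t[jq + 1] < x)) {
      while (jq < n - 2 && t[jq + 1] < x) ++jq;
      j = jq;
      double hi = h[j], ih = invh[j];
      tj = t[j];
      c0 = y[j];
      c1 = (y[j + 1] - y[j]) * ih - hi * (2.0 * M[j] + M[j + 1]) / 6.0;
      c2 = 0.5 * M[j];
      c3 = (M[j + 1] - M[j]) * ih / 6.0;
    }
    double B = x - tj;
    out[q] = c0 + B * (c1 + B * (c2 + B * c3));
  }
}

static void check_spline_input(const double* t, R_xlen_t n,
                               std::vector<double>& h,
                               std::vector<double>& invh) {
  h.resize(n - 1);
  invh.resize(n - 1);
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    h[i] = t[i + 1] - t[i];
    if (!(h[i] > 0)) stop("sample times must be strictly increasing");
    invh[i] = 1.0 / h[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_spline_resample(NumericVector t, NumericVector y,
                                  NumericVector tq) {
  R_xlen_t n = t.size();
  if (n < 4) stop("need at least 4 samples for cubic resampling");
  if (y.size() != n) stop("t and y lengths differ");
  static std::vector<double> h, invh, cp, dp, M;
  cp.resize(n - 2); dp.resize(n - 2); M.resize(n);
  check_spline_input(t.begin(), n, h, invh);
  NumericVector out(tq.size());
  spline_fill(t.begin(), y.begin(), n, tq.begin(), out.begin(), tq.size(),
              h, invh, cp, dp, M);
  return out;
}

// Fused resample-to-magnitude: evaluates the three per-axis splines at
// the query points and returns the Euclidean magnitude (times `scale`)
// without materialising the per-axis resampled signal.
// [[Rcpp::export]]
NumericVector cpp_spline_magnitude(NumericVector t, NumericMatrix Y,
                                   NumericVector tq, double scale) {
  R_xlen_t n = t.size();
  if (n < 4) stop("need at least 4 samples for cubic resampling");
  if (Y.nrow() != n) stop("t and Y lengths differ");
  static std::vector<double> h, invh, cp, dp, M, tmp;
  cp.resize(n - 2); dp.resize(n - 2); M.resize(n);
  check_spline_input(t.begin(), n, h, invh);
  R_xlen_t nq = tq.size();
  NumericVector out(nq);
  tmp.resize(nq);
  for (int j = 0; j < 3; ++j) {
    spline_fill(t.begin(), &Y(0, j), n, tq.begin(), tmp.data(), nq,
                h, invh, cp, dp, M);
    if (j == 0)
      for (R_xlen_t q = 0; q < nq; ++q) out[q] = tmp[q] * tmp[q];
    else
      for (R_xlen_t q = 0; q < nq; ++q) out[q] += tmp[q] * tmp[q];
  }
  for (R_xlen_t q = 0; q < nq; ++q) out[q] = std::sqrt(out[q]) * scale;
  return out;
}

// Multi-column variant sharing one workspace (used for x/y/z axes).
// [[Rcpp::export]]
NumericMatrix cpp_spline_resample_mat(NumericVector t, NumericMatrix Y,
                                      NumericVector tq) {
  R_xlen_t n = t.size();
  if (n < 4) stop("need at least 4 samples for cubic resampling");
  if (Y.nrow() != n) stop("t and Y lengths differ");
  static std::vector<double> h, invh, cp, dp, M;
  cp.resize(n - 2); dp.resize(n - 2); M.resize(n);
  check_spline_input(t.begin(), n, h, invh);
  NumericMatrix out(tq.size(), Y.ncol());
  for (int j = 0; j < Y.ncol(); ++j)
    spline_fill(t.begin(), &Y(0, j), n, tq.begin(), &out(0, j), tq.size(),
                h, invh, cp, dp, M);
  return out;
}
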