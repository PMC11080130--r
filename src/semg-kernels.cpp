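// Compiled kernels for the hot paths: windowed continuous wavelet
// transform (FFT convolution against precomputed kernel spectra, FFTW
// with plan reuse), direct-form IIR filtering, and motor-unit
// action-potential train superposition.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>

using namespace arma;

namespace {

// RAII wrapper around one FFT size: forward + backward c2c plans sharing
// in/out buffers.
struct FftPair {
  int n;
  fftw_complex *in, *out;
  fftw_plan fwd, bwd;
  explicit FftPair(int nfft) : n(nfft) {
    in = (fftw_complex*)fftw_malloc(sizeof(fftw_complex) * n);
    out = (fftw_complex*)fftw_malloc(sizeof(fftw_complex) * n);
    fwd = fftw_plan_dft_1d(n, in, out, FFTW_FORWARD, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_1d(n, in, out, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FftPair() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
    fftw_free(in);
    fftw_free(out);
  }
};

inline std::complex<double>* as_cplx(fftw_complex* p) {
  return reinterpret_cast<std::complex<double>*>(p);
}

}  // namespace

// Continuous wavelet coefficients of a single window.
// kernfft holds, per scale (column), the FFT of the reversed, circularly
// wrapped wavelet kernel g(u) = psi*(u/a)/sqrt(a); nfft must satisfy
// nfft >= L + 2h + 1 so the circular convolution never wraps onto the
// window support.  Returns scales x L complex coefficients.
// [[Rcpp::export]]
arma::cx_mat cpp_cwt_window(const arma::vec& x, const arma::cx_mat& kernfft) {
  const int nfft = kernfft.n_rows;
  const int S = kernfft.n_cols;
  const int L = x.n_elem;
  FftPair fft(nfft);
  std::complex<double>* in = as_cplx(fft.in);
  std::complex<double>* out = as_cplx(fft.out);
  for (int i = 0; i < nfft; ++i) in[i] = (i < L) ? x[i] : 0.0;
  fftw_execute(fft.fwd);
  std::vector<std::complex<double>> fx(out, out + nfft);
  cx_mat C(S, L);
  const double inv_n = 1.0 / nfft;
  for (int s = 0; s < S; ++s) {
    const std::complex<double>* k = kernfft.colptr(s);
    for (int i = 0; i < nfft; ++i) in[i] = fx[i] * k[i];
    fftw_execute(fft.bwd);
    for (int b = 0; b < L; ++b) C(s, b) = out[b] * inv_n;
  }
  return C;
}

// Sample excess kurtosis (bias-corrected, the G2 estimator).
static double excess_kurtosis_g2(const vec& x) {
  const double m = (double)x.n_elem;
  if (m < 4.0) return datum::nan;
  const double xb = mean(x);
  const double s = stddev(x);  // n-1 denominator
  if (s <= 0.0) return datum::nan;
  const double s4 = accu(pow((x - xb) / s, 4));
  return m * (m + 1.0) / ((m - 1.0) * (m - 2.0) * (m - 3.0)) * s4 -
         3.0 * (m - 1.0) * (m - 1.0) / ((m - 2.0) * (m - 3.0));
}

// Gaussian-kernel density of pooled values on an m-point equispaced grid
// spanning their range (linear binning, Scott's-rule bandwidth), then
// the G2 kurtosis of the m density ordinates.  NaN on degenerate input.
static double kde_grid_kurtosis(const vec& v, const int m) {
  const double lo = v.min(), hi = v.max();
  if (!(hi > lo)) return datum::nan;
  const double n = (double)v.n_elem;
  const double delta = (hi - lo) / (double)(m - 1);
  const double bw = stddev(v) * std::pow(n, -0.2);
  if (!(bw > 0.0)) return datum::nan;
  vec cnt(m, fill::zeros);
  for (uword i = 0; i < v.n_elem; ++i) {
    double pos = (v[i] - lo) / delta;
    int j = (int)std::floor(pos);
    if (j >= m - 1) { cnt[m - 1] += 1.0; continue; }
    double w = pos - (double)j;
    cnt[j] += 1.0 - w;
    cnt[j + 1] += w;
  }
  vec phi(m);
  const double norm = 1.0 / (bw * std::sqrt(2.0 * datum::pi));
  for (int k = 0; k < m; ++k) {
    double z = (double)k * delta / bw;
    phi[k] = norm * std::exp(-0.5 * z * z);
  }
  vec pdf(m, fill::zeros);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    for (int j = 0; j < m; ++j) acc += cnt[j] * phi[std::abs(i - j)];
    pdf[i] = acc / n;
  }
  return excess_kurtosis_g2(pdf);
}

// Wavelet-domain features for a batch of analysis windows.
// X: L x W matrix (one window per column); kernfft as in cpp_cwt_window.
// Returns per-window per-scale power (S x W), wavelet entropy (natural
// log), and the kurtosis of the kernel-density estimate of the pooled
// coefficient moduli (m grid points).
// [[Rcpp::export]]
Rcpp::List cpp_cwt_features(const arma::mat& X, const arma::cx_mat& kernfft,
                            const int m) {
  const int nfft = kernfft.n_rows;
  const int S = kernfft.n_cols;
  const int L = X.n_rows;
  const int W = X.n_cols;
  mat power(S, W);
  vec we(W), kurt(W);
  FftPair fft(nfft);
  std::complex<double>* in = as_cplx(fft.in);
  std::complex<double>* out = as_cplx(fft.out);
  std::vector<std::complex<double>> fx(nfft);
  const double inv_n = 1.0 / nfft;
  vec pooled(S * L);
  for (int w = 0; w < W; ++w) {
    const double* xw = X.colptr(w);
    for (int i = 0; i < nfft; ++i) in[i] = (i < L) ? xw[i] : 0.0;
    fftw_execute(fft.fwd);
    std::copy(out, out + nfft, fx.begin());
    for (int s = 0; s < S; ++s) {
      const std::complex<double>* k = kernfft.colptr(s);
      for (int i = 0; i < nfft; ++i) in[i] = fx[i] * k[i];
      fftw_execute(fft.bwd);
      double acc = 0.0;
      for (int b = 0; b < L; ++b) {
        double md = std::abs(out[b]) * inv_n;
        pooled[s * L + b] = md;
        acc += md * md;
      }
      power(s, w) = acc / (double)L;
    }
    const double tot = accu(power.col(w));
    if (tot > 0.0) {
      double h_ent = 0.0;
      for (int s = 0; s < S; ++s) {
        double h = power(s, w) / tot;
        if (h > 0.0) h_ent -= h * std::log(h);
      }
      we[w] = h_ent;
    } else {
      we[w] = datum::nan;
    }
    kurt[w] = kde_grid_kurtosis(pooled, m);
  }
  return Rcpp::List::create(Rcpp::Named("power") = power,
                            Rcpp::Named("we") = we,
                            Rcpp::Named("kurtosis") = kurt);
}

// Direct-form-II-transposed IIR filter (the classic difference
// equation), a[0] must be 1.
// [[Rcpp::export]]
arma::vec cpp_iir_filter(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns + 1, 0.0);
  vec y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j <= ns; ++j) {
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      z[j - 1] = bj * xi - aj * yi + z[j];
    }
    y[i] = yi;
  }
  return y;
}

// Superpose motor-unit action-potential trains over channels.
// starts[i]: 0-based sample indices where unit i's template begins;
// templates[i]: the unit's waveform; gains/delays: unit x channel.
// [[Rcpp::export]]
arma::mat cpp_superpose(const int ns, const int n_ch,
                        const Rcpp::List& starts, const Rcpp::List& templates,
                        const arma::mat& gains, const arma::imat& delays) {
  mat Y(n_ch, ns, fill::zeros);
  const int n_mu = starts.size();
  for (int i = 0; i < n_mu; ++i) {
    Rcpp::IntegerVector st = starts[i];
    Rcpp::NumericVector tp = templates[i];
    const int tl = tp.size();
    for (int c = 0; c < n_ch; ++c) {
      const double g = gains(i, c);
      const int d = delays(i, c);
      for (int k = 0; k < st.size(); ++k) {
        const int s0 = st[k] + d;
        const int u0 = s0 < 0 ? -s0 : 0;
        const int u1 = std::min(tl, ns - s0);
        for (int u = u0; u < u1; ++u) Y(c, s0 + u) += g * tp[u];
      }
    }
  }
  return Y;
}
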