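// Streaming per-trial model pipeline: spatial filtering in the frequency
// domain, temporal convolution, quadrature energy, delayed divisive
// normalization with channel pooling, and the reductions needed by the
// switch stage (channel-collapsed response, engagement, spatial map).
//
// The R-level run_model() composes the same stages from the exported
// module functions; this path avoids materializing the full 5-D response
// tensors when many trials are simulated. Per-channel energy and lowpass
// stages are held in single precision to bound the working set; all
// reductions accumulate in double precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat band_matrix(int n, const arma::vec& g) {
  int r = (g.n_elem - 1) / 2;
  arma::fmat C(n, n, arma::fill::zeros);
  for (int j = -r; j <= r; ++j) {
    for (int i = 0; i < n; ++i) {
      int s = i + j;
      if (s >= 0 && s < n) C(i, s) = (float)g(j + r);
    }
  }
  return C;
}

// [[Rcpp::export]]
List cpp_stream_model(const arma::cube& frames, const List& transfers,
                      const List& hts, int nth, int nom,
                      const List& pool_idx, const List& pool_w,
                      double a_iir, const arma::vec& gk,
                      double sigma, double n_exp, bool return_collapsed) {
  const int ny = frames.n_rows, nx = frames.n_cols, nt = frames.n_slices;
  const int npix = ny * nx;
  arma::cx_mat G0 = as<arma::cx_mat>(transfers[0]);
  const int PY = G0.n_rows, PX = G0.n_cols;

  // forward FFTs of all (zero-padded) frames
  std::vector<arma::cx_mat> Fr(nt);
  {
    arma::mat zim(ny, nx, arma::fill::zeros);
    for (int t = 0; t < nt; ++t) {
      arma::cx_mat P(PY, PX, arma::fill::zeros);
      P.submat(0, 0, ny - 1, nx - 1) =
        arma::cx_mat(frames.slice(t), zim);
      Fr[t] = arma::fft2(P);
    }
  }

  arma::fmat Cy = band_matrix(ny, gk);
  arma::fmat CxT = band_matrix(nx, gk).t();
  const float a = (float)a_iir;

  std::vector<arma::fmat> RE(nth * nom), RL(nth * nom);
  arma::fmat rs_re(npix, nt), rs_im(npix, nt);
  for (int i = 0; i < nth; ++i) {
    arma::fmat HT = arma::conv_to<arma::fmat>::from(as<arma::mat>(hts[i]));
    for (int j = 0; j < nom; ++j) {
      arma::cx_mat G = as<arma::cx_mat>(transfers[i * nom + j]);
      for (int t = 0; t < nt; ++t) {
        arma::cx_mat r = arma::ifft2(Fr[t] % G);
        float* pre = rs_re.colptr(t);
        float* pim = rs_im.colptr(t);
        for (int x = 0; x < nx; ++x) {
          const std::complex<double>* cp = r.colptr(x);
          for (int y = 0; y < ny; ++y) {
            pre[x * ny + y] = (float)cp[y].real();
            pim[x * ny + y] = (float)cp[y].imag();
          }
        }
      }
      arma::fmat e = arma::square(rs_re * HT) + arma::square(rs_im * HT);
      // unit-gain exponential temporal lowpass
      arma::fmat L(npix, nt);
      L.col(0) = (1.0f - a) * e.col(0);
      for (int t = 1; t < nt; ++t)
        L.col(t) = a * L.col(t - 1) + (1.0f - a) * e.col(t);
      // separable spatial Gaussian (unit-sum, truncated at the borders)
      for (int t = 0; t < nt; ++t) {
        arma::fmat M(L.colptr(t), ny, nx, false, true);
        M = Cy * M * CxT;
      }
      RE[i * nom + j] = std::move(e);
      RL[i * nom + j] = std::move(L);
    }
  }

  arma::mat engagement(nth, nom);
  arma::mat coll(npix, nt, arma::fill::zeros);
  arma::vec smap(npix, arma::fill::zeros);
  const double sig_n = std::pow(sigma, n_exp);
  arma::fmat rlp(npix, nt);
  for (int i = 0; i < nth; ++i) {
    for (int j = 0; j < nom; ++j) {
      const int idx = i * nom + j;
      arma::uvec nb = as<arma::uvec>(pool_idx[idx]);   // 0-based channel ids
      arma::vec w = as<arma::vec>(pool_w[idx]);
      rlp.zeros();
      for (arma::uword q = 0; q < nb.n_elem; ++q)
        rlp += (float)w(q) * RL[nb(q)];
      const arma::fmat& e = RE[idx];
      double eng = 0.0;
      for (int t = 0; t < nt; ++t) {
        const float* ep = e.colptr(t);
        const float* lp = rlp.colptr(t);
        double* cp = coll.colptr(t);
        for (int p = 0; p < npix; ++p) {
          double en = std::pow((double)ep[p], n_exp);
          double rn = en / (sig_n + std::pow((double)lp[p], n_exp));
          eng += rn;
          cp[p] += rn;
          smap(p) += rn;
        }
      }
      engagement(i, j) = eng;
    }
  }
  coll /= (double)(nth * nom);

  // measured-change series: spatial max of positive temporal differences
  arma::vec meas(nt, arma::fill::zeros);
  for (int t = 1; t < nt; ++t) {
    double m = 0.0;
    const double* c0 = coll.colptr(t - 1);
    const double* c1 = coll.colptr(t);
    for (int p = 0; p < npix; ++p) {
      double d = c1[p] - c0[p];
      if (d > m) m = d;
    }
    meas(t) = m;
  }

  List out = List::create(
    Named("meas") = meas,
    Named("engagement") = engagement,
    Named("spatial_map") = arma::mat(smap.memptr(), ny, nx));
  if (return_collapsed) out["collapsed"] = coll;
  return out;
}
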