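// Low-level array kernels for the IOSI pipeline.
//
// All filters use edge replication (clamped indices) so that a spatially
// constant frame is preserved exactly, matching the documented pipeline
// conventions. The fused filter+block-mean kernel accumulates exactly the
// same clamped taps as the sequential pair, so the two routes agree to
// floating-point rounding.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Filter the columns of A (i.e. along the row index) with kernel k,
// clamped at the edges. A is (n x m); result overwrites B (n x m).
static void filter_down_columns(const arma::mat& A, arma::mat& B,
                                const arma::vec& k) {
  const int n = A.n_rows, m = A.n_cols, h = ((int)k.n_elem - 1) / 2;
  B.zeros(n, m);
  // operate on transposed data for contiguous access
  arma::mat At = A.t();                     // m x n, columns = rows of A
  arma::mat Bt(m, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int d = -h; d <= h; ++d)
      Bt.col(i) += k(d + h) * At.col(clampi(i + d, 0, n - 1));
  B = Bt.t();
}

static void filter_across_columns(const arma::mat& A, arma::mat& B,
                                  const arma::vec& k) {
  const int m = A.n_cols, h = ((int)k.n_elem - 1) / 2;
  B.zeros(A.n_rows, m);
  for (int j = 0; j < m; ++j)
    for (int d = -h; d <= h; ++d)
      B.col(j) += k(d + h) * A.col(clampi(j + d, 0, m - 1));
}

// [[Rcpp::export]]
arma::cube cpp_sep_filter(const arma::cube& X, const arma::vec& k) {
  arma::cube Z(X.n_rows, X.n_cols, X.n_slices);
  arma::mat B;
  for (arma::uword t = 0; t < X.n_slices; ++t) {
    filter_down_columns(X.slice(t), B, k);
    filter_across_columns(B, Z.slice(t), k);
  }
  return Z;
}

// [[Rcpp::export]]
arma::cube cpp_block_mean(const arma::cube& X, const int f) {
  const int n = X.n_rows / f, m = X.n_cols / f;
  arma::cube Z(n, m, X.n_slices);
  const double inv = 1.0 / (f * f);
  for (arma::uword t = 0; t < X.n_slices; ++t) {
    const arma::mat& A = X.slice(t);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i)
        Z(i, j, t) = arma::accu(A.submat(i * f, j * f,
                                         i * f + f - 1, j * f + f - 1)) * inv;
  }
  return Z;
}

// Weights of the composition (block mean of f) o (clamped filter k), along
// one axis of length n. Row I of the result holds the raw-index weights for
// analysis index I, restricted to the support [I*f - h, I*f + f - 1 + h].
static arma::mat fused_weights(int n, int f, const arma::vec& k, int& off) {
  const int h = ((int)k.n_elem - 1) / 2, nf = n / f, sup = f + 2 * h;
  arma::mat W(nf, sup, arma::fill::zeros);
  off = h;
  for (int I = 0; I < nf; ++I)
    for (int b = I * f; b < I * f + f; ++b)
      for (int d = -h; d <= h; ++d) {
        int r = clampi(b + d, 0, n - 1);
        int c = r - (I * f - h);
        if (c >= 0 && c < sup) W(I, c) += k(d + h) / f;
      }
  return W;
}

// [[Rcpp::export]]
arma::cube cpp_filter_block(const arma::cube& X, const arma::vec& k,
                            const int f) {
  const int n = X.n_rows, m = X.n_cols;
  const int nf = n / f, mf = m / f, h = ((int)k.n_elem - 1) / 2;
  int off;
  arma::mat Wr = fused_weights(n, f, k, off);
  arma::mat Wc = fused_weights(m, f, k, off);
  const int sup = f + 2 * h;
  arma::cube Z(nf, mf, X.n_slices);
  arma::mat Y(nf, m);
  for (arma::uword t = 0; t < X.n_slices; ++t) {
    const arma::mat& A = X.slice(t);
    Y.zeros();
    for (int I = 0; I < nf; ++I) {
      const int r0 = I * f - h;
      for (int c = 0; c < sup; ++c) {
        int r = r0 + c;
        if (r < 0 || r >= n) continue;   // clamped taps were folded inward
        double w = Wr(I, c);
        if (w != 0.0) Y.row(I) += w * A.row(r);
      }
    }
    arma::mat& S = Z.slice(t);
    S.zeros();
    for (int J = 0; J < mf; ++J) {
      const int c0 = J * f - h;
      for (int c = 0; c < sup; ++c) {
        int cc = c0 + c;
        if (cc < 0 || cc >= m) continue;
        double w = Wc(J, c);
        if (w != 0.0) S.col(J) += w * Y.col(cc);
      }
    }
  }
  return Z;
}

// Streaming synthesis + reduction for simulation loops: generates each raw
// frame, applies the fused filter+block-mean reduction, and keeps only the
// analysis-grid result. Numerically identical (to rounding) to
// cpp_phantom_stack followed by cpp_filter_block, without holding the raw
// movie in memory.
// [[Rcpp::export]]
arma::cube cpp_phantom_processed(const arma::mat& V, const arma::mat& G,
                                 const arma::vec& s, const double amplitude,
                                 const double sd, const arma::vec& k,
                                 const int f) {
  const int n = V.n_rows, m = V.n_cols;
  const int nf = n / f, mf = m / f, h = ((int)k.n_elem - 1) / 2;
  int off;
  arma::mat Wr = fused_weights(n, f, k, off);
  arma::mat Wc = fused_weights(m, f, k, off);
  const int sup = f + 2 * h;
  const arma::uword nt = s.n_elem;
  arma::cube Z(nf, mf, nt);
  arma::mat frame(n, m), Y(nf, m);
  for (arma::uword t = 0; t < nt; ++t) {
    frame = V % (1.0 + amplitude * s(t) * G);
    if (sd > 0) {
      arma::mat eps(n, m, arma::fill::randn);
      frame %= (1.0 + sd * eps);
    }
    Y.zeros();
    for (int I = 0; I < nf; ++I) {
      const int r0 = I * f - h;
      for (int c = 0; c < sup; ++c) {
        int r = r0 + c;
        if (r < 0 || r >= n) continue;
        double w = Wr(I, c);
        if (w != 0.0) Y.row(I) += w * frame.row(r);
      }
    }
    arma::mat S(nf, mf, arma::fill::zeros);
    for (int J = 0; J < mf; ++J) {
      const int c0 = J * f - h;
      for (int c = 0; c < sup; ++c) {
        int cc = c0 + c;
        if (cc < 0 || cc >= m) continue;
        double w = Wc(J, c);
        if (w != 0.0) S.col(J) += w * Y.col(cc);
      }
    }
    Z.slice(t) = S;
  }
  return Z;
}

// Synthesize one trial's raw reflectance movie:
//   R(x, t) = V(x) * (1 + amplitude * G(x) * s(t)) * (1 + sd * eps(x, t))
// eps are iid standard normals drawn from R's RNG (seed with set.seed()).
// [[Rcpp::export]]
arma::cube cpp_phantom_stack(const arma::mat& V, const arma::mat& G,
                             const arma::vec& s, const double amplitude,
                             const double sd) {
  const arma::uword n = V.n_rows, m = V.n_cols, nt = s.n_elem;
  arma::cube out(n, m, nt);
  for (arma::uword t = 0; t < nt; ++t) {
    arma::mat mean_t = V % (1.0 + amplitude * s(t) * G);
    if (sd > 0) {
      arma::mat eps(n, m, arma::fill::randn);
      out.slice(t) = mean_t % (1.0 + sd * eps);
    } else {
      out.slice(t) = mean_t;
    }
  }
  return out;
}
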