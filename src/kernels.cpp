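// Fused single-pass kernels for the decoder's non-GEMM layers. The data
// layouts match the R side: feature maps are matrices whose rows are
// grouped per feature channel in contiguous blocks of N rows (N = 1 for
// the spatial stage), and whose columns run over (time, trial).
#include <Rcpp.h>
using namespace Rcpp;

// Per-feature-channel mean and (population) variance over contiguous row
// blocks of size N and all columns.
// [[Rcpp::export]]
List bnStatsGrouped(const NumericMatrix& A, const int N) {
  const int nr = A.nrow(), nc = A.ncol(), G = nr / N;
  std::vector<double> s1(G, 0.0), s2(G, 0.0);
  const double* a = A.begin();
  for (int j = 0; j < nc; ++j) {
    const double* col = a + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const double v = col[i];
      const int g = i / N;
      s1[g] += v;
      s2[g] += v * v;
    }
  }
  const double cnt = (double)N * nc;
  NumericVector mean(G), var(G);
  for (int g = 0; g < G; ++g) {
    mean[g] = s1[g] / cnt;
    double v = s2[g] / cnt - mean[g] * mean[g];
    var[g] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Normalize and scale/shift in one pass; returns the normalized
// activations (xhat) and the BN output.
// [[Rcpp::export]]
List bnApplyGrouped(const NumericMatrix& A, const int N,
                    const NumericVector& mean, const NumericVector& inv,
                    const NumericVector& gamma, const NumericVector& beta) {
  const int nr = A.nrow(), nc = A.ncol();
  NumericMatrix xhat(nr, nc), out(nr, nc);
  std::vector<double> mr(nr), ir(nr), gr(nr), br(nr);
  for (int i = 0; i < nr; ++i) {
    const int g = i / N;
    mr[i] = mean[g]; ir[i] = inv[g]; gr[i] = gamma[g]; br[i] = beta[g];
  }
  const double* a = A.begin();
  double* xh = xhat.begin();
  double* o = out.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const double z = (a[off + i] - mr[i]) * ir[i];
      xh[off + i] = z;
      o[off + i] = z * gr[i] + br[i];
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// Normalization only (no scale/shift); used when the affine part of BN is
// folded into the following convolution.
// [[Rcpp::export]]
NumericMatrix bnNormalizeGrouped(const NumericMatrix& A, const int N,
                                 const NumericVector& mean,
                                 const NumericVector& inv) {
  const int nr = A.nrow(), nc = A.ncol();
  NumericMatrix xhat(nr, nc);
  std::vector<double> mr(nr), ir(nr);
  for (int i = 0; i < nr; ++i) {
    const int g = i / N;
    mr[i] = mean[g]; ir[i] = inv[g];
  }
  const double* a = A.begin();
  double* xh = xhat.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i)
      xh[off + i] = (a[off + i] - mr[i]) * ir[i];
  }
  return xhat;
}

// Batch-norm backward taking the gradient at xhat directly (dH =
// gamma (.) d(BN output)); returns the input gradient plus the
// scale/shift gradients (recovered as sums of dH/gamma products).
// [[Rcpp::export]]
List bnBackwardFromXhat(const NumericMatrix& dH, const NumericMatrix& xhat,
                        const NumericVector& inv,
                        const NumericVector& gamma, const int N) {
  const int nr = dH.nrow(), nc = dH.ncol(), G = nr / N;
  std::vector<double> sH(G, 0.0), sHX(G, 0.0);
  const double* dh = dH.begin();
  const double* xh = xhat.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int g = i / N;
      sH[g] += dh[off + i];
      sHX[g] += dh[off + i] * xh[off + i];
    }
  }
  const double cnt = (double)N * nc;
  NumericVector dgamma(G), dbeta(G);
  std::vector<double> c1(nr), c2(nr), ir(nr);
  for (int g = 0; g < G; ++g) {
    const double gm = gamma[g] != 0 ? gamma[g] : 1e-300;
    dgamma[g] = sHX[g] / gm;
    dbeta[g] = sH[g] / gm;
  }
  for (int i = 0; i < nr; ++i) {
    const int g = i / N;
    c1[i] = sH[g] / cnt;
    c2[i] = sHX[g] / cnt;
    ir[i] = inv[g];
  }
  NumericMatrix dX(nr, nc);
  double* dx = dX.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i)
      dx[off + i] = ir[i] * (dh[off + i] - c1[i] - xh[off + i] * c2[i]);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Batch-norm backward for row-grouped statistics: returns the input
// gradient and the per-channel scale/shift gradients.
// [[Rcpp::export]]
List bnBackwardGroupedCpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                          const NumericVector& inv,
                          const NumericVector& gamma, const int N) {
  const int nr = dY.nrow(), nc = dY.ncol(), G = nr / N;
  std::vector<double> sDg(G, 0.0), sDb(G, 0.0), m1(G, 0.0), m2(G, 0.0);
  const double* dy = dY.begin();
  const double* xh = xhat.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int g = i / N;
      const double d = dy[off + i], x = xh[off + i];
      sDb[g] += d;
      sDg[g] += d * x;
      m1[g] += d * gamma[g];
      m2[g] += d * gamma[g] * x;
    }
  }
  const double cnt = (double)N * nc;
  NumericVector dgamma(G), dbeta(G);
  std::vector<double> c1(nr), c2(nr), ir(nr), gr(nr);
  for (int g = 0; g < G; ++g) {
    dgamma[g] = sDg[g];
    dbeta[g] = sDb[g];
  }
  for (int i = 0; i < nr; ++i) {
    const int g = i / N;
    c1[i] = m1[g] / cnt;
    c2[i] = m2[g] / cnt;
    ir[i] = inv[g];
    gr[i] = gamma[g];
  }
  NumericMatrix dX(nr, nc);
  double* dx = dX.begin();
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i)
      dx[off + i] = ir[i] * (dy[off + i] * gr[i] - c1[i] -
                             xh[off + i] * c2[i]);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ELU (alpha = 1) forward.
// [[Rcpp::export]]
NumericMatrix eluForwardCpp(const NumericMatrix& Y) {
  const int nr = Y.nrow(), nc = Y.ncol();
  NumericMatrix E(nr, nc);
  const double* y = Y.begin();
  double* e = E.begin();
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i)
    e[i] = y[i] > 0 ? y[i] : std::expm1(y[i]);
  return E;
}

// ELU backward: derivative is 1 above zero, exp(y) = E + 1 below.
// [[Rcpp::export]]
NumericMatrix eluBackwardCpp(const NumericMatrix& dE,
                             const NumericMatrix& E) {
  const int nr = dE.nrow(), nc = dE.ncol();
  NumericMatrix dY(nr, nc);
  const double* de = dE.begin();
  const double* e = E.begin();
  double* dy = dY.begin();
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i)
    dy[i] = e[i] > 0 ? de[i] : de[i] * (e[i] + 1.0);
  return dY;
}

// Average pooling over non-overlapping windows of K time columns.
// E is C x (M*B) with columns (m, b), m fastest; output C x ((M/K)*B).
// [[Rcpp::export]]
NumericMatrix poolForwardCpp(const NumericMatrix& E, const int K) {
  const int C = E.nrow(), nc = E.ncol(), np = nc / K;
  NumericMatrix P(C, np);
  const double* e = E.begin();
  double* p = P.begin();
  for (int jp = 0; jp < np; ++jp) {
    double* pc = p + (size_t)jp * C;
    for (int k = 0; k < K; ++k) {
      const double* ec = e + ((size_t)jp * K + k) * C;
      for (int i = 0; i < C; ++i) pc[i] += ec[i];
    }
    for (int i = 0; i < C; ++i) pc[i] /= K;
  }
  return P;
}

// Pooling backward: spread 1/K of each pooled gradient over its window.
// [[Rcpp::export]]
NumericMatrix poolBackwardCpp(const NumericMatrix& dP, const int K) {
  const int C = dP.nrow(), np = dP.ncol();
  NumericMatrix dE(C, np * K);
  const double* dp = dP.begin();
  double* de = dE.begin();
  for (int jp = 0; jp < np; ++jp) {
    const double* pc = dp + (size_t)jp * C;
    for (int k = 0; k < K; ++k) {
      double* ec = de + ((size_t)jp * K + k) * C;
      for (int i = 0; i < C; ++i) ec[i] = pc[i] / K;
    }
  }
  return dE;
}

// im2col along time for one temporal branch: X is N x (M*B), columns
// (m, b) with m fastest; output is S x (N*M*B) where row s holds the
// input shifted by (s - (S-1)/2 - 1) samples within each trial, zero
// outside, flattened electrode-fastest.
// [[Rcpp::export]]
NumericMatrix im2colTimeCpp(const NumericMatrix& X, const int M,
                            const int S) {
  const int N = X.nrow(), nc = X.ncol();
  const int h = (S - 1) / 2;
  NumericMatrix out(S, (size_t)N * nc);
  const double* x = X.begin();
  double* o = out.begin();
  for (int j = 0; j < nc; ++j) {
    const int m = j % M;
    for (int s = 0; s < S; ++s) {
      const int off = s - h;
      const int ms = m + off;
      if (ms < 0 || ms >= M) continue;
      const double* src = x + (size_t)(j + off) * N;
      // destination: row s, columns j*N .. j*N + N - 1
      double* dst = o + (size_t)j * N * S + s;
      for (int n = 0; n < N; ++n) dst[(size_t)n * S] = src[n];
    }
  }
  return out;
}

// Scatter one branch's convolution output (F x (N*M*B), electrode-fastest
// columns) into the concatenated feature matrix A ((Ftot*N) x (M*B)) at
// channel offset c0 (0-based). A is modified in place.
// [[Rcpp::export]]
void fillConcatCpp(NumericMatrix A, const NumericMatrix& Z, const int N,
                   const int c0) {
  const int F = Z.nrow();
  const size_t ncz = Z.ncol();   // N * M * B
  const int nrA = A.nrow();
  const size_t ncols = ncz / N;  // M * B
  double* a = A.begin();
  const double* z = Z.begin();
  for (size_t j = 0; j < ncols; ++j) {
    for (int f = 0; f < F; ++f) {
      const int rowBase = (c0 + f) * N;
      double* dst = a + j * nrA + rowBase;
      const double* src = z + (j * N) * F + f;
      for (int n = 0; n < N; ++n) dst[n] = src[(size_t)n * F];
    }
  }
}

// Inverse of fillConcatCpp: gather the gradient rows of one branch from
// dA into the F x (N*M*B) layout.
// [[Rcpp::export]]
NumericMatrix gatherConcatCpp(const NumericMatrix& dA, const int N,
                              const int c0, const int F) {
  const int nrA = dA.nrow();
  const size_t ncols = dA.ncol();   // M * B
  NumericMatrix dZ(F, (size_t)N * ncols);
  const double* a = dA.begin();
  double* z = dZ.begin();
  for (size_t j = 0; j < ncols; ++j) {
    for (int f = 0; f < F; ++f) {
      const int rowBase = (c0 + f) * N;
      const double* src = a + j * nrA + rowBase;
      double* dst = z + (j * N) * F + f;
      for (int n = 0; n < N; ++n) dst[(size_t)n * F] = src[n];
    }
  }
  return dZ;
}
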