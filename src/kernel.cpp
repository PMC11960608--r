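#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Feature matrices are passed transposed (D x N) so that one voxel's
// feature vector is contiguous in memory; neighbour gathers then touch a
// single cache line per voxel.

// k-nearest-neighbour search in composite-feature space, restricted to a
// cubic spatial window around each voxel. Operates on the masked voxel set
// only; `vox` holds 1-based linear indices of the masked voxels in the
// full grid, `featT` one feature column per masked voxel.
// Returns k x N neighbour indices (1-based columns of `featT`), squared
// feature distances, and a pad flag for slots beyond the number of in-mask
// candidates (padded with the voxel itself at infinite distance).
// [[Rcpp::export]]
List kk_knn(NumericMatrix featT, IntegerVector vox, IntegerVector dim,
            int radius, int k) {
  const int D = featT.nrow(), N = featT.ncol();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *F = featT.begin();
  const R_xlen_t nvox_full = (R_xlen_t)nx * ny * nz;
  std::vector<int> map(nvox_full, -1);
  for (int i = 0; i < N; ++i) map[vox[i] - 1] = i;

  IntegerMatrix idx(k, N);
  NumericMatrix d2(k, N);
  LogicalMatrix pad(k, N);
  int *pidx = idx.begin();
  double *pd2 = d2.begin();
  int *ppad = pad.begin();
  std::vector<std::pair<double, int> > cand;
  cand.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));

  for (int i = 0; i < N; ++i) {
    R_xlen_t v = (R_xlen_t)(vox[i] - 1);
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    const double *fi = F + (R_xlen_t)i * D;
    cand.clear();
    int z0 = std::max(0, z - radius), z1 = std::min(nz - 1, z + radius);
    int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
    int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
    for (int zz = z0; zz <= z1; ++zz) {
      for (int yy = y0; yy <= y1; ++yy) {
        R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
        for (int xx = x0; xx <= x1; ++xx) {
          int j = map[base + xx];
          if (j < 0) continue;
          const double *fj = F + (R_xlen_t)j * D;
          double s = 0.0;
          for (int d = 0; d < D; ++d) {
            double df = fi[d] - fj[d];
            s += df * df;
          }
          cand.push_back(std::make_pair(s, j));
        }
      }
    }
    int m = (int)cand.size();
    int kk = std::min(k, m);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    int *ii = pidx + (R_xlen_t)i * k;
    double *di = pd2 + (R_xlen_t)i * k;
    int *pi = ppad + (R_xlen_t)i * k;
    for (int j = 0; j < kk; ++j) {
      ii[j] = cand[j].second + 1;
      di[j] = cand[j].first;
      pi[j] = 0;
    }
    for (int j = kk; j < k; ++j) {
      ii[j] = i + 1;
      di[j] = R_PosInf;
      pi[j] = 1;
    }
  }
  return List::create(_["idx"] = idx, _["d2"] = d2, _["pad"] = pad);
}

// squared feature distances along a frozen neighbour topology; padded
// slots get infinite distance (hence zero Gaussian weight)
// [[Rcpp::export]]
NumericMatrix kk_edge_dist2(NumericMatrix GT, IntegerMatrix idx,
                            LogicalMatrix pad) {
  const int D = GT.nrow(), N = GT.ncol(), k = idx.nrow();
  const double *G = GT.begin();
  const int *pidx = idx.begin();
  const int *ppad = pad.begin();
  NumericMatrix d2(k, N);
  double *pd2 = d2.begin();
  for (int i = 0; i < N; ++i) {
    const double *gi = G + (R_xlen_t)i * D;
    const int *ii = pidx + (R_xlen_t)i * k;
    const int *pi = ppad + (R_xlen_t)i * k;
    double *di = pd2 + (R_xlen_t)i * k;
    for (int j = 0; j < k; ++j) {
      if (pi[j]) { di[j] = R_PosInf; continue; }
      const double *gn = G + (R_xlen_t)(ii[j] - 1) * D;
      double s = 0.0;
      for (int d = 0; d < D; ++d) {
        double df = gi[d] - gn[d];
        s += df * df;
      }
      di[j] = s;
    }
  }
  return d2;
}

// y_i = sum_j W(j,i) * x[idx(j,i)]  (row-stochastic neighbour average)
// [[Rcpp::export]]
NumericVector kk_apply(NumericMatrix W, IntegerMatrix idx, NumericVector x) {
  const int N = W.ncol(), k = W.nrow();
  const double *pw = W.begin();
  const int *pidx = idx.begin();
  const double *px = x.begin();
  NumericVector y(N);
  for (int i = 0; i < N; ++i) {
    const double *wi = pw + (R_xlen_t)i * k;
    const int *ii = pidx + (R_xlen_t)i * k;
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += wi[j] * px[ii[j] - 1];
    y[i] = s;
  }
  return y;
}

// One forward + backward pass of the self-supervised kernel objective
//   L(theta) = sum_m || z_a - K(theta) z_m ||^2
// for the Gaussian k-NN kernel built on transformed features GT (D x N):
//   K_ij = u_ij / sum_j u_ij,  u_ij = exp(-||g_i - g_j||^2 / den).
// Returns the loss and dL/dG (D x N). `ZT` is M x N (composite frames),
// `pad` marks padded neighbour slots (weight zero).
// [[Rcpp::export]]
List kk_loss_grad(NumericMatrix GT, IntegerMatrix idx, LogicalMatrix pad,
                  NumericMatrix ZT, NumericVector za, double den) {
  const int D = GT.nrow(), N = GT.ncol(), k = idx.nrow(), M = ZT.nrow();
  const double *G = GT.begin();
  const int *pidx = idx.begin();
  const int *ppad = pad.begin();
  const double *Z = ZT.begin();
  NumericMatrix dGT(D, N);
  double *dG = dGT.begin();
  double loss = 0.0;
  std::vector<double> w(k), A(k), r(M);
  for (int i = 0; i < N; ++i) {
    const double *gi = G + (R_xlen_t)i * D;
    const int *ii = pidx + (R_xlen_t)i * k;
    const int *pi = ppad + (R_xlen_t)i * k;
    double s = 0.0;
    for (int j = 0; j < k; ++j) {
      if (pi[j]) { w[j] = 0.0; continue; }
      const double *gn = G + (R_xlen_t)(ii[j] - 1) * D;
      double d2 = 0.0;
      for (int d = 0; d < D; ++d) {
        double df = gi[d] - gn[d];
        d2 += df * df;
      }
      w[j] = std::exp(-d2 / den);
      s += w[j];
    }
    double inv = 1.0 / s;
    // residuals per composite frame, dL/dW accumulator A
    for (int m = 0; m < M; ++m) r[m] = 0.0;
    std::fill(A.begin(), A.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      if (w[j] == 0.0) continue;
      w[j] *= inv;
      const double *zn = Z + (R_xlen_t)(ii[j] - 1) * M;
      for (int m = 0; m < M; ++m) r[m] += w[j] * zn[m];
    }
    for (int m = 0; m < M; ++m) {
      r[m] -= za[i];
      loss += r[m] * r[m];
    }
    for (int j = 0; j < k; ++j) {
      if (w[j] == 0.0) continue;
      const double *zn = Z + (R_xlen_t)(ii[j] - 1) * M;
      double a = 0.0;
      for (int m = 0; m < M; ++m) a += r[m] * zn[m];
      A[j] = 2.0 * a;
    }
    double wa = 0.0;
    for (int j = 0; j < k; ++j) wa += w[j] * A[j];
    double *dgi = dG + (R_xlen_t)i * D;
    for (int j = 0; j < k; ++j) {
      if (w[j] == 0.0) continue;
      int n = ii[j] - 1;
      if (n == i) continue;  // self edge: zero distance gradient
      double B = w[j] * (A[j] - wa);   // dL/dS_j with S = -d2/den
      double C = -2.0 * B / den;       // chain through d2 and the factor 2
      const double *gn = G + (R_xlen_t)n * D;
      double *dgn = dG + (R_xlen_t)n * D;
      for (int d = 0; d < D; ++d) {
        double g = C * (gi[d] - gn[d]);
        dgi[d] += g;
        dgn[d] -= g;
      }
    }
  }
  return List::create(_["loss"] = loss, _["dG"] = dGT);
}
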