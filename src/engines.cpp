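// Patch-based denoising engines and small numeric kernels.
// All 4-D arrays arrive as flat NumericVectors in R's column-major
// (x fastest) order with explicit dims; everything here is 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t idx3(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
}

// Patch start offsets along one axis: stride steps, with the final patch
// shifted inward so the rim is always covered.
static std::vector<int> patch_starts(int dim, int P, int stride) {
  std::vector<int> s;
  for (int x = 0; x + P <= dim; x += stride) s.push_back(x);
  if (s.empty() || s.back() != dim - P) s.push_back(dim - P);
  return s;
}

// Marchenko-Pastur rank selection on a descending eigenspectrum of the
// scaled covariance (X'X)/M of an M x N Casorati matrix.  Accepts the
// smallest p whose trailing N-p eigenvalues fit inside the MP bulk:
// lam[p] - lam[N-1] <= sigma2(p) * (4 sqrt(g) + a * M^(-2/3) g^(-1/6)
// (1+sqrt(g))^(4/3)), g = (N-p)/M, sigma2(p) = mean of the trailing
// eigenvalues.  The first term is the asymptotic MP bulk width; the second
// is a Tracy-Widom finite-size allowance for the edge fluctuations (a = 2
// covers ~99.9% of pure-noise draws while widening the bound by only a few
// percent, so planted signal above the bulk edge is still detected).
static int mp_rank(const arma::vec& lam, int M, int N, double& sigma2_out) {
  const double tw_allow = 2.0;
  arma::vec suffix(N + 1, arma::fill::zeros);
  for (int i = N - 1; i >= 0; --i) suffix[i] = suffix[i + 1] + lam[i];
  for (int p = 0; p < N; ++p) {
    double s2 = suffix[p] / (N - p);
    double g = (double)(N - p) / (double)M;
    double width = 4.0 * std::sqrt(g) +
      tw_allow * std::pow((double)M, -2.0 / 3.0) * std::pow(g, -1.0 / 6.0) *
      std::pow(1.0 + std::sqrt(g), 4.0 / 3.0);
    if (lam[p] - lam[N - 1] <= s2 * width) { sigma2_out = s2; return p; }
  }
  sigma2_out = 0.0;
  return N;
}

// [[Rcpp::export(name = ".mp_rank_cpp")]]
List mp_rank_cpp(NumericVector eigenvalues, int M, int N) {
  arma::vec lam(eigenvalues.begin(), eigenvalues.size());
  double s2 = 0.0;
  int p = mp_rank(lam, M, N, s2);
  return List::create(_["rank"] = p, _["sigma2"] = s2);
}

// Shared patch loop.  method: 0 = MPPCA (eigen of X'X/M, MP rank), 1 = NORDIC
// (SVD of noise-normalised X, hard threshold at tau).  aggregation:
// 0 = average over all covering patches, 1 = centre voxel only.
// [[Rcpp::export(name = ".patch_engine_cpp")]]
List patch_engine_cpp(NumericVector data, IntegerVector dims, int P,
                      int stride, int aggregation, int method,
                      double tau, NumericVector noise_map, bool demean) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], N = dims[3];
  const int M = P * P * P;
  const size_t nvox = (size_t)nx * ny * nz;
  if (P > nx || P > ny || P > nz)
    stop("patch size %d exceeds image extent (%d, %d, %d)", P, nx, ny, nz);

  std::vector<int> xs = patch_starts(nx, P, stride);
  std::vector<int> ys = patch_starts(ny, P, stride);
  std::vector<int> zs = patch_starts(nz, P, stride);

  NumericVector out((size_t)nvox * N), wt(nvox), sig(nvox), rnk(nvox);
  arma::mat X(M, N), Xr(M, N);
  std::vector<size_t> vox(M);

  for (int zi : zs) for (int yi : ys) for (int xi : xs) {
    int k = 0;
    for (int dz = 0; dz < P; ++dz)
      for (int dy = 0; dy < P; ++dy)
        for (int dx = 0; dx < P; ++dx)
          vox[k++] = idx3(xi + dx, yi + dy, zi + dz, nx, ny);
    for (int j = 0; j < N; ++j) {
      size_t off = (size_t)j * nvox;
      for (int i = 0; i < M; ++i) X(i, j) = data[off + vox[i]];
    }

    double s2 = 0.0;
    int p = 0;
    if (method == 0) {                      // MPPCA
      arma::rowvec mu(N, arma::fill::zeros);
      if (demean) { mu = arma::mean(X, 0); X.each_row() -= mu; }
      arma::mat C = X.t() * X / (double)M;
      arma::vec ev; arma::mat V;
      arma::eig_sym(ev, V, C);              // ascending
      arma::vec lam = arma::reverse(ev);
      p = mp_rank(lam, M, N, s2);
      if (p >= N) {
        Xr = X;
      } else if (p == 0) {
        Xr.zeros();
      } else {
        arma::mat Vs = V.cols(N - p, N - 1);
        Xr = X * (Vs * Vs.t());
      }
      if (demean) { Xr.each_row() += mu; }
    } else {                                // NORDIC
      arma::vec g(M);
      for (int i = 0; i < M; ++i) g[i] = noise_map[vox[i]];
      arma::mat Xn = X;
      Xn.each_col() /= g;
      arma::mat U, V; arma::vec sv;
      arma::svd_econ(U, sv, V, Xn);
      arma::uvec keep = arma::find(sv > tau);
      p = (int)keep.n_elem;
      arma::vec tailsq = arma::square(sv);
      double tailsum = 0.0; int ntail = 0;
      for (arma::uword i = 0; i < sv.n_elem; ++i)
        if (sv[i] <= tau) { tailsum += tailsq[i]; ++ntail; }
      s2 = ntail > 0 ? tailsum / ((double)M * ntail) : 0.0;
      arma::vec svt = sv;
      for (arma::uword i = 0; i < svt.n_elem; ++i) if (svt[i] <= tau) svt[i] = 0.0;
      Xr = U * arma::diagmat(svt) * V.t();
      Xr.each_col() %= g;
    }

    if (aggregation == 1) {                 // centre voxel only
      int h = P / 2;
      size_t c = idx3(xi + h, yi + h, zi + h, nx, ny);
      for (int j = 0; j < N; ++j) {
        // centre row index inside the patch
        int ci = h + P * (h + P * h);
        out[(size_t)j * nvox + c] += Xr(ci, j);
      }
      wt[c] += 1.0; sig[c] += std::sqrt(s2); rnk[c] += p;
    } else {
      for (int i = 0; i < M; ++i) {
        size_t v = vox[i];
        for (int j = 0; j < N; ++j) out[(size_t)j * nvox + v] += Xr(i, j);
        wt[v] += 1.0; sig[v] += std::sqrt(s2); rnk[v] += p;
      }
    }
  }

  for (size_t v = 0; v < nvox; ++v) {
    double w = wt[v];
    if (w > 0) {
      for (int j = 0; j < N; ++j) out[(size_t)j * nvox + v] /= w;
      sig[v] /= w; rnk[v] /= w;
    } else {
      for (int j = 0; j < N; ++j) out[(size_t)j * nvox + v] = data[(size_t)j * nvox + v];
      sig[v] = NA_REAL; rnk[v] = NA_REAL;
    }
  }
  return List::create(_["denoised"] = out, _["sigma"] = sig,
                      _["rank"] = rnk, _["weight"] = wt);
}

// Classical non-local means on a single 3-D volume.
// w = exp(-max(d2 - 2*sigma^2, 0) / h^2), d2 = mean squared patch difference.
// [[Rcpp::export(name = ".nlm_cpp")]]
NumericVector nlm_cpp(NumericVector vol, IntegerVector dims, double sigma,
                      int patch_radius, int search_radius, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double h2 = h * h, two_s2 = 2.0 * sigma * sigma;
  const int pr = patch_radius, sr = search_radius;
  const int np = (2 * pr + 1) * (2 * pr + 1) * (2 * pr + 1);

  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };

  // precomputed patch offsets (flat strides, valid away from the border)
  std::vector<ptrdiff_t> poff;
  poff.reserve(np);
  for (int pz = -pr; pz <= pr; ++pz)
  for (int py = -pr; py <= pr; ++py)
  for (int px = -pr; px <= pr; ++px)
    poff.push_back((ptrdiff_t)px + (ptrdiff_t)nx * ((ptrdiff_t)py + (ptrdiff_t)ny * pz));

  const int brd = pr + sr;
  const double* v = &vol[0];

  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    double wsum = 0.0, acc = 0.0;
    bool interior = x >= brd && y >= brd && z >= brd &&
                    x < nx - brd && y < ny - brd && z < nz - brd;
    if (interior) {
      const double* c = v + idx3(x, y, z, nx, ny);
      for (int dz = -sr; dz <= sr; ++dz)
      for (int dy = -sr; dy <= sr; ++dy)
      for (int dx = -sr; dx <= sr; ++dx) {
        const double* q = c + (ptrdiff_t)dx +
          (ptrdiff_t)nx * ((ptrdiff_t)dy + (ptrdiff_t)ny * dz);
        double d2 = 0.0;
        for (int k = 0; k < np; ++k) {
          double diff = c[poff[k]] - q[poff[k]];
          d2 += diff * diff;
        }
        d2 /= np;
        double arg = d2 - two_s2;
        if (arg < 0.0) arg = 0.0;
        double w = std::exp(-arg / h2);
        wsum += w;
        acc += w * (*q);
      }
    } else {
      for (int dz = -sr; dz <= sr; ++dz)
      for (int dy = -sr; dy <= sr; ++dy)
      for (int dx = -sr; dx <= sr; ++dx) {
        int qx = x + dx, qy = y + dy, qz = z + dz;
        if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
        double d2 = 0.0;
        for (int pz = -pr; pz <= pr; ++pz)
        for (int py = -pr; py <= pr; ++py)
        for (int px = -pr; px <= pr; ++px) {
          int ax = clampi(x + px, 0, nx - 1), ay = clampi(y + py, 0, ny - 1),
              az = clampi(z + pz, 0, nz - 1);
          int bx = clampi(qx + px, 0, nx - 1), by = clampi(qy + py, 0, ny - 1),
              bz = clampi(qz + pz, 0, nz - 1);
          double diff = vol[idx3(ax, ay, az, nx, ny)] - vol[idx3(bx, by, bz, nx, ny)];
          d2 += diff * diff;
        }
        d2 /= np;
        double arg = d2 - two_s2;
        if (arg < 0.0) arg = 0.0;
        double w = std::exp(-arg / h2);
        wsum += w;
        acc += w * vol[idx3(qx, qy, qz, nx, ny)];
      }
    }
    out[idx3(x, y, z, nx, ny)] = acc / wsum;
  }
  return out;
}

// Batch symmetric 3x3 eigendecomposition.  d6 columns: xx, yy, zz, xy, xz, yz.
// Returns descending eigenvalues and the principal eigenvector per row.
// [[Rcpp::export(name = ".eig3_batch_cpp")]]
List eig3_batch_cpp(NumericMatrix d6) {
  const int n = d6.nrow();
  NumericMatrix evals(n, 3), v1(n, 3);
  arma::mat33 D;
  arma::vec ev; arma::mat V;
  for (int i = 0; i < n; ++i) {
    D(0, 0) = d6(i, 0); D(1, 1) = d6(i, 1); D(2, 2) = d6(i, 2);
    D(0, 1) = D(1, 0) = d6(i, 3);
    D(0, 2) = D(2, 0) = d6(i, 4);
    D(1, 2) = D(2, 1) = d6(i, 5);
    arma::eig_sym(ev, V, D);               // ascending
    evals(i, 0) = ev[2]; evals(i, 1) = ev[1]; evals(i, 2) = ev[0];
    v1(i, 0) = V(0, 2); v1(i, 1) = V(1, 2); v1(i, 2) = V(2, 2);
  }
  return List::create(_["evals"] = evals, _["v1"] = v1);
}

// Separable Gaussian smoothing of a 3-D array with edge renormalisation
// (kernel weights falling outside the array are dropped and the remainder
// rescaled, so constants are preserved at the boundary).
// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector arr, IntegerVector dims,
                           NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> a(arr.begin(), arr.end()), b(nvox);

  int dim_n[3] = {nx, ny, nz};
  size_t stridev[3] = {1, (size_t)nx, (size_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    for (int i = -rad; i <= rad; ++i)
      k[i + rad] = std::exp(-0.5 * (double)i * i / (s * s));
    int n = dim_n[ax];
    size_t st = stridev[ax];
    // iterate over all lines along axis ax
    for (size_t v = 0; v < nvox; ++v) {
      // position along the axis for this voxel
      int pos;
      if (ax == 0) pos = (int)(v % nx);
      else if (ax == 1) pos = (int)((v / nx) % ny);
      else pos = (int)(v / ((size_t)nx * ny));
      double acc = 0.0, wsum = 0.0;
      int lo = std::max(-rad, -pos), hi = std::min(rad, n - 1 - pos);
      for (int i = lo; i <= hi; ++i) {
        double w = k[i + rad];
        acc += w * a[v + (ptrdiff_t)i * (ptrdiff_t)st];
        wsum += w;
      }
      b[v] = acc / wsum;
    }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}
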