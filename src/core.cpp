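// Numerical kernels: sliding-window MPPCA, batched per-voxel SENSE solves,
// and voxelwise (re)weighted least-squares model fitting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Marcenko-Pastur consistency window half-width constant: the noise
// eigenvalues of a (M x n) pure-noise Casorati matrix span ~ 4*sqrt(n/M)*sigma^2.
static const double MP_SPREAD_CONST = 4.0;

// MP fit on ascending eigenvalues `lam` of (1/M) X^H X, where `lam` has the
// length of the smaller matrix dimension and M is the larger one.
// Returns sigma2 (noise variance per complex element) and p (signal count):
// the smallest p such that the n-p smallest eigenvalues are MP-consistent.
static void mp_fit(const vec& lam_in, const double M, double& sigma2, int& p_out) {
  const int n = lam_in.n_elem;
  vec lam = lam_in;
  const double lmax = lam.max();
  if (lmax > 0) {
    // clamp numerical-noise eigenvalues so exactly-low-rank data terminates
    lam.elem(find(lam < 1e-12 * lmax)).zeros();
  }
  for (int p = 0; p < n; ++p) {
    const int ntail = n - p;
    const double s2 = mean(lam.subvec(0, ntail - 1));
    const double gam = (double)ntail / M;
    const double spread = lam(ntail - 1) - lam(0);
    if (spread <= MP_SPREAD_CONST * std::sqrt(gam) * s2) {
      sigma2 = s2;
      p_out = p;
      return;
    }
  }
  // every component signal-like except the last singleton (always consistent);
  // unreachable in practice, kept as a safe fallback
  sigma2 = 0.0;
  p_out = n - 1;
}

// [[Rcpp::export]]
Rcpp::List cpp_mp_threshold(const arma::vec& eigenvalues, const double M) {
  double sigma2;
  int p;
  mp_fit(eigenvalues, M, sigma2, p);
  return Rcpp::List::create(Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("p_signal") = p);
}

// Sliding-kernel MPPCA over a complex 4D series [nx, ny, nz, nvol].
// Center-voxel write-back; at edges the kernel is shifted to stay in bounds.
// [[Rcpp::export]]
Rcpp::List cpp_mppca(const arma::cx_vec& data, Rcpp::IntegerVector dims,
                     Rcpp::IntegerVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], N = dims[3];
  const int kx = std::min(kernel[0], nx), ky = std::min(kernel[1], ny),
            kz = std::min(kernel[2], nz);
  const int M = kx * ky * kz;
  const uword nvox = (uword)nx * ny * nz;

  cx_vec out(data.n_elem, fill::zeros);
  vec sigma_map(nvox, fill::zeros);
  ivec rank_map(nvox, fill::zeros);

  cx_mat X(M, N);
  auto idx = [&](int i, int j, int k, int v) -> uword {
    return (uword)i + (uword)nx * (j + (uword)ny * (k + (uword)nz * (uword)v));
  };

  for (int k = 0; k < nz; ++k) {
    const int sk = std::max(0, std::min(k - kz / 2, nz - kz));
    for (int j = 0; j < ny; ++j) {
      const int sj = std::max(0, std::min(j - ky / 2, ny - ky));
      for (int i = 0; i < nx; ++i) {
        const int si = std::max(0, std::min(i - kx / 2, nx - kx));
        // Casorati matrix for this kernel position
        int row = 0, crow = -1;
        for (int dk = 0; dk < kz; ++dk)
          for (int dj = 0; dj < ky; ++dj)
            for (int di = 0; di < kx; ++di, ++row) {
              const int ii = si + di, jj = sj + dj, kk = sk + dk;
              if (ii == i && jj == j && kk == k) crow = row;
              for (int v = 0; v < N; ++v)
                X(row, v) = data(idx(ii, jj, kk, v));
            }

        const uword vox = (uword)i + (uword)nx * (j + (uword)ny * k);
        double sigma2;
        int p;
        cx_rowvec xden(N);

        if (M >= N) {
          cx_mat G = (X.t() * X) / (double)M;  // N x N, .t() is conj-transpose
          vec lam;
          cx_mat V;
          eig_sym(lam, V, G);  // ascending
          mp_fit(lam, (double)M, sigma2, p);
          if (p == 0) {
            xden.zeros();
          } else {
            cx_mat Vp = V.tail_cols(p);
            xden = X.row(crow) * Vp * Vp.t();
          }
        } else {
          cx_mat G = (X * X.t()) / (double)N;  // M x M
          vec lam;
          cx_mat U;
          eig_sym(lam, U, G);
          mp_fit(lam, (double)N, sigma2, p);
          if (p == 0) {
            xden.zeros();
          } else {
            cx_mat Up = U.tail_cols(p);
            xden = Up.row(crow) * (Up.t() * X);
          }
        }

        for (int v = 0; v < N; ++v) out(idx(i, j, k, v)) = xden(v);
        sigma_map(vox) = std::sqrt(std::max(sigma2, 0.0));
        rank_map(vox) = p;
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("denoised") = out,
                            Rcpp::Named("sigma") = sigma_map,
                            Rcpp::Named("rank") = Rcpp::wrap(rank_map));
}

// Batched per-voxel least-squares unfolding.
// E: [n_eq, P, nvox] encoding matrices; s: [n_eq, n_rhs, nvox] aliased data
// (n_rhs right-hand sides, e.g. volumes, sharing each voxel's system).
// Returns rho [P, n_rhs, nvox], gfactor [P, nvox], and a bad-conditioning
// flag. Voxels whose encoding matrix is numerically zero (outside coil
// support) yield rho = 0 and gfactor = NaN without being flagged.
// [[Rcpp::export]]
Rcpp::List cpp_unfold(const arma::cx_cube& E, const arma::cx_cube& s,
                      const double cond_limit, const double support_eps) {
  const uword n_eq = E.n_rows, P = E.n_cols, nvox = E.n_slices;
  const uword n_rhs = s.n_cols;
  cx_cube rho(P, n_rhs, nvox, fill::zeros);
  mat g(P, nvox);
  g.fill(datum::nan);
  uvec bad(nvox, fill::zeros);

  // global scale for the support test
  double emax = 0.0;
  for (uword v = 0; v < nvox; ++v) {
    const double m = abs(E.slice(v)).max();
    if (m > emax) emax = m;
  }
  const double sup_thresh = support_eps * emax;

  for (uword v = 0; v < nvox; ++v) {
    const cx_mat Ev = E.slice(v);  // n_eq x P
    if (abs(Ev).max() <= sup_thresh) continue;  // background voxel
    cx_mat A = Ev.t() * Ev;                     // P x P Hermitian
    vec lam = eig_sym(A);
    const double lmin = lam.min(), lmax = lam.max();
    if (lmin <= 0.0 || lmax / lmin > cond_limit) {
      bad(v) = 1;
      continue;
    }
    cx_mat Ainv = inv_sympd(A);
    rho.slice(v) = Ainv * (Ev.t() * s.slice(v));
    for (uword p = 0; p < P; ++p)
      g(p, v) = std::sqrt(std::real(Ainv(p, p)) * std::real(A(p, p)));
  }
  (void)n_eq;
  return Rcpp::List::create(Rcpp::Named("rho") = rho, Rcpp::Named("gfactor") = g,
                            Rcpp::Named("bad") = Rcpp::wrap(bad));
}

// Voxelwise log-linear (re)weighted least squares for tensor/kurtosis models.
// B: [nvol, P] design; S: [nvol, nvox] magnitude signals.
// Nonpositive signals are excluded per voxel (zero weight in every pass;
// counted). Initial fit is unweighted on log-signals; each iteration
// reweights by the squared currently-predicted signal. max_iter = 0 gives
// the plain (unweighted) log-linear fit. Convergence: relative parameter
// change < tol. Voxels with fewer usable volumes than parameters get NaN.
// [[Rcpp::export]]
Rcpp::List cpp_wls_fit(const arma::mat& B, const arma::mat& S,
                       const int max_iter, const double tol) {
  const uword nvol = B.n_rows, P = B.n_cols, nvox = S.n_cols;
  mat coef(P, nvox, fill::zeros);
  ivec iters(nvox, fill::zeros);
  uvec converged(nvox, fill::zeros);
  uword n_excluded = 0, n_unfittable = 0;

  const mat Bpinv = pinv(B);

  for (uword v = 0; v < nvox; ++v) {
    const vec s = S.col(v);
    const uvec use = find(s > 0.0);
    n_excluded += nvol - use.n_elem;
    if (use.n_elem < P) {
      coef.col(v).fill(datum::nan);
      ++n_unfittable;
      continue;
    }
    const bool full = (use.n_elem == nvol);
    const mat Bu = full ? B : B.rows(use);
    const vec y = log(full ? s : vec(s.elem(use)));
    vec beta = full ? vec(Bpinv * y) : vec(pinv(Bu) * y);
    bool conv = (max_iter == 0);
    int it = 0;
    for (; it < max_iter; ++it) {
      vec w = exp(Bu * beta);            // predicted signal
      const double wfloor = 1e-6 * w.max();
      w.elem(find(w < wfloor)).fill(wfloor);
      const vec w2 = square(w);
      const mat Bw = Bu.each_col() % w2;  // W B
      vec beta_new;
      const bool ok = solve(beta_new, Bu.t() * Bw, Bu.t() * (w2 % y),
                            solve_opts::no_approx);
      if (!ok) break;
      const double rel = norm(beta_new - beta) /
                         std::max(norm(beta), 1e-300);
      beta = beta_new;
      if (rel < tol) {
        conv = true;
        ++it;
        break;
      }
    }
    coef.col(v) = beta;
    iters(v) = it;
    converged(v) = conv ? 1 : 0;
  }
  return Rcpp::List::create(
      Rcpp::Named("coef") = coef, Rcpp::Named("iterations") = Rcpp::wrap(iters),
      Rcpp::Named("converged") = Rcpp::wrap(converged),
      Rcpp::Named("n_excluded") = (double)n_excluded,
      Rcpp::Named("n_unfittable") = (double)n_unfittable);
}
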