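// Diagonally preconditioned primal-dual hybrid gradient (Chambolle-Pock)
// solver for one wish-list stage:
//
//   minimize  phi(d)   over fluence x >= 0,  d = d0 + A x
//   subject to block constraints on d (per-voxel max dose, structure mean
//   dose, and epsilon-constraints on hinge-sum objectives of earlier
//   priorities).
//
// The caller passes a base matrix over unique sampled voxels plus a gather
// map assigning each stacked block row to a base row (structures appear in
// several blocks; this avoids duplicating matrix rows). Block kinds:
//   0 lin_obj   phi = w * sum(d)                       (mean dose)
//   1 under_obj phi = w * sum(max(t - d, 0))           (mean underdose)
//   2 over_obj  phi = w * sum(max(d - t, 0))           (mean overdose)
//   3 max_con   d_i <= B per row
//   4 mean_con  w * sum(d) <= B
//   5 under_con w * sum(max(t - d, 0)) <= B
//   6 over_con  w * sum(max(d - t, 0)) <= B
//   7 inactive
//   8 min_con   d_i >= t per row (zero-bound underdose constraint)
//   9 cap_con   d_i <= t per row (zero-bound overdose constraint)
// Coupled blocks (4,5,6) use a uniform dual step within the block so their
// Euclidean projections stay valid under the diagonal preconditioner.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::sp_mat;
using arma::vec;

static inline double prox_under(double z, double tp, double lw) {
  if (z >= tp) return z;
  if (z < tp - lw) return z + lw;
  return tp;
}
static inline double prox_over(double z, double tp, double lw) {
  if (z <= tp) return z;
  if (z > tp + lw) return z - lw;
  return tp;
}

struct Block {
  int kind, r0, r1; // stacked row range, 0-based inclusive
  double w, t, B, ftol;
  int m() const { return r1 - r0 + 1; }
};

// [[Rcpp::export]]
List cpp_pdhg_stage(const arma::sp_mat &A, IntegerVector map,
                    const arma::vec &d0,
                    IntegerVector kind, IntegerVector r0, IntegerVector r1,
                    NumericVector wgt, NumericVector thr, NumericVector bnd,
                    NumericVector ftol,
                    arma::vec x0, arma::vec y0,
                    int max_iter, int check_every, int min_iter,
                    double obj_tol, double balance) {
  const int m0 = A.n_rows, n = A.n_cols, nb = kind.size(), ms = map.size();
  std::vector<Block> blocks(nb);
  int obj_idx = -1;
  for (int b = 0; b < nb; ++b) {
    blocks[b] = {kind[b], r0[b], r1[b], wgt[b], thr[b], bnd[b], ftol[b]};
    if (kind[b] <= 2) obj_idx = b;
  }
  if (obj_idx < 0) stop("no objective block");
  const sp_mat At = A.t();

  // row duplicate counts in the active stacked system
  vec dup(m0, arma::fill::zeros);
  for (int i = 0; i < ms; ++i) dup[map[i]] += 1.0;

  // diagonal preconditioners (Pock-Chambolle alpha = 1)
  vec rsum0(m0, arma::fill::zeros), csum(n, arma::fill::zeros);
  for (sp_mat::const_iterator it = A.begin(); it != A.end(); ++it) {
    const double a = std::fabs(*it);
    rsum0[it.row()] += a;
    csum[it.col()] += a * dup[it.row()];
  }
  vec sigma(ms), tau(n);
  for (int i = 0; i < ms; ++i) {
    const double rs = rsum0[map[i]];
    sigma[i] = (rs > 0 ? 1.0 / rs : 1.0) / balance;
  }
  for (int j = 0; j < n; ++j) tau[j] = (csum[j] > 0 ? 1.0 / csum[j] : 0.0) * balance;
  for (int b = 0; b < nb; ++b) {
    if (blocks[b].kind >= 4 && blocks[b].kind <= 6) {
      double s = arma::datum::inf;
      for (int i = blocks[b].r0; i <= blocks[b].r1; ++i) s = std::min(s, sigma[i]);
      for (int i = blocks[b].r0; i <= blocks[b].r1; ++i) sigma[i] = s;
    }
  }

  // hinge-sum projections by bisection on the prox multiplier
  auto project_under = [&](vec &v, const Block &B) {
    double s = 0;
    for (int i = B.r0; i <= B.r1; ++i) s += std::max(B.t - d0[i] - v[i], 0.0);
    if (B.w * s <= B.B) return;
    auto g_at = [&](double lam) {
      double g = 0;
      for (int i = B.r0; i <= B.r1; ++i) {
        double p = prox_under(v[i], B.t - d0[i], lam * B.w);
        g += std::max(B.t - d0[i] - p, 0.0);
      }
      return B.w * g;
    };
    double lo = 0.0, hi = 1.0;
    int guard = 0;
    while (g_at(hi) > B.B && guard++ < 80) hi *= 2.0;
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (g_at(mid) > B.B) lo = mid; else hi = mid;
    }
    for (int i = B.r0; i <= B.r1; ++i) v[i] = prox_under(v[i], B.t - d0[i], hi * B.w);
  };
  auto project_over = [&](vec &v, const Block &B) {
    double s = 0;
    for (int i = B.r0; i <= B.r1; ++i) s += std::max(v[i] + d0[i] - B.t, 0.0);
    if (B.w * s <= B.B) return;
    auto g_at = [&](double lam) {
      double g = 0;
      for (int i = B.r0; i <= B.r1; ++i) {
        double p = prox_over(v[i], B.t - d0[i], lam * B.w);
        g += std::max(p + d0[i] - B.t, 0.0);
      }
      return B.w * g;
    };
    double lo = 0.0, hi = 1.0;
    int guard = 0;
    while (g_at(hi) > B.B && guard++ < 80) hi *= 2.0;
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (g_at(mid) > B.B) lo = mid; else hi = mid;
    }
    for (int i = B.r0; i <= B.r1; ++i) v[i] = prox_over(v[i], B.t - d0[i], hi * B.w);
  };

  vec x = x0, y = y0, xbar = x0, xold(n), zb(m0), v(ms), p(ms), acc(m0), g(n);
  double phi_prev = NA_REAL, phi_best = arma::datum::inf;
  vec x_best = x;
  bool have_best = false, converged = false;
  int stable = 0, iters = 0;

  auto eval_state = [&](const vec &xe, double &phi, double &maxviol) {
    vec z0 = A * xe;
    phi = 0; maxviol = 0;
    for (int b = 0; b < nb; ++b) {
      const Block &B = blocks[b];
      double val = 0, s = 0, mx = -arma::datum::inf;
      switch (B.kind) {
      case 0: for (int i=B.r0;i<=B.r1;++i) s += z0[map[i]] + d0[i];
              phi = B.w*s; break;
      case 1: for (int i=B.r0;i<=B.r1;++i) s += std::max(B.t - z0[map[i]] - d0[i], 0.0);
              phi = B.w*s; break;
      case 2: for (int i=B.r0;i<=B.r1;++i) s += std::max(z0[map[i]] + d0[i] - B.t, 0.0);
              phi = B.w*s; break;
      case 3: for (int i=B.r0;i<=B.r1;++i) mx = std::max(mx, z0[map[i]] + d0[i]);
              val = mx - B.B; break;
      case 4: for (int i=B.r0;i<=B.r1;++i) s += z0[map[i]] + d0[i];
              val = B.w*s - B.B; break;
      case 5: for (int i=B.r0;i<=B.r1;++i) s += std::max(B.t - z0[map[i]] - d0[i], 0.0);
              val = B.w*s - B.B; break;
      case 6: for (int i=B.r0;i<=B.r1;++i) s += std::max(z0[map[i]] + d0[i] - B.t, 0.0);
              val = B.w*s - B.B; break;
      case 8: for (int i=B.r0;i<=B.r1;++i) mx = std::max(mx, B.t - z0[map[i]] - d0[i]);
              val = mx; break;
      case 9: for (int i=B.r0;i<=B.r1;++i) mx = std::max(mx, z0[map[i]] + d0[i] - B.t);
              val = mx; break;
      default: break;
      }
      if (B.kind >= 3 && B.kind != 7) {
        double rel = std::max(0.0, val) / std::max(B.ftol, 1e-300);
        maxviol = std::max(maxviol, rel);
      }
    }
  };

  for (int k = 0; k < max_iter; ++k) {
    iters = k + 1;
    zb = A * xbar;
    for (int i = 0; i < ms; ++i) v[i] = y[i] + sigma[i] * zb[map[i]];
    for (int i = 0; i < ms; ++i) p[i] = v[i] / sigma[i];
    for (int b = 0; b < nb; ++b) {
      const Block &B = blocks[b];
      switch (B.kind) {
      case 0:
        for (int i = B.r0; i <= B.r1; ++i) p[i] -= B.w / sigma[i];
        break;
      case 1:
        for (int i = B.r0; i <= B.r1; ++i)
          p[i] = prox_under(p[i], B.t - d0[i], B.w / sigma[i]);
        break;
      case 2:
        for (int i = B.r0; i <= B.r1; ++i)
          p[i] = prox_over(p[i], B.t - d0[i], B.w / sigma[i]);
        break;
      case 3:
        for (int i = B.r0; i <= B.r1; ++i) p[i] = std::min(p[i], B.B - d0[i]);
        break;
      case 4: {
        double s = 0;
        for (int i = B.r0; i <= B.r1; ++i) s += p[i] + d0[i];
        s *= B.w;
        if (s > B.B) {
          const double shift = (s - B.B) / (B.w * B.m());
          for (int i = B.r0; i <= B.r1; ++i) p[i] -= shift;
        }
      } break;
      case 5: project_under(p, B); break;
      case 6: project_over(p, B); break;
      case 8:
        for (int i = B.r0; i <= B.r1; ++i) p[i] = std::max(p[i], B.t - d0[i]);
        break;
      case 9:
        for (int i = B.r0; i <= B.r1; ++i) p[i] = std::min(p[i], B.t - d0[i]);
        break;
      default: break; // inactive: y component becomes 0
      }
    }
    for (int i = 0; i < ms; ++i) y[i] = v[i] - sigma[i] * p[i];
    acc.zeros();
    for (int i = 0; i < ms; ++i) acc[map[i]] += y[i];
    g = At * acc;
    xold = x;
    for (int j = 0; j < n; ++j) {
      double xn = x[j] - tau[j] * g[j];
      x[j] = xn > 0 ? xn : 0.0;
    }
    xbar = 2.0 * x - xold;

    if ((k + 1) % check_every == 0 || k + 1 == max_iter) {
      double phi, maxviol;
      eval_state(x, phi, maxviol);
      bool feas = maxviol <= 1.0;
      if (feas && phi < phi_best) { phi_best = phi; x_best = x; have_best = true; }
      if (!ISNA(phi_prev) &&
          std::fabs(phi - phi_prev) <= obj_tol * (1.0 + std::fabs(phi)) && feas) {
        stable++;
      } else stable = 0;
      phi_prev = phi;
      if (stable >= 2 && k + 1 >= min_iter) { converged = true; break; }
    }
  }

  vec xr = have_best ? x_best : x;
  double phi_r, viol_r;
  eval_state(xr, phi_r, viol_r);
  return List::create(_["x"] = xr, _["y"] = y, _["objective"] = phi_r,
                      _["max_rel_viol"] = viol_r, _["iters"] = iters,
                      _["converged"] = converged, _["feasible"] = viol_r <= 1.0);
}
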