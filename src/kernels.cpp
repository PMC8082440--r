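// Analytic pencil-beam dose kernels: radiological depth by ray marching and
// sparse beamlet influence assembly. Parallel (non-divergent) beam geometry.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Water-equivalent (density-weighted) depth from the grid boundary toward
// the source for each voxel position. coords: m x 3 (mm, isocentric),
// u: unit vector pointing toward the source, step_mm: march step.
// [[Rcpp::export]]
NumericVector cpp_radiological_depth(NumericVector density, IntegerVector shape,
                                     double voxel_mm, NumericMatrix coords,
                                     NumericVector u, double step_mm) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double ox = (nx - 1) / 2.0, oy = (ny - 1) / 2.0, oz = (nz - 1) / 2.0;
  const int m = coords.nrow();
  NumericVector out(m);
  // half-diagonal of the grid bounds the march length
  const double span = voxel_mm * std::sqrt((double)nx * nx + (double)ny * ny +
                                           (double)nz * nz);
  const int nstep = (int)std::ceil(span / step_mm);
  const double ux = u[0], uy = u[1], uz = u[2];
  const double *dens = REAL(density);
  for (int v = 0; v < m; ++v) {
    const double px = coords(v, 0), py = coords(v, 1), pz = coords(v, 2);
    double acc = 0.0;
    for (int s = 0; s < nstep; ++s) {
      const double t = (s + 0.5) * step_mm;
      const double qx = px + t * ux, qy = py + t * uy, qz = pz + t * uz;
      const int ix = (int)std::lround(qx / voxel_mm + ox);
      const int iy = (int)std::lround(qy / voxel_mm + oy);
      const int iz = (int)std::lround(qz / voxel_mm + oz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
        break; // left the grid: vacuum beyond
      acc += dens[ix + nx * (iy + (R_xlen_t)ny * iz)] * step_mm;
    }
    out[v] = acc;
  }
  return out;
}

// Sparse influence triplets for one beam. Voxel BEV coordinates (bu, bv) and
// radiological depths are precomputed in R. The beamlet lattice is
// rectangular: center (a, b) = (u0 + a*spacing, v0 + b*spacing),
// a in 0..nu-1, b in 0..nv-1, column index j = a + nu*b (0-based).
// Kernel: val = OF * exp(-mu*depth) * exp(-r^2/(2 sigma^2)); entries below
// trunc_rel of their beamlet's maximum are dropped.
// [[Rcpp::export]]
List cpp_influence(NumericVector depth, NumericVector bu, NumericVector bv,
                   double u0, double v0, double spacing, int nu, int nv,
                   double mu, double sigma, double output_factor,
                   double trunc_rel) {
  const int m = depth.size();
  // generation cutoff: generous so that exact per-column truncation decides
  const double r_cut = sigma * std::sqrt(2.0 * std::log(1.0 / (trunc_rel * 0.01)));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(m * 8); tj.reserve(m * 8); tx.reserve(m * 8);
  std::vector<double> colmax((size_t)nu * nv, 0.0);
  for (int v = 0; v < m; ++v) {
    const double att = output_factor * std::exp(-mu * depth[v]);
    const double pu = bu[v], pv = bv[v];
    int a0 = clampi((int)std::ceil((pu - u0 - r_cut) / spacing), 0, nu - 1);
    int a1 = clampi((int)std::floor((pu - u0 + r_cut) / spacing), 0, nu - 1);
    int b0 = clampi((int)std::ceil((pv - v0 - r_cut) / spacing), 0, nv - 1);
    int b1 = clampi((int)std::floor((pv - v0 + r_cut) / spacing), 0, nv - 1);
    for (int b = b0; b <= b1; ++b) {
      const double dv = pv - (v0 + b * spacing);
      for (int a = a0; a <= a1; ++a) {
        const double du = pu - (u0 + a * spacing);
        const double r2 = du * du + dv * dv;
        if (r2 > r_cut * r_cut) continue;
        const double val = att * std::exp(-r2 * inv2s2);
        const int j = a + nu * b;
        if (val > colmax[j]) colmax[j] = val;
        ti.push_back(v); tj.push_back(j); tx.push_back(val);
      }
    }
  }
  // exact truncation relative to each beamlet's maximum
  std::vector<int> ki, kj; std::vector<double> kx;
  ki.reserve(ti.size()); kj.reserve(ti.size()); kx.reserve(ti.size());
  for (size_t q = 0; q < ti.size(); ++q) {
    if (tx[q] >= trunc_rel * colmax[tj[q]]) {
      ki.push_back(ti[q]); kj.push_back(tj[q]); kx.push_back(tx[q]);
    }
  }
  return List::create(_["i"] = wrap(ki), _["j"] = wrap(kj), _["x"] = wrap(kx));
}
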