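#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Quaternion helpers. Convention: q = (w, x, y, z), unit norm, acting as the
// rotation matrix R(q) on column vectors. All rotations are about a body's
// reference centroid; a pose (q, t) maps x -> R (x - c0) + c0 + t.
// ---------------------------------------------------------------------------

static inline void quat_normalize(double q[4]) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

static inline void quat_to_mat(const double q[4], double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2*(y*y + z*z); R[1] = 2*(x*y - w*z);     R[2] = 2*(x*z + w*y);
  R[3] = 2*(x*y + w*z);     R[4] = 1 - 2*(x*x + z*z); R[5] = 2*(y*z - w*x);
  R[6] = 2*(x*z - w*y);     R[7] = 2*(y*z + w*x);     R[8] = 1 - 2*(x*x + y*y);
}

static inline void quat_mult(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void quat_random(double q[4]) {
  // 4 standard normals normalized: uniform on SO(3)
  for (int i = 0; i < 4; ++i) q[i] = norm_rand();
  quat_normalize(q);
}

static inline void quat_axis_angle(int axis, double angle_rad, double q[4]) {
  double h = 0.5 * angle_rad;
  q[0] = std::cos(h); q[1] = q[2] = q[3] = 0.0;
  q[1 + axis] = std::sin(h);
}

// [[Rcpp::export]]
double cpp_quat_angle(NumericVector q1, NumericVector q2) {
  double d = q1[0]*q2[0] + q1[1]*q2[1] + q1[2]*q2[2] + q1[3]*q2[3];
  d = std::fabs(d); if (d > 1.0) d = 1.0;
  return 2.0 * std::acos(d); // radians
}

// ---------------------------------------------------------------------------
// Gaussian density simulation on a regular grid.
// Each point contributes w_i * G_sigma(r), G normalized to unit integral,
// truncated at 4 sigma. Grid: value index (i,j,k) 0-based sits at
// origin + (i,j,k) * voxel; the values vector is x-fastest (R array order).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_simulate_density(NumericMatrix coords, NumericVector weights,
                                   double sigma, NumericVector origin,
                                   IntegerVector dims, double voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double cut = 4.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const int rad = (int)std::ceil(cut / voxel);
  for (int a = 0; a < coords.nrow(); ++a) {
    double px = coords(a,0), py = coords(a,1), pz = coords(a,2);
    double w = weights[a] * norm;
    int ci = (int)std::floor((px - origin[0]) / voxel + 0.5);
    int cj = (int)std::floor((py - origin[1]) / voxel + 0.5);
    int ck = (int)std::floor((pz - origin[2]) / voxel + 0.5);
    int i0 = std::max(0, ci - rad), i1 = std::min(nx - 1, ci + rad);
    int j0 = std::max(0, cj - rad), j1 = std::min(ny - 1, cj + rad);
    int k0 = std::max(0, ck - rad), k1 = std::min(nz - 1, ck + rad);
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * voxel - pz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * voxel - py;
        double d2yz = dy*dy + dz*dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * voxel - px;
          double r2 = dx*dx + d2yz;
          if (r2 <= cut * cut) out[base + i] += w * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pose scoring: simulate the body (already transformed coords) locally and
// Pearson-correlate against the map over the body's own support mask
// (voxels where the simulated body density >= mask_frac * its maximum).
// Returns NA when the mask is degenerate (empty, or constant map values).
// ---------------------------------------------------------------------------

// Tabulated Gaussian exp(-r^2 / 2 sigma^2) on [0, cut^2], linearly
// interpolated; the fitting inner loop spends most of its time here and
// the ~1e-7 interpolation error is far below the score tolerances.
struct GaussLUT {
  double cut, cut2, scale;
  std::vector<double> tab;
  GaussLUT(double sigma, double cut_sigma) {
    cut = cut_sigma * sigma;
    cut2 = cut * cut;
    const int N = 4096;
    tab.resize(N + 2);
    scale = N / cut2;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int i = 0; i <= N + 1; ++i)
      tab[i] = std::exp(-(i / scale) * inv2s2);
  }
  inline double operator()(double r2) const {
    double f = r2 * scale;
    int i = (int)f;
    double d = f - i;
    return tab[i] * (1.0 - d) + tab[i + 1] * d;
  }
};

static double splat_ncc(const double* map, int nx, int ny, int nz,
                        const double* origin, double voxel,
                        const std::vector<double>& cx,
                        const std::vector<double>& cy,
                        const std::vector<double>& cz,
                        const std::vector<double>& w,
                        const GaussLUT& G, double mask_frac,
                        std::vector<double>& buf) {
  const int n = (int)cx.size();
  const double cut = G.cut;
  // bounding box in voxel indices
  double lox = cx[0], hix = cx[0], loy = cy[0], hiy = cy[0], loz = cz[0], hiz = cz[0];
  for (int a = 1; a < n; ++a) {
    lox = std::min(lox, cx[a]); hix = std::max(hix, cx[a]);
    loy = std::min(loy, cy[a]); hiy = std::max(hiy, cy[a]);
    loz = std::min(loz, cz[a]); hiz = std::max(hiz, cz[a]);
  }
  int i0 = std::max(0, (int)std::floor((lox - cut - origin[0]) / voxel));
  int i1 = std::min(nx - 1, (int)std::ceil((hix + cut - origin[0]) / voxel));
  int j0 = std::max(0, (int)std::floor((loy - cut - origin[1]) / voxel));
  int j1 = std::min(ny - 1, (int)std::ceil((hiy + cut - origin[1]) / voxel));
  int k0 = std::max(0, (int)std::floor((loz - cut - origin[2]) / voxel));
  int k1 = std::min(nz - 1, (int)std::ceil((hiz + cut - origin[2]) / voxel));
  if (i1 < i0 || j1 < j0 || k1 < k0) return NA_REAL;
  const int bx = i1 - i0 + 1, by = j1 - j0 + 1, bz = k1 - k0 + 1;
  const R_xlen_t nb = (R_xlen_t)bx * by * bz;
  if ((R_xlen_t)buf.size() < nb) buf.resize(nb);
  std::fill(buf.begin(), buf.begin() + nb, 0.0);
  const int rad = (int)std::ceil(cut / voxel);
  for (int a = 0; a < n; ++a) {
    int ci = (int)std::floor((cx[a] - origin[0]) / voxel + 0.5);
    int cj = (int)std::floor((cy[a] - origin[1]) / voxel + 0.5);
    int ck = (int)std::floor((cz[a] - origin[2]) / voxel + 0.5);
    int ai0 = std::max(i0, ci - rad), ai1 = std::min(i1, ci + rad);
    int aj0 = std::max(j0, cj - rad), aj1 = std::min(j1, cj + rad);
    int ak0 = std::max(k0, ck - rad), ak1 = std::min(k1, ck + rad);
    for (int k = ak0; k <= ak1; ++k) {
      double dz = origin[2] + k * voxel - cz[a];
      for (int j = aj0; j <= aj1; ++j) {
        double dy = origin[1] + j * voxel - cy[a];
        double d2 = dy*dy + dz*dz;
        R_xlen_t base = (R_xlen_t)(k - k0) * bx * by + (R_xlen_t)(j - j0) * bx - i0;
        for (int i = ai0; i <= ai1; ++i) {
          double dx = origin[0] + i * voxel - cx[a];
          double r2 = dx*dx + d2;
          if (r2 <= G.cut2) buf[base + i] += w[a] * G(r2);
        }
      }
    }
  }
  double bmax = 0.0;
  for (R_xlen_t t = 0; t < nb; ++t) bmax = std::max(bmax, buf[t]);
  if (bmax <= 0.0) return NA_REAL;
  const double thr = mask_frac * bmax;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; R_xlen_t m = 0;
  for (int k = 0; k < bz; ++k)
    for (int j = 0; j < by; ++j) {
      R_xlen_t lb = (R_xlen_t)k * bx * by + (R_xlen_t)j * bx;
      R_xlen_t gb = (R_xlen_t)(k + k0) * nx * ny + (R_xlen_t)(j + j0) * nx + i0;
      for (int i = 0; i < bx; ++i) {
        double b = buf[lb + i];
        if (b >= thr) {
          double a = map[gb + i];
          sa += a; sb += b; saa += a*a; sbb += b*b; sab += a*b; ++m;
        }
      }
    }
  if (m < 8) return NA_REAL;
  double va = saa - sa*sa/m, vb = sbb - sb*sb/m;
  if (va <= 1e-300 || vb <= 1e-300) return NA_REAL;
  return (sab - sa*sb/m) / std::sqrt(va * vb);
}

static void transform_coords(const NumericMatrix& ref, const double c0[3],
                             const double q[4], const double t[3],
                             std::vector<double>& cx, std::vector<double>& cy,
                             std::vector<double>& cz) {
  double R[9]; quat_to_mat(q, R);
  int n = ref.nrow();
  cx.resize(n); cy.resize(n); cz.resize(n);
  for (int a = 0; a < n; ++a) {
    double x = ref(a,0) - c0[0], y = ref(a,1) - c0[1], z = ref(a,2) - c0[2];
    cx[a] = R[0]*x + R[1]*y + R[2]*z + c0[0] + t[0];
    cy[a] = R[3]*x + R[4]*y + R[5]*z + c0[1] + t[1];
    cz[a] = R[6]*x + R[7]*y + R[8]*z + c0[2] + t[2];
  }
}

// [[Rcpp::export]]
double cpp_pose_ncc(NumericVector map, IntegerVector dims, NumericVector origin,
                    double voxel, NumericMatrix ref, NumericVector weights,
                    NumericVector centroid, NumericVector quat, NumericVector trans,
                    double sigma, double mask_frac, double cut_sigma = 3.0) {
  std::vector<double> cx, cy, cz, buf;
  double c0[3] = {centroid[0], centroid[1], centroid[2]};
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double t[3] = {trans[0], trans[1], trans[2]};
  std::vector<double> w(weights.begin(), weights.end());
  transform_coords(ref, c0, q, t, cx, cy, cz);
  GaussLUT G(sigma, cut_sigma);
  return splat_ncc(REAL(map), dims[0], dims[1], dims[2], REAL(origin), voxel,
                   cx, cy, cz, w, G, mask_frac, buf);
}

// ---------------------------------------------------------------------------
// Global fit: n_starts random restarts, each locally optimized by a
// multiscale coordinate hill climb (translation / rotation axis moves,
// step halved when a full sweep yields no improvement).
// start_points: candidate centroid positions (Angstrom) to draw from.
// Returns n_starts x 8 matrix: qw qx qy qz tx ty tz ncc.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_global_fit(NumericVector map, IntegerVector dims,
                             NumericVector origin, double voxel,
                             NumericMatrix ref, NumericVector weights,
                             NumericVector centroid, NumericMatrix start_points,
                             int n_starts, int n_opt_steps, double sigma,
                             double mask_frac, double trans_step0,
                             double rot_step0_deg, double trans_floor,
                             double rot_floor_deg, double cut_sigma = 3.0) {
  NumericMatrix out(n_starts, 8);
  std::vector<double> cx, cy, cz, buf;
  std::vector<double> w(weights.begin(), weights.end());
  const double* m = REAL(map);
  const double* org = REAL(origin);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double c0[3] = {centroid[0], centroid[1], centroid[2]};
  const int nsp = start_points.nrow();
  GaussLUT G(sigma, cut_sigma);

  for (int s = 0; s < n_starts; ++s) {
    double q[4]; quat_random(q);
    int sp = (int)std::floor(unif_rand() * nsp); if (sp >= nsp) sp = nsp - 1;
    double t[3] = {start_points(sp,0) - c0[0], start_points(sp,1) - c0[1],
                   start_points(sp,2) - c0[2]};
    transform_coords(ref, c0, q, t, cx, cy, cz);
    double sc = splat_ncc(m, nx, ny, nz, org, voxel, cx, cy, cz, w, G,
                          mask_frac, buf);
    if (ISNAN(sc)) sc = -1.0;
    double ts = trans_step0, rs = rot_step0_deg * M_PI / 180.0;
    const double tfl = trans_floor, rfl = rot_floor_deg * M_PI / 180.0;
    int evals = 0;
    while (evals < n_opt_steps) {
      bool improved = false;
      // translation moves
      for (int ax = 0; ax < 3 && evals < n_opt_steps; ++ax) {
        for (int sgn = -1; sgn <= 1 && evals < n_opt_steps; sgn += 2) {
          double t2[3] = {t[0], t[1], t[2]};
          t2[ax] += sgn * ts;
          transform_coords(ref, c0, q, t2, cx, cy, cz);
          double sc2 = splat_ncc(m, nx, ny, nz, org, voxel, cx, cy, cz, w,
                                 G, mask_frac, buf);
          ++evals;
          if (!ISNAN(sc2) && sc2 > sc) { sc = sc2; t[ax] = t2[ax]; improved = true; }
        }
      }
      // rotation moves (global axes, about the moved centroid)
      for (int ax = 0; ax < 3 && evals < n_opt_steps; ++ax) {
        for (int sgn = -1; sgn <= 1 && evals < n_opt_steps; sgn += 2) {
          double dq[4]; quat_axis_angle(ax, sgn * rs, dq);
          double q2[4]; quat_mult(dq, q, q2); quat_normalize(q2);
          transform_coords(ref, c0, q2, t, cx, cy, cz);
          double sc2 = splat_ncc(m, nx, ny, nz, org, voxel, cx, cy, cz, w,
                                 G, mask_frac, buf);
          ++evals;
          if (!ISNAN(sc2) && sc2 > sc) {
            sc = sc2; for (int i = 0; i < 4; ++i) q[i] = q2[i]; improved = true;
          }
        }
      }
      if (!improved) {
        if (ts <= tfl * 1.0001 && rs <= rfl * 1.0001) break;
        ts = std::max(tfl, ts * 0.5);
        rs = std::max(rfl, rs * 0.5);
      }
    }
    out(s,0) = q[0]; out(s,1) = q[1]; out(s,2) = q[2]; out(s,3) = q[3];
    out(s,4) = t[0]; out(s,5) = t[1]; out(s,6) = t[2]; out(s,7) = sc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Composite scoring of a library-indexed configuration, and simulated
// annealing Monte Carlo recombination over fit indices.
//
// Per body b: pts[[b]] is a K_b x (3*n_pts_b) matrix (x1 y1 z1 x2 ...) of
// restraint point coordinates under each fit; beads[[b]] likewise; ncc[[b]]
// a K_b vector. Links are candidate rows (body1, pt1, body2, pt2), 0-based,
// grouped by link id (per-link distance = min over candidates). Connectivity
// rows (body1, pt1, body2, pt2) with max_len. Clash over inter-body beads.
// ---------------------------------------------------------------------------

struct ScoreCtx {
  std::vector<NumericMatrix> pts, beads;
  std::vector<NumericVector> ncc, radii;
  IntegerMatrix cand; IntegerVector cand_link; int n_links;
  IntegerMatrix conn; NumericVector conn_max;
  double w_em, w_xl, w_conn, w_clash, xl_thresh, xl_sigma, conn_sigma;
  double xl_cap;
  int B;
};

static inline void body_point(const ScoreCtx& C, const std::vector<int>& idx,
                              int b, int p, double* xyz) {
  const NumericMatrix& M = C.pts[b];
  int k = idx[b];
  xyz[0] = M(k, 3*p); xyz[1] = M(k, 3*p + 1); xyz[2] = M(k, 3*p + 2);
}

static void score_config(const ScoreCtx& C, const std::vector<int>& idx,
                         double out[5]) {
  double em = 0.0;
  for (int b = 0; b < C.B; ++b) em -= C.ncc[b][idx[b]];
  double xl = 0.0;
  {
    int nc = C.cand.nrow();
    int cur = -1; double dmin = 0.0;
    for (int r = 0; r <= nc; ++r) {
      int lid = (r < nc) ? C.cand_link[r] : -2;
      if (lid != cur) {
        if (cur >= 0) {
          double d = std::sqrt(dmin);
          if (d > C.xl_thresh) {
            double v = (d - C.xl_thresh) / C.xl_sigma;
            xl += std::min(v * v, C.xl_cap);
          }
        }
        cur = lid; dmin = std::numeric_limits<double>::infinity();
      }
      if (r < nc) {
        double a[3], b2[3];
        body_point(C, idx, C.cand(r,0), C.cand(r,1), a);
        body_point(C, idx, C.cand(r,2), C.cand(r,3), b2);
        double dx = a[0]-b2[0], dy = a[1]-b2[1], dz = a[2]-b2[2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < dmin) dmin = d2;
      }
    }
  }
  double cn = 0.0;
  for (int r = 0; r < C.conn.nrow(); ++r) {
    double a[3], b2[3];
    body_point(C, idx, C.conn(r,0), C.conn(r,1), a);
    body_point(C, idx, C.conn(r,2), C.conn(r,3), b2);
    double dx = a[0]-b2[0], dy = a[1]-b2[1], dz = a[2]-b2[2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d > C.conn_max[r]) {
      double v = (d - C.conn_max[r]) / C.conn_sigma; cn += v * v;
    }
  }
  double cl = 0.0;
  for (int b1 = 0; b1 < C.B; ++b1) {
    const NumericMatrix& A = C.beads[b1];
    int k1 = idx[b1], n1 = A.ncol() / 3;
    for (int b2 = b1 + 1; b2 < C.B; ++b2) {
      const NumericMatrix& Bm = C.beads[b2];
      int k2 = idx[b2], n2 = Bm.ncol() / 3;
      for (int i = 0; i < n1; ++i) {
        double ax = A(k1,3*i), ay = A(k1,3*i+1), az = A(k1,3*i+2);
        double ri = C.radii[b1][i];
        for (int j = 0; j < n2; ++j) {
          double dx = ax - Bm(k2,3*j), dy = ay - Bm(k2,3*j+1), dz = az - Bm(k2,3*j+2);
          double d2 = dx*dx + dy*dy + dz*dz;
          double rr = ri + C.radii[b2][j];
          if (d2 < rr * rr) {
            double ov = rr - std::sqrt(d2); cl += ov * ov;
          }
        }
      }
    }
  }
  out[0] = em; out[1] = xl; out[2] = cn; out[3] = cl;
  out[4] = C.w_em * em + C.w_xl * xl + C.w_conn * cn + C.w_clash * cl;
}

static ScoreCtx build_ctx(List pts, List beads, List ncc, List radii,
                          IntegerMatrix cand, IntegerVector cand_link,
                          IntegerMatrix conn, NumericVector conn_max,
                          NumericVector weights, double xl_thresh,
                          double xl_sigma, double conn_sigma,
                          double xl_cap) {
  ScoreCtx C;
  C.B = pts.size();
  for (int b = 0; b < C.B; ++b) {
    C.pts.push_back(as<NumericMatrix>(pts[b]));
    C.beads.push_back(as<NumericMatrix>(beads[b]));
    C.ncc.push_back(as<NumericVector>(ncc[b]));
    C.radii.push_back(as<NumericVector>(radii[b]));
  }
  C.cand = cand; C.cand_link = cand_link;
  C.conn = conn; C.conn_max = conn_max;
  C.w_em = weights[0]; C.w_xl = weights[1];
  C.w_conn = weights[2]; C.w_clash = weights[3];
  C.xl_thresh = xl_thresh; C.xl_sigma = xl_sigma; C.conn_sigma = conn_sigma;
  C.xl_cap = xl_cap;
  return C;
}

// [[Rcpp::export]]
NumericVector cpp_score_indices(IntegerVector idx, List pts, List beads,
                                List ncc, List radii, IntegerMatrix cand,
                                IntegerVector cand_link, IntegerMatrix conn,
                                NumericVector conn_max, NumericVector weights,
                                double xl_thresh, double xl_sigma,
                                double conn_sigma, double xl_cap) {
  ScoreCtx C = build_ctx(pts, beads, ncc, radii, cand, cand_link, conn,
                         conn_max, weights, xl_thresh, xl_sigma, conn_sigma,
                         xl_cap);
  std::vector<int> ix(idx.begin(), idx.end());
  double out[5]; score_config(C, ix, out);
  return NumericVector::create(_["em"] = out[0], _["xl"] = out[1],
                               _["conn"] = out[2], _["clash"] = out[3],
                               _["total"] = out[4]);
}

// One independent annealed MC run; returns best index vector and its score.
// [[Rcpp::export]]
List cpp_mc_recombine(List pts, List beads, List ncc, List radii,
                      IntegerMatrix cand, IntegerVector cand_link,
                      IntegerMatrix conn, NumericVector conn_max,
                      NumericVector weights, double xl_thresh, double xl_sigma,
                      double conn_sigma, double xl_cap,
                      int n_steps, double T0, double T1) {
  ScoreCtx C = build_ctx(pts, beads, ncc, radii, cand, cand_link, conn,
                         conn_max, weights, xl_thresh, xl_sigma, conn_sigma,
                         xl_cap);
  std::vector<int> nk(C.B);
  for (int b = 0; b < C.B; ++b) nk[b] = C.ncc[b].size();
  std::vector<int> idx(C.B);
  for (int b = 0; b < C.B; ++b)
    idx[b] = std::min(nk[b] - 1, (int)std::floor(unif_rand() * nk[b]));
  double cur[5]; score_config(C, idx, cur);
  std::vector<int> best = idx; double bestv[5];
  for (int i = 0; i < 5; ++i) bestv[i] = cur[i];
  const double decay = (n_steps > 1) ? std::pow(T1 / T0, 1.0 / (n_steps - 1)) : 1.0;
  double T = T0;
  for (int st = 0; st < n_steps; ++st, T *= decay) {
    int b = std::min(C.B - 1, (int)std::floor(unif_rand() * C.B));
    if (nk[b] < 2) continue;
    int old = idx[b];
    int prop = std::min(nk[b] - 1, (int)std::floor(unif_rand() * nk[b]));
    if (prop == old) continue;
    idx[b] = prop;
    double nw[5]; score_config(C, idx, nw);
    double dE = nw[4] - cur[4];
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
      for (int i = 0; i < 5; ++i) cur[i] = nw[i];
      if (cur[4] < bestv[4]) { best = idx; for (int i = 0; i < 5; ++i) bestv[i] = cur[i]; }
    } else {
      idx[b] = old;
    }
  }
  return List::create(_["indices"] = IntegerVector(best.begin(), best.end()),
                      _["score"] = NumericVector::create(
                        _["em"] = bestv[0], _["xl"] = bestv[1],
                        _["conn"] = bestv[2], _["clash"] = bestv[3],
                        _["total"] = bestv[4]));
}

// ---------------------------------------------------------------------------
// Continuous-space refinement: small rigid perturbations of one body at a
// time, Metropolis-accepted under the composite score with the EM term
// recomputed (splat NCC) for the perturbed body. Poses: B x 7 (q, t).
// Reference coordinates are per body: restraint points, beads (+radii),
// and scoring coordinates (beads used for the EM term).
// ---------------------------------------------------------------------------

struct RefineCtx {
  std::vector<NumericMatrix> pts, beads;      // reference coords (n x 3)
  std::vector<NumericVector> radii, bw;       // bead radii, bead weights
  std::vector<std::vector<double> > c0;       // body centroids
  IntegerMatrix cand; IntegerVector cand_link;
  IntegerMatrix conn; NumericVector conn_max;
  double w_em, w_xl, w_conn, w_clash, xl_thresh, xl_sigma, conn_sigma;
  double xl_cap;
  int B;
};

static void refine_score(const RefineCtx& C,
                         const std::vector<std::vector<double> >& P, // pts coords
                         const std::vector<std::vector<double> >& Bd, // bead coords
                         const std::vector<double>& nccv, double out[5]) {
  double em = 0.0;
  for (int b = 0; b < C.B; ++b) em -= nccv[b];
  double xl = 0.0;
  int nc = C.cand.nrow(); int cur = -1; double dmin = 0.0;
  for (int r = 0; r <= nc; ++r) {
    int lid = (r < nc) ? C.cand_link[r] : -2;
    if (lid != cur) {
      if (cur >= 0) {
        double d = std::sqrt(dmin);
        if (d > C.xl_thresh) {
          double v = (d - C.xl_thresh)/C.xl_sigma;
          xl += std::min(v*v, C.xl_cap);
        }
      }
      cur = lid; dmin = std::numeric_limits<double>::infinity();
    }
    if (r < nc) {
      const std::vector<double>& A = P[C.cand(r,0)];
      const std::vector<double>& Bv = P[C.cand(r,2)];
      int p1 = C.cand(r,1), p2 = C.cand(r,3);
      double dx = A[3*p1]-Bv[3*p2], dy = A[3*p1+1]-Bv[3*p2+1], dz = A[3*p1+2]-Bv[3*p2+2];
      double d2 = dx*dx+dy*dy+dz*dz; if (d2 < dmin) dmin = d2;
    }
  }
  double cn = 0.0;
  for (int r = 0; r < C.conn.nrow(); ++r) {
    const std::vector<double>& A = P[C.conn(r,0)];
    const std::vector<double>& Bv = P[C.conn(r,2)];
    int p1 = C.conn(r,1), p2 = C.conn(r,3);
    double dx = A[3*p1]-Bv[3*p2], dy = A[3*p1+1]-Bv[3*p2+1], dz = A[3*p1+2]-Bv[3*p2+2];
    double d = std::sqrt(dx*dx+dy*dy+dz*dz);
    if (d > C.conn_max[r]) { double v = (d - C.conn_max[r])/C.conn_sigma; cn += v*v; }
  }
  double cl = 0.0;
  for (int b1 = 0; b1 < C.B; ++b1) {
    int n1 = (int)Bd[b1].size() / 3;
    for (int b2 = b1 + 1; b2 < C.B; ++b2) {
      int n2 = (int)Bd[b2].size() / 3;
      for (int i = 0; i < n1; ++i) {
        double ax = Bd[b1][3*i], ay = Bd[b1][3*i+1], az = Bd[b1][3*i+2];
        double ri = C.radii[b1][i];
        for (int j = 0; j < n2; ++j) {
          double dx = ax-Bd[b2][3*j], dy = ay-Bd[b2][3*j+1], dz = az-Bd[b2][3*j+2];
          double d2 = dx*dx+dy*dy+dz*dz; double rr = ri + C.radii[b2][j];
          if (d2 < rr*rr) { double ov = rr - std::sqrt(d2); cl += ov*ov; }
        }
      }
    }
  }
  out[0] = em; out[1] = xl; out[2] = cn; out[3] = cl;
  out[4] = C.w_em*em + C.w_xl*xl + C.w_conn*cn + C.w_clash*cl;
}

static void apply_pose(const NumericMatrix& ref, const double c0[3],
                       const double q[4], const double t[3],
                       std::vector<double>& out) {
  double R[9]; quat_to_mat(q, R);
  int n = ref.nrow(); out.resize(3 * n);
  for (int a = 0; a < n; ++a) {
    double x = ref(a,0)-c0[0], y = ref(a,1)-c0[1], z = ref(a,2)-c0[2];
    out[3*a]   = R[0]*x + R[1]*y + R[2]*z + c0[0] + t[0];
    out[3*a+1] = R[3]*x + R[4]*y + R[5]*z + c0[1] + t[1];
    out[3*a+2] = R[6]*x + R[7]*y + R[8]*z + c0[2] + t[2];
  }
}

// [[Rcpp::export]]
List cpp_mc_refine(NumericVector map, IntegerVector dims, NumericVector origin,
                   double voxel, List pts, List beads, List radii, List bweights,
                   List score_pts, List score_w,
                   NumericMatrix centroids, NumericMatrix poses,
                   IntegerMatrix cand, IntegerVector cand_link,
                   IntegerMatrix conn, NumericVector conn_max,
                   NumericVector weights, double xl_thresh, double xl_sigma,
                   double conn_sigma, double xl_cap,
                   double sigma, double mask_frac,
                   int n_steps, double T0, double T1, double trans_step,
                   double rot_step_deg) {
  RefineCtx C;
  C.B = pts.size();
  std::vector<NumericMatrix> sp;
  std::vector<NumericVector> sw;
  for (int b = 0; b < C.B; ++b) {
    C.pts.push_back(as<NumericMatrix>(pts[b]));
    C.beads.push_back(as<NumericMatrix>(beads[b]));
    C.radii.push_back(as<NumericVector>(radii[b]));
    C.bw.push_back(as<NumericVector>(bweights[b]));
    sp.push_back(as<NumericMatrix>(score_pts[b]));
    sw.push_back(as<NumericVector>(score_w[b]));
    std::vector<double> c(3);
    c[0] = centroids(b,0); c[1] = centroids(b,1); c[2] = centroids(b,2);
    C.c0.push_back(c);
  }
  C.cand = cand; C.cand_link = cand_link; C.conn = conn; C.conn_max = conn_max;
  C.w_em = weights[0]; C.w_xl = weights[1]; C.w_conn = weights[2]; C.w_clash = weights[3];
  C.xl_thresh = xl_thresh; C.xl_sigma = xl_sigma; C.conn_sigma = conn_sigma;
  C.xl_cap = xl_cap;

  const double* m = REAL(map); const double* org = REAL(origin);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  GaussLUT G(sigma, 3.0);
  std::vector<std::vector<double> > Q(C.B, std::vector<double>(4));
  std::vector<std::vector<double> > T(C.B, std::vector<double>(3));
  std::vector<std::vector<double> > P(C.B), Bd(C.B);
  std::vector<double> nccv(C.B);
  std::vector<double> cx, cy, cz, buf;
  for (int b = 0; b < C.B; ++b) {
    for (int i = 0; i < 4; ++i) Q[b][i] = poses(b, i);
    for (int i = 0; i < 3; ++i) T[b][i] = poses(b, 4 + i);
    double q[4] = {Q[b][0],Q[b][1],Q[b][2],Q[b][3]};
    double t[3] = {T[b][0],T[b][1],T[b][2]};
    double c0[3] = {C.c0[b][0],C.c0[b][1],C.c0[b][2]};
    apply_pose(C.pts[b], c0, q, t, P[b]);
    apply_pose(C.beads[b], c0, q, t, Bd[b]);
    std::vector<double> S;
    apply_pose(sp[b], c0, q, t, S);
    int n = (int)S.size()/3;
    cx.resize(n); cy.resize(n); cz.resize(n);
    for (int a = 0; a < n; ++a) { cx[a]=S[3*a]; cy[a]=S[3*a+1]; cz[a]=S[3*a+2]; }
    std::vector<double> w(sw[b].begin(), sw[b].end());
    double v = splat_ncc(m, nx, ny, nz, org, voxel, cx, cy, cz, w, G,
                         mask_frac, buf);
    nccv[b] = ISNAN(v) ? -1.0 : v;
  }
  double cur[5]; refine_score(C, P, Bd, nccv, cur);
  std::vector<std::vector<double> > bQ = Q, bT = T; double bestv[5];
  for (int i = 0; i < 5; ++i) bestv[i] = cur[i];
  const double decay = (n_steps > 1) ? std::pow(T1/T0, 1.0/(n_steps-1)) : 1.0;
  double Temp = T0;
  const double rot_step = rot_step_deg * M_PI / 180.0;
  for (int st = 0; st < n_steps; ++st, Temp *= decay) {
    int b = std::min(C.B - 1, (int)std::floor(unif_rand() * C.B));
    // propose a small rigid perturbation
    double dq[4], axn[3];
    for (int i = 0; i < 3; ++i) axn[i] = norm_rand();
    double an = std::sqrt(axn[0]*axn[0]+axn[1]*axn[1]+axn[2]*axn[2]);
    double ang = unif_rand() * rot_step;
    dq[0] = std::cos(ang/2);
    for (int i = 0; i < 3; ++i) dq[1+i] = std::sin(ang/2) * axn[i] / an;
    double q2[4]; double qold[4] = {Q[b][0],Q[b][1],Q[b][2],Q[b][3]};
    quat_mult(dq, qold, q2); quat_normalize(q2);
    double t2[3];
    for (int i = 0; i < 3; ++i) t2[i] = T[b][i] + (2*unif_rand()-1) * trans_step;
    double c0[3] = {C.c0[b][0],C.c0[b][1],C.c0[b][2]};
    std::vector<double> Pnew, Bnew, Snew;
    apply_pose(C.pts[b], c0, q2, t2, Pnew);
    apply_pose(C.beads[b], c0, q2, t2, Bnew);
    apply_pose(sp[b], c0, q2, t2, Snew);
    int n = (int)Snew.size()/3;
    cx.resize(n); cy.resize(n); cz.resize(n);
    for (int a = 0; a < n; ++a) { cx[a]=Snew[3*a]; cy[a]=Snew[3*a+1]; cz[a]=Snew[3*a+2]; }
    std::vector<double> w(sw[b].begin(), sw[b].end());
    double v = splat_ncc(m, nx, ny, nz, org, voxel, cx, cy, cz, w, G,
                         mask_frac, buf);
    double nccnew = ISNAN(v) ? -1.0 : v;
    std::vector<double> Pold, Bold; double nccold = nccv[b];
    std::swap(Pold, P[b]); std::swap(Bold, Bd[b]);
    P[b] = Pnew; Bd[b] = Bnew; nccv[b] = nccnew;
    double nw[5]; refine_score(C, P, Bd, nccv, nw);
    double dE = nw[4] - cur[4];
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / Temp)) {
      for (int i = 0; i < 5; ++i) cur[i] = nw[i];
      for (int i = 0; i < 4; ++i) Q[b][i] = q2[i];
      for (int i = 0; i < 3; ++i) T[b][i] = t2[i];
      if (cur[4] < bestv[4]) {
        bQ = Q; bT = T; for (int i = 0; i < 5; ++i) bestv[i] = cur[i];
      }
    } else {
      std::swap(P[b], Pold); std::swap(Bd[b], Bold); nccv[b] = nccold;
    }
  }
  NumericMatrix outp(C.B, 7);
  for (int b = 0; b < C.B; ++b) {
    for (int i = 0; i < 4; ++i) outp(b,i) = bQ[b][i];
    for (int i = 0; i < 3; ++i) outp(b,4+i) = bT[b][i];
  }
  return List::create(_["poses"] = outp,
                      _["score"] = NumericVector::create(
                        _["em"] = bestv[0], _["xl"] = bestv[1],
                        _["conn"] = bestv[2], _["clash"] = bestv[3],
                        _["total"] = bestv[4]));
}

// Trilinear interpolation of a map at arbitrary physical points (Angstrom).
// Points outside the grid return fill.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector map, IntegerVector dims,
                            NumericVector origin, double voxel,
                            NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* m = REAL(map);
  int n = pts.nrow();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double fx = (pts(a,0) - origin[0]) / voxel;
    double fy = (pts(a,1) - origin[1]) / voxel;
    double fz = (pts(a,2) - origin[2]) / voxel;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1) {
      // clamp exact upper boundary
      if (fx >= 0 && fy >= 0 && fz >= 0 &&
          fx <= nx - 1 && fy <= ny - 1 && fz <= nz - 1) {
        i = std::min(i, nx - 2); j = std::min(j, ny - 2); k = std::min(k, nz - 2);
      } else { out[a] = fill; continue; }
    }
    double dx = fx - i, dy = fy - j, dz = fz - k;
    R_xlen_t b000 = (R_xlen_t)k*nx*ny + (R_xlen_t)j*nx + i;
    R_xlen_t b001 = b000 + (R_xlen_t)nx*ny;
    double v00 = m[b000]*(1-dx) + m[b000+1]*dx;
    double v10 = m[b000+nx]*(1-dx) + m[b000+nx+1]*dx;
    double v01 = m[b001]*(1-dx) + m[b001+1]*dx;
    double v11 = m[b001+nx]*(1-dx) + m[b001+nx+1]*dx;
    out[a] = (v00*(1-dy) + v10*dy)*(1-dz) + (v01*(1-dy) + v11*dy)*dz;
  }
  return out;
}
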