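// Deterministic RK4 streamline tracking on a single-slice pseudo-tensor
// grid with probabilistic nearest-neighbor interpolation.
//
// Coordinates: continuous display-frame positions (x, y), x = column index,
// y = nr + 1 - row (y increases upward); voxel centers at integer
// coordinates 1..nc / 1..nr. Tensor component matrices are in the display
// frame, so the in-plane principal eigenvector is a display-frame direction.
//
// All randomness comes from R's RNG stream (unif_rand), one draw per
// interpolation call, so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// termination codes (kept in sync with .term_reasons in R/tracking.R)
enum Status { OK = 0, MASK_EXIT = 1, LOW_FA = 2, HIGH_CURV = 3,
              MAX_STEPS = 4, ZERO_TENSOR = 5 };

struct Grid {
  const double* dxx;
  const double* dxy;
  const double* dyy;
  const double* fa;     // may be null
  const int* brain;     // may be null
  int nr, nc;
  inline int idx(int row, int col) const { return (col - 1) * nr + (row - 1); }
  inline int row_of_y(double y) const {
    return nr + 1 - (int)std::lround(y);
  }
  inline bool in_grid(double x, double y) const {
    return x >= 1.0 && x <= (double)nc && y >= 1.0 && y <= (double)nr;
  }
};

// probabilistic nearest-neighbor selection among the <= 4 surrounding
// nodes, with probabilities equal to the bilinear weights; returns the
// linear index of the chosen voxel or -1 when out of domain. Consumes
// exactly one uniform draw.
int interp_select(const Grid& g, double x, double y) {
  double u = unif_rand();
  if (!g.in_grid(x, y)) return -1;
  int x0 = (int)std::floor(x);
  int y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double wts[4] = { (1 - fx) * (1 - fy), fx * (1 - fy),
                    (1 - fx) * fy, fx * fy };
  int xs[4] = { x0, x0 + 1, x0, x0 + 1 };
  int ys[4] = { y0, y0, y0 + 1, y0 + 1 };
  double cum = 0.0;
  int chosen = -1;
  for (int k = 0; k < 4; ++k) {
    if (wts[k] <= 0.0) continue;
    if (xs[k] < 1 || xs[k] > g.nc || ys[k] < 1 || ys[k] > g.nr) return -1;
    cum += wts[k];
    if (chosen < 0 && u < cum) chosen = k;
  }
  if (chosen < 0) { // u == 1 edge; take the last positive-weight node
    for (int k = 3; k >= 0; --k) if (wts[k] > 0.0) { chosen = k; break; }
  }
  int row = g.nr + 1 - ys[chosen];
  return g.idx(row, xs[chosen]);
}

// in-plane principal eigenvector, sign-aligned to (px, py) when supplied
// (otherwise toward +x, ties toward +y); returns ZERO_TENSOR for
// isotropic or non-positive tensors.
int principal_dir(double dxx, double dxy, double dyy,
                  bool have_prev, double px, double py,
                  double& vx, double& vy) {
  double tr = dxx + dyy;
  double disc = std::sqrt((dxx - dyy) * (dxx - dyy) + 4.0 * dxy * dxy);
  if (tr <= 0.0 || disc <= 1e-12 * tr) return ZERO_TENSOR;
  double b = 2.0 * dxy + 0.0; // canonicalize -0 so atan2 picks +pi, not -pi
  double phi = 0.5 * std::atan2(b, dxx - dyy);
  vx = std::cos(phi); vy = std::sin(phi);
  double d = have_prev ? (vx * px + vy * py)
                       : (vx != 0.0 ? vx : vy);
  if (d < 0.0) { vx = -vx; vy = -vy; }
  return OK;
}

// single classical RK4 step of length `step` through the direction field
// principal_dir(interp_select(.)); every stage is sign-aligned to the
// incoming direction and guarded against turning >= the curve threshold.
int rk4_step_core(const Grid& g, double x, double y,
                  double dirx, double diry, double step, double costh,
                  double& nx, double& ny, double& vx, double& vy) {
  double kx[4], ky[4];
  const double frac[4] = { 0.0, 0.5, 0.5, 1.0 };
  double prevx = dirx, prevy = diry;
  for (int s = 0; s < 4; ++s) {
    double px = x, py = y;
    if (s > 0) {
      px += step * frac[s] * kx[s - 1];
      py += step * frac[s] * ky[s - 1];
    }
    int vi = interp_select(g, px, py);
    if (vi < 0) return MASK_EXIT;
    int st = principal_dir(g.dxx[vi], g.dxy[vi], g.dyy[vi],
                           true, dirx, diry, kx[s], ky[s]);
    if (st != OK) return st;
    // stage curvature guard: a stage deviating by >= the threshold from
    // the incoming direction terminates the streamline
    if (kx[s] * dirx + ky[s] * diry <= costh + 1e-12) return HIGH_CURV;
    prevx = kx[s]; prevy = ky[s];
  }
  (void)prevx; (void)prevy;
  double sx = (kx[0] + 2 * kx[1] + 2 * kx[2] + kx[3]) / 6.0;
  double sy = (ky[0] + 2 * ky[1] + 2 * ky[2] + ky[3]) / 6.0;
  double nrm = std::sqrt(sx * sx + sy * sy);
  if (nrm < 1e-12) return ZERO_TENSOR;
  vx = sx / nrm; vy = sy / nrm;
  nx = x + step * vx;
  ny = y + step * vy;
  return OK;
}

// one launch from (sx, sy) along unit (dx0, dy0); appends points
int launch(const Grid& g, double sx, double sy, double dx0, double dy0,
           double step, double costh, double fa_min, int max_steps,
           std::vector<double>& xs, std::vector<double>& ys) {
  double x = sx, y = sy, dirx = dx0, diry = dy0;
  xs.push_back(x); ys.push_back(y);
  for (;;) {
    if ((int)xs.size() - 1 >= max_steps) return MAX_STEPS;
    double nx2, ny2, vx, vy;
    int st = rk4_step_core(g, x, y, dirx, diry, step, costh, nx2, ny2, vx, vy);
    if (st != OK) return st;
    // per-step curvature: angle between consecutive segment directions
    if (vx * dirx + vy * diry <= costh + 1e-12) return HIGH_CURV;
    if (!g.in_grid(nx2, ny2)) return MASK_EXIT;
    if (g.brain != nullptr) { // containment at the nearest voxel
      int row = g.row_of_y(ny2);
      int col = (int)std::lround(nx2);
      if (row < 1 || row > g.nr || col < 1 || col > g.nc) return MASK_EXIT;
      if (!g.brain[g.idx(row, col)]) return MASK_EXIT;
    }
    // FA stop uses the voxel selected by probabilistic interpolation at
    // the new position (same substrate as the direction field)
    int vi = interp_select(g, nx2, ny2);
    if (vi < 0) return MASK_EXIT;
    if (g.fa != nullptr && g.fa[vi] <= fa_min) return LOW_FA;
    x = nx2; y = ny2; dirx = vx; diry = vy;
    xs.push_back(x); ys.push_back(y);
  }
}

Grid make_grid(const NumericMatrix& dxx, const NumericMatrix& dxy,
               const NumericMatrix& dyy, const NumericMatrix& fa,
               const IntegerMatrix& brain) {
  Grid g;
  g.dxx = dxx.begin(); g.dxy = dxy.begin(); g.dyy = dyy.begin();
  g.fa = fa.nrow() > 0 ? fa.begin() : nullptr;
  g.brain = brain.nrow() > 0 ? brain.begin() : nullptr;
  g.nr = dxx.nrow(); g.nc = dxx.ncol();
  return g;
}

} // namespace

// [[Rcpp::export(name = ".interp_select_cpp")]]
List interp_select_cpp(NumericMatrix dxx, NumericMatrix dxy, NumericMatrix dyy,
                       double x, double y) {
  NumericMatrix empty(0, 0);
  IntegerMatrix iempty(0, 0);
  Grid g = make_grid(dxx, dxy, dyy, empty, iempty);
  int vi = interp_select(g, x, y);
  if (vi < 0) return List::create(_["ok"] = false);
  int col = vi / g.nr + 1, row = vi % g.nr + 1;
  return List::create(_["ok"] = true, _["row"] = row, _["col"] = col,
                      _["dxx"] = g.dxx[vi], _["dxy"] = g.dxy[vi],
                      _["dyy"] = g.dyy[vi]);
}

// [[Rcpp::export(name = ".rk4_step_cpp")]]
List rk4_step_cpp(NumericMatrix dxx, NumericMatrix dxy, NumericMatrix dyy,
                  double x, double y, double dirx, double diry,
                  double step, double curve_threshold_deg) {
  NumericMatrix empty(0, 0);
  IntegerMatrix iempty(0, 0);
  Grid g = make_grid(dxx, dxy, dyy, empty, iempty);
  double costh = std::cos(curve_threshold_deg * M_PI / 180.0);
  double nx2, ny2, vx, vy;
  int st = rk4_step_core(g, x, y, dirx, diry, step, costh, nx2, ny2, vx, vy);
  if (st != OK) return List::create(_["status"] = st);
  return List::create(_["status"] = st,
                      _["pos"] = NumericVector::create(nx2, ny2),
                      _["dir"] = NumericVector::create(vx, vy));
}

// [[Rcpp::export(name = ".track_seed_cpp")]]
List track_seed_cpp(NumericMatrix dxx, NumericMatrix dxy, NumericMatrix dyy,
                    NumericMatrix fa, IntegerMatrix brain,
                    double seed_x, double seed_y,
                    int iterations, bool bidirectional,
                    double step, double curve_threshold_deg,
                    double fa_min, int max_steps, int min_points) {
  Grid g = make_grid(dxx, dxy, dyy, fa, brain);
  double costh = std::cos(curve_threshold_deg * M_PI / 180.0);
  // launch direction from the seed voxel's own tensor (deterministic)
  int srow = g.row_of_y(seed_y), scol = (int)std::lround(seed_x);
  if (srow < 1 || srow > g.nr || scol < 1 || scol > g.nc)
    stop("seed position outside the grid");
  int si = g.idx(srow, scol);
  double d0x, d0y;
  int st0 = principal_dir(g.dxx[si], g.dxy[si], g.dyy[si], false, 0, 0, d0x, d0y);
  List out;
  if (st0 != OK) return out; // isotropic seed voxel: nothing to track
  for (int it = 0; it < iterations; ++it) {
    std::vector<double> fxs, fys, bxs, bys;
    int fr = launch(g, seed_x, seed_y, d0x, d0y, step, costh, fa_min,
                    max_steps, fxs, fys);
    int br = MASK_EXIT;
    size_t nb = 0;
    if (bidirectional) {
      br = launch(g, seed_x, seed_y, -d0x, -d0y, step, costh, fa_min,
                  max_steps, bxs, bys);
      nb = bxs.size() - 1; // seed point shared with the forward half
    }
    size_t n = nb + fxs.size();
    if ((int)n < min_points) continue;
    NumericMatrix pts(n, 2);
    for (size_t k = 0; k < nb; ++k) { // backward half, reversed
      pts(k, 0) = bxs[nb - k];
      pts(k, 1) = bys[nb - k];
    }
    for (size_t k = 0; k < fxs.size(); ++k) {
      pts(nb + k, 0) = fxs[k];
      pts(nb + k, 1) = fys[k];
    }
    out.push_back(List::create(_["points"] = pts,
                               _["reason_start"] = bidirectional ? br : NA_INTEGER,
                               _["reason_end"] = fr,
                               _["iteration"] = it + 1));
  }
  return out;
}
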