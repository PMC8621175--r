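// Crystallographic similarity norms: for each site, the n_coord closest
// Voronoi neighbors are normalized by their mean radius and compared, over
// a scanned mesh of symmetry-element orientations, with their images under
// the reference crystal's characteristic symmetry operations.  The norm is
// the orientation-minimized RMS nearest-vector mismatch; a constant
// penalty of 1 applies when the shell is under-coordinated.
#include "polymc_core.h"
using namespace Rcpp;

typedef std::array<double, 9> Mat3;

static Mat3 mat_mult(const Mat3& A, const Mat3& B) {
  Mat3 C;
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 3; c++) {
      C[3 * r + c] = A[3 * r] * B[c] + A[3 * r + 1] * B[3 + c] + A[3 * r + 2] * B[6 + c];
    }
  return C;
}

static Vec3 mat_apply(const Mat3& M, const Vec3& v) {
  return Vec3(M[0] * v.x + M[1] * v.y + M[2] * v.z,
              M[3] * v.x + M[4] * v.y + M[5] * v.z,
              M[6] * v.x + M[7] * v.y + M[8] * v.z);
}

static Mat3 rot_axis(const Vec3& a, double ang) {
  double c = std::cos(ang), s = std::sin(ang), t = 1 - c;
  Mat3 M;
  M[0] = t * a.x * a.x + c;       M[1] = t * a.x * a.y - s * a.z; M[2] = t * a.x * a.z + s * a.y;
  M[3] = t * a.x * a.y + s * a.z; M[4] = t * a.y * a.y + c;       M[5] = t * a.y * a.z - s * a.x;
  M[6] = t * a.x * a.z - s * a.y; M[7] = t * a.y * a.z + s * a.x; M[8] = t * a.z * a.z + c;
  return M;
}

static Mat3 euler_zyz(double al, double be, double ga) {
  Mat3 Rz1 = rot_axis(Vec3(0, 0, 1), al);
  Mat3 Ry = rot_axis(Vec3(0, 1, 0), be);
  Mat3 Rz2 = rot_axis(Vec3(0, 0, 1), ga);
  return mat_mult(mat_mult(Rz1, Ry), Rz2);
}

struct Crystal {
  int n_coord;
  std::vector<Vec3> axes;
  int mult;
  bool improper, inversion;
  std::vector<int> powers;
  double roll_max;  // degrees; > 0 means a third Euler angle is scanned
};

// symmetry operations for a given frame orientation R
static void build_ops(const Crystal& cr, const Mat3& R, std::vector<Mat3>& ops) {
  ops.clear();
  for (size_t a = 0; a < cr.axes.size(); a++) {
    Vec3 ax = mat_apply(R, cr.axes[a]);
    for (size_t pw = 0; pw < cr.powers.size(); pw++) {
      int k = cr.powers[pw];
      Mat3 M = rot_axis(ax, 2 * M_PI * k / cr.mult);
      if (cr.improper && (k % 2 == 1)) {
        for (int q = 0; q < 9; q++) M[q] = -M[q];
      }
      ops.push_back(M);
    }
  }
  if (cr.inversion) {
    Mat3 I;
    I.fill(0);
    I[0] = I[4] = I[8] = -1;
    ops.push_back(I);
  }
}

// raw mismatch sum for one op table, with early abort at `bound`
static double mismatch_raw(const std::vector<Mat3>& ops,
                           const std::vector<Vec3>& u, double bound) {
  double acc = 0;
  int nc = u.size();
  for (size_t o = 0; o < ops.size(); o++) {
    const Mat3& M = ops[o];
    for (int k = 0; k < nc; k++) {
      Vec3 w = mat_apply(M, u[k]);
      double best = 1e18;
      for (int j = 0; j < nc; j++) {
        double d2 = (w - u[j]).norm2();
        if (d2 < best) best = d2;
      }
      acc += best;
      if (acc >= bound) return acc;
    }
  }
  return acc;
}

struct OrientGrid {
  std::vector<double> al, be, ga;
  std::vector<std::vector<Mat3> > ops;
};

static void build_grid(const Crystal& cr, double step_deg, int dim,
                       OrientGrid& g) {
  g.al.clear(); g.be.clear(); g.ga.clear(); g.ops.clear();
  double st = step_deg * M_PI / 180.0;
  if (dim == 2) {
    g.al.push_back(0); g.be.push_back(0); g.ga.push_back(0);
    std::vector<Mat3> ops;
    Mat3 I; I.fill(0); I[0] = I[4] = I[8] = 1;
    build_ops(cr, I, ops);
    g.ops.push_back(ops);
    return;
  }
  double gmax = (cr.roll_max > 0) ? cr.roll_max * M_PI / 180.0 : st;
  for (double be = 0; be <= M_PI / 2 + 1e-9; be += st) {
    double almax = (be < 1e-9) ? st : 2 * M_PI;
    for (double al = 0; al < almax - 1e-9; al += st) {
      for (double ga = 0; ga < gmax - 1e-9; ga += st) {
        g.al.push_back(al); g.be.push_back(be); g.ga.push_back(ga);
        std::vector<Mat3> ops;
        build_ops(cr, euler_zyz(al, be, ga), ops);
        g.ops.push_back(ops);
      }
    }
  }
}

// exact norm for one shell against one crystal (optionally stopping as
// soon as the norm drops below thres: on-the-fly labeling)
static double cce_eval(const Crystal& cr, const OrientGrid& grid,
                       const std::vector<Vec3>& u, int dim, double step_deg,
                       bool refine, bool on_the_fly, double thres) {
  // (refine may be disabled below when the mesh optimum is clearly
  // outside the labeling region)
  int nc = u.size();
  int nops = grid.ops[0].size();
  double denom = (double)nops * nc;
  double thres_raw = thres * thres * denom;
  double best = 1e18;
  int bestk = 0;
  for (size_t k = 0; k < grid.ops.size(); k++) {
    // in on-the-fly mode orientations are abandoned once they exceed the
    // labeling region; norms above ~1.5*thres become upper bounds
    double bound = on_the_fly ? std::min(best, thres_raw * 2.25) : best;
    double raw = mismatch_raw(grid.ops[k], u, bound);
    if (raw < best) { best = raw; bestk = k; }
    if (on_the_fly && best <= thres_raw) break;
  }
  if (on_the_fly && best > thres_raw * 2.25) refine = false;
  if (refine && dim == 3) {
    double al = grid.al[bestk], be = grid.be[bestk], ga = grid.ga[bestk];
    double st = step_deg * M_PI / 180.0 / 2;
    bool use_ga = cr.roll_max > 0;
    std::vector<Mat3> ops;
    while (st > 0.2 * M_PI / 180.0) {
      bool improved = false;
      double trial[6][3] = {
        {al + st, be, ga}, {al - st, be, ga},
        {al, be + st, ga}, {al, be - st, ga},
        {al, be, ga + st}, {al, be, ga - st}};
      int ntr = use_ga ? 6 : 4;
      for (int t = 0; t < ntr; t++) {
        build_ops(cr, euler_zyz(trial[t][0], trial[t][1], trial[t][2]), ops);
        double raw = mismatch_raw(ops, u, best);
        if (raw < best) {
          best = raw;
          al = trial[t][0]; be = trial[t][1]; ga = trial[t][2];
          improved = true;
        }
      }
      if (!improved) st /= 2;
    }
  }
  return std::sqrt(best / denom);
}

static double binom(int n, int k) {
  double r = 1;
  for (int i = 0; i < k; i++) r = r * (n - i) / (i + 1);
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_cce(List p, List vor, List cats, double phi_step,
                      double eps_thres, bool on_the_fly, bool refine) {
  Sys s;
  s.from_packed(p);
  List nb = vor["neighbors"];
  List disp = vor["disp"];
  List dst = vor["dists"];
  int ns = nb.size();
  int ncr = cats.size();
  std::vector<Crystal> crs(ncr);
  std::vector<OrientGrid> grids(ncr);
  for (int c = 0; c < ncr; c++) {
    List cl = cats[c];
    Crystal& cr = crs[c];
    cr.n_coord = as<int>(cl["n_coord"]);
    NumericMatrix ax = cl["axes"];
    for (int a = 0; a < ax.nrow(); a++) {
      cr.axes.push_back(Vec3(ax(a, 0), ax(a, 1), ax(a, 2)));
    }
    cr.mult = as<int>(cl["mult"]);
    cr.improper = as<bool>(cl["improper"]);
    cr.inversion = as<bool>(cl["inversion"]);
    cr.powers = as<std::vector<int> >(cl["powers"]);
    cr.roll_max = as<double>(cl["roll_max"]);
    build_grid(cr, phi_step, s.dim, grids[c]);
  }

  NumericMatrix out(ns, ncr);
  for (int q = 0; q < ns; q++) {
    NumericMatrix dp = disp[q];
    NumericVector dd = dst[q];
    int nv = dp.nrow();
    for (int c = 0; c < ncr; c++) {
      const Crystal& cr = crs[c];
      int nc = cr.n_coord;
      if (nv < nc) { out(q, c) = 1.0; continue; }  // penalty branch
      // tie-aware shell cut: equidistant neighbors spanning the cut are
      // resolved by taking the norm-maximizing subset (conservative)
      double dcut = dd[nc - 1];
      double lo = dcut * (1 - 1e-3), hi = dcut * (1 + 1e-3);
      std::vector<int> base, tied;
      for (int k = 0; k < nv; k++) {
        if (dd[k] < lo) base.push_back(k);
        else if (dd[k] <= hi) tied.push_back(k);
      }
      int need = nc - (int)base.size();
      std::vector<std::vector<int> > subsets;
      if (need > 0 && tied.size() > (size_t)need &&
          binom(tied.size(), need) <= 64) {
        // enumerate subsets of `tied` of size `need`
        std::vector<int> idx(need);
        for (int k = 0; k < need; k++) idx[k] = k;
        while (true) {
          std::vector<int> sub = base;
          for (int k = 0; k < need; k++) sub.push_back(tied[idx[k]]);
          subsets.push_back(sub);
          int t = need - 1;
          while (t >= 0 && idx[t] == (int)tied.size() - need + t) t--;
          if (t < 0) break;
          idx[t]++;
          for (int k = t + 1; k < need; k++) idx[k] = idx[k - 1] + 1;
        }
      } else {
        std::vector<int> sub = base;
        for (int k = 0; k < need; k++) sub.push_back(tied[k]);
        subsets.push_back(sub);
      }
      double eps = 0;  // max over tie subsets
      for (size_t ss = 0; ss < subsets.size(); ss++) {
        std::vector<Vec3> u(nc);
        double mean = 0;
        for (int k = 0; k < nc; k++) {
          int w = subsets[ss][k];
          u[k] = Vec3(dp(w, 0), dp(w, 1), dp(w, 2));
          mean += dd[w];
        }
        mean /= nc;
        for (int k = 0; k < nc; k++) u[k] = u[k] * (1.0 / mean);
        double e = cce_eval(cr, grids[c], u, s.dim, phi_step, refine,
                            on_the_fly, eps_thres);
        if (e > eps) eps = e;
      }
      out(q, c) = eps;
      if (on_the_fly && eps <= eps_thres) {
        for (int c2 = c + 1; c2 < ncr; c2++) out(q, c2) = NA_REAL;
        break;
      }
    }
    if ((q & 0x0F) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
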