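// Shared system state, cell list and energy kernels for the MC engine.
// Units: lengths in sigma, energies in kT. Coordinates are stored padded to
// 3 components; dim==2 systems keep z == 0 and ignore the third dimension.
// Chain connectivity is held as an undirected bond list (<= 2 bonds per
// site, simple paths only); directed successor/predecessor arrays are only
// derived at the R boundary.
#ifndef POLYMC_CORE_H
#define POLYMC_CORE_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
#include <algorithm>

static const double INF = std::numeric_limits<double>::infinity();

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

// rotation of v about unit axis a by angle (Rodrigues)
inline Vec3 rotate_about(const Vec3& v, const Vec3& a, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  Vec3 axv = a.cross(v);
  double ad = a.dot(v);
  return v * c + axv * s + a * (ad * (1 - c));
}

enum ConfType { CONF_NONE = 0, CONF_WALLS = 1, CONF_CYL = 2, CONF_SPH = 3 };
enum Mode { MODE_HS = 0, MODE_SW = 1, MODE_SS = 2, MODE_LJ = 3 };

struct Filler {
  int kind;        // 0 sphere, 1 cylinder
  Vec3 c;          // center (sphere) / transverse anchor (cylinder)
  double d;        // diameter
  int axis;        // cylinder axis dimension, 0-based
};

struct Sys {
  int n, dim;
  std::vector<Vec3> X;
  double L[3];
  bool per[3];
  int conf, caxis;                 // caxis 0-based cylinder axis
  std::vector<Filler> fillers;
  std::vector<std::array<int, 2> > bnd;  // undirected bonds, -1 = empty slot
  // interaction spec
  int mode;
  double sigma, sigma2, eps, epslj, sglj, rcut, dl, bond_lo;
  double kth, th0, ktor, tor0;     // angles in degrees
  bool ex13;
  double s2core;                   // sigma^2 with overlap tolerance
  double rng2;                     // interaction range squared
  double ljshift;
  // cell list
  int nb[3];
  double bw[3];
  std::vector<int> head, nextp, binof;
  std::vector<int> stencil;      // nstencil neighbor bins per bin
  int nstencil;

  int nbond(int i) const { return (bnd[i][0] >= 0) + (bnd[i][1] >= 0); }
  // the neighbor of i other than j (-1 if none)
  int other(int i, int j) const {
    if (bnd[i][0] == j) return bnd[i][1];
    if (bnd[i][1] == j) return bnd[i][0];
    return -2;  // j is not bonded to i
  }
  void add_bond(int i, int j) {
    bnd[i][bnd[i][0] < 0 ? 0 : 1] = j;
    bnd[j][bnd[j][0] < 0 ? 0 : 1] = i;
  }
  void del_bond(int i, int j) {
    if (bnd[i][0] == j) bnd[i][0] = -1; else bnd[i][1] = -1;
    if (bnd[j][0] == i) bnd[j][0] = -1; else bnd[j][1] = -1;
  }

  double range() const {
    switch (mode) {
      case MODE_SW: case MODE_SS: return sigma2;
      case MODE_LJ: return rcut;
      default: return sigma;
    }
  }

  void from_packed(const Rcpp::List& p) {
    Rcpp::NumericMatrix co = p["coords"];
    n = co.nrow();
    dim = Rcpp::as<int>(p["dim"]);
    X.resize(n);
    for (int i = 0; i < n; i++) X[i] = Vec3(co(i, 0), co(i, 1), co(i, 2));
    Rcpp::NumericVector Lr = p["L"];
    Rcpp::LogicalVector pr = p["periodic"];
    for (int d = 0; d < 3; d++) { L[d] = Lr[d]; per[d] = pr[d]; }
    conf = Rcpp::as<int>(p["conf"]);
    caxis = Rcpp::as<int>(p["conf_axis"]) - 1;
    Rcpp::NumericMatrix fm = p["fillers"];
    fillers.clear();
    for (int k = 0; k < fm.nrow(); k++) {
      Filler f;
      f.kind = (int)fm(k, 0);
      f.c = Vec3(fm(k, 1), fm(k, 2), fm(k, 3));
      f.d = fm(k, 4);
      f.axis = (int)fm(k, 5) - 1;
      fillers.push_back(f);
    }
    std::vector<int> nxt = Rcpp::as<std::vector<int> >(p["nxt"]);
    std::array<int, 2> none = {{-1, -1}};
    bnd.assign(n, none);
    for (int i = 0; i < n; i++) if (nxt[i] >= 0) add_bond(i, nxt[i]);
    Rcpp::NumericVector sp = p["spec"];
    mode = (int)sp[0];
    sigma = sp[1]; sigma2 = sp[2]; eps = sp[3]; epslj = sp[4]; sglj = sp[5];
    rcut = sp[6]; dl = sp[7]; bond_lo = sp[8];
    kth = sp[9]; th0 = sp[10]; ktor = sp[11]; tor0 = sp[12];
    ex13 = sp[13] != 0;
    s2core = sigma * sigma * (1 - 1e-12);
    double r = range();
    rng2 = r * r;
    ljshift = 0;
    if (mode == MODE_LJ) {
      double sr6 = std::pow(sglj / rcut, 6.0);
      ljshift = 4 * epslj * (sr6 * sr6 - sr6);
    }
  }

  // derive directed links (arbitrary orientation per chain) for the R side
  Rcpp::List to_state() const {
    Rcpp::NumericMatrix co(n, 3);
    for (int i = 0; i < n; i++) { co(i, 0) = X[i].x; co(i, 1) = X[i].y; co(i, 2) = X[i].z; }
    std::vector<int> nxt(n, -1), prv(n, -1), chain(n, 0);
    std::vector<char> seen(n, 0);
    int cid = 0;
    for (int i = 0; i < n; i++) {
      if (seen[i] || nbond(i) != 1) continue;
      cid++;
      int prev = -1, cur = i;
      while (cur >= 0) {
        seen[cur] = 1;
        chain[cur] = cid;
        prv[cur] = prev;
        int nx = (bnd[cur][0] != prev && bnd[cur][0] >= 0) ? bnd[cur][0]
                 : (bnd[cur][1] != prev ? bnd[cur][1] : -1);
        if (nx == prev) nx = -1;
        nxt[cur] = nx;
        prev = cur;
        cur = nx;
      }
    }
    return Rcpp::List::create(
      Rcpp::Named("coords") = co,
      Rcpp::Named("L") = Rcpp::NumericVector::create(L[0], L[1], L[2]),
      Rcpp::Named("nxt") = nxt, Rcpp::Named("prv") = prv,
      Rcpp::Named("chain") = chain);
  }

  double volume() const {
    double v = 1;
    for (int d = 0; d < dim; d++) v *= L[d];
    return v;
  }

  double phi() const {
    double vm = (dim == 2) ? n * M_PI / 4 * sigma * sigma
                           : n * M_PI / 6 * sigma * sigma * sigma;
    return vm / volume();
  }

  // minimum-image displacement b - a (coordinates live in [0, L), so one
  // fold per dimension suffices)
  Vec3 delta(const Vec3& a, const Vec3& b) const {
    Vec3 d = b - a;
    double* c = &d.x;
    for (int k = 0; k < dim; k++) {
      if (per[k]) {
        double hl = 0.5 * L[k];
        if (c[k] > hl) c[k] -= L[k];
        else if (c[k] < -hl) c[k] += L[k];
      }
    }
    if (dim == 2) d.z = 0;
    return d;
  }

  double dist2(int i, int j) const { return delta(X[i], X[j]).norm2(); }

  void wrap(Vec3& v) const {
    double* c = &v.x;
    for (int k = 0; k < dim; k++) {
      if (per[k]) {
        c[k] -= L[k] * std::floor(c[k] / L[k]);
        if (c[k] >= L[k] || c[k] < 0) c[k] = 0;  // guard against round-off
      }
    }
    if (dim == 2) v.z = 0;
  }

  // wall / filler / closed-confinement clearance: true if position allowed
  bool site_ok(const Vec3& v) const {
    const double* c = &v.x;
    double h = sigma / 2 * (1 - 1e-12);
    if (conf == CONF_WALLS) {
      for (int d = 0; d < dim; d++) {
        if (!per[d] && (c[d] < h || c[d] > L[d] - h)) return false;
      }
    } else if (conf == CONF_CYL) {
      double r2 = 0;
      int t = -1;
      for (int d = 0; d < 3; d++) {
        if (d == caxis || d >= dim) continue;
        double dd = c[d] - L[d] / 2;
        r2 += dd * dd;
        t = d;
      }
      double rmax = L[t] / 2 - h;
      if (rmax < 0 || r2 > rmax * rmax) return false;
      if (!per[caxis] && (c[caxis] < h || c[caxis] > L[caxis] - h)) return false;
    } else if (conf == CONF_SPH) {
      double r2 = 0;
      for (int d = 0; d < dim; d++) {
        double dd = c[d] - L[d] / 2;
        r2 += dd * dd;
      }
      double rmax = L[0] / 2 - h;
      if (rmax < 0 || r2 > rmax * rmax) return false;
    }
    for (size_t k = 0; k < fillers.size(); k++) {
      const Filler& f = fillers[k];
      double rmin = (f.d + sigma) / 2 * (1 - 1e-12);
      if (f.kind == 0) {
        Vec3 d = delta(f.c, v);
        if (d.norm2() < rmin * rmin) return false;
      } else {
        double r2 = 0;
        const double* fc = &f.c.x;
        for (int d = 0; d < 3; d++) {
          if (d == f.axis || d >= dim) continue;
          double dd = c[d] - fc[d];
          if (per[d]) dd -= L[d] * std::round(dd / L[d]);
          r2 += dd * dd;
        }
        if (r2 < rmin * rmin) return false;
      }
    }
    return true;
  }

  // ---- cell list ----------------------------------------------------
  void build_cells() {
    double r = std::max(range(), sigma + dl);
    for (int d = 0; d < 3; d++) {
      if (d < dim) {
        nb[d] = std::max(1, (int)std::floor(L[d] / r));
        bw[d] = L[d] / nb[d];
      } else { nb[d] = 1; bw[d] = 1; }
    }
    head.assign(nb[0] * nb[1] * nb[2], -1);
    nextp.assign(n, -1);
    binof.assign(n, -1);
    for (int i = 0; i < n; i++) insert_cell(i);
    build_stencil();
  }

  // per-bin table of (deduplicated) neighbor bins, padded with -1
  void build_stencil() {
    int nbins = nb[0] * nb[1] * nb[2];
    nstencil = 27;
    stencil.assign((size_t)nbins * nstencil, -1);
    std::vector<int> tmp;
    for (int bz = 0; bz < nb[2]; bz++) {
      for (int by = 0; by < nb[1]; by++) {
        for (int bx = 0; bx < nb[0]; bx++) {
          int bidx = (bz * nb[1] + by) * nb[0] + bx;
          Vec3 v((bx + 0.5) * bw[0], (by + 0.5) * bw[1], (bz + 0.5) * bw[2]);
          neighbor_bins_slow(v, tmp);
          for (size_t k = 0; k < tmp.size() && (int)k < nstencil; k++) {
            stencil[(size_t)bidx * nstencil + k] = tmp[k];
          }
        }
      }
    }
  }

  const int* bin_stencil(const Vec3& v) const {
    return &stencil[(size_t)bin_index(v) * nstencil];
  }

  int bin_index(const Vec3& v) const {
    const double* c = &v.x;
    int b[3] = {0, 0, 0};
    for (int d = 0; d < dim; d++) {
      int k = (int)std::floor(c[d] / bw[d]);
      if (k < 0) k = 0;
      if (k >= nb[d]) k = nb[d] - 1;
      b[d] = k;
    }
    return (b[2] * nb[1] + b[1]) * nb[0] + b[0];
  }

  void insert_cell(int i) {
    int b = bin_index(X[i]);
    binof[i] = b;
    nextp[i] = head[b];
    head[b] = i;
  }

  void remove_cell(int i) {
    int b = binof[i];
    int j = head[b];
    if (j == i) { head[b] = nextp[i]; return; }
    while (j >= 0) {
      if (nextp[j] == i) { nextp[j] = nextp[i]; return; }
      j = nextp[j];
    }
  }

  void move_cell(int i) {
    int b = bin_index(X[i]);
    if (b != binof[i]) { remove_cell(i); insert_cell(i); }
  }

  // collect (deduplicated) neighbor bins of a position
  void neighbor_bins(const Vec3& v, std::vector<int>& out) const {
    const int* st = bin_stencil(v);
    out.clear();
    for (int k = 0; k < nstencil && st[k] >= 0; k++) out.push_back(st[k]);
  }

  void neighbor_bins_slow(const Vec3& v, std::vector<int>& out) const {
    out.clear();
    const double* c = &v.x;
    int b[3] = {0, 0, 0};
    for (int d = 0; d < dim; d++) {
      int k = (int)std::floor(c[d] / bw[d]);
      if (k < 0) k = 0;
      if (k >= nb[d]) k = nb[d] - 1;
      b[d] = k;
    }
    // with >= 3 bins per dimension the 27-stencil never repeats a bin
    bool nodup = true;
    for (int d = 0; d < dim; d++) if (nb[d] < 3) nodup = false;
    int lo[3], hi[3];
    for (int d = 0; d < 3; d++) {
      if (d >= dim || nb[d] == 1) { lo[d] = hi[d] = b[d]; continue; }
      lo[d] = b[d] - 1; hi[d] = b[d] + 1;
    }
    for (int kz = lo[2]; kz <= hi[2]; kz++) {
      for (int ky = lo[1]; ky <= hi[1]; ky++) {
        for (int kx = lo[0]; kx <= hi[0]; kx++) {
          int q[3] = {kx, ky, kz};
          bool ok = true;
          for (int d = 0; d < dim; d++) {
            if (q[d] < 0) { if (per[d]) q[d] += nb[d]; else ok = false; }
            else if (q[d] >= nb[d]) { if (per[d]) q[d] -= nb[d]; else ok = false; }
          }
          if (!ok) continue;
          int idx = (q[2] * nb[1] + q[1]) * nb[0] + q[0];
          if (nodup || std::find(out.begin(), out.end(), idx) == out.end())
            out.push_back(idx);
        }
      }
    }
  }

  // scratch buffer reused by the energy kernels (single-threaded engine)
  mutable std::vector<int> binscratch;

  // ---- energies -----------------------------------------------------
  double pairU(double r2) const {
    switch (mode) {
      case MODE_HS:
        return (r2 < s2core) ? INF : 0.0;
      case MODE_SW:
        if (r2 < s2core) return INF;
        return (r2 < sigma2 * sigma2) ? -eps : 0.0;
      case MODE_SS:
        if (r2 < s2core) return INF;
        return (r2 < sigma2 * sigma2) ? eps : 0.0;
      default: {
        if (r2 >= rcut * rcut) return 0.0;
        double sr6 = std::pow(sglj * sglj / r2, 3.0);
        return 4 * epslj * (sr6 * sr6 - sr6) - ljshift;
      }
    }
  }

  bool bonded12(int i, int j) const {
    return bnd[i][0] == j || bnd[i][1] == j;
  }

  bool excluded(int i, int j) const {
    if (bonded12(i, j)) return true;
    if (ex13) {
      for (int a = 0; a < 2; a++) {
        int m = bnd[i][a];
        if (m < 0) continue;
        if (bnd[m][0] == j || bnd[m][1] == j) return true;
      }
    }
    return false;
  }

  double bond_energy(double r2) const {
    double lo = bond_lo - 1e-9, hi = sigma + dl + 1e-9;
    if (r2 < lo * lo || r2 > hi * hi) return INF;
    return 0.0;
  }

  // bending-angle supplement (degrees) at center xj of triplet xi-xj-xk
  double bend_theta(const Vec3& xi, const Vec3& xj, const Vec3& xk) const {
    Vec3 u = delta(xi, xj), v = delta(xj, xk);
    double c = u.dot(v) / std::sqrt(u.norm2() * v.norm2());
    c = std::max(-1.0, std::min(1.0, c));
    return std::acos(c) * 180.0 / M_PI;
  }

  double bend_energy_at(int j) const {
    if (kth <= 0) return 0.0;
    int i = bnd[j][0], k = bnd[j][1];
    if (i < 0 || k < 0) return 0.0;
    double th = bend_theta(X[i], X[j], X[k]);
    double d = th - th0;
    return kth * d * d;
  }

  double torsion_quad(const Vec3& xi, const Vec3& xj, const Vec3& xk,
                      const Vec3& xl) const {
    Vec3 b1 = delta(xi, xj), b2 = delta(xj, xk), b3 = delta(xk, xl);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double nn = std::sqrt(n1.norm2() * n2.norm2());
    if (nn < 1e-12) return 0.0;
    double cphi = std::max(-1.0, std::min(1.0, n1.dot(n2) / nn));
    double phi = std::acos(cphi) * 180.0 / M_PI;
    double d = (phi - tor0) * M_PI / 180.0;
    return ktor * (1 - std::cos(d));
  }

  // torsion on the quad around bond (j, k)
  double torsion_energy_at_bond(int j, int k) const {
    if (ktor <= 0) return 0.0;
    int i = other(j, k), l = other(k, j);
    if (i < 0 || l < 0) return 0.0;
    return torsion_quad(X[i], X[j], X[k], X[l]);
  }

  // non-bonded energy of a (possibly virtual) position for site i,
  // skipping sites flagged in `skip` (regrowth) and bonded exclusions
  double nb_energy_at(int i, const Vec3& v, const std::vector<char>* skip = 0) const {
    if (!site_ok(v)) return INF;
    double E = 0;
    const int* st = bin_stencil(v);
    for (int b = 0; b < nstencil && st[b] >= 0; b++) {
      for (int j = head[st[b]]; j >= 0; j = nextp[j]) {
        if (j == i) continue;
        if (skip && (*skip)[j]) continue;
        if (i >= 0 && excluded(i, j)) continue;
        double r2 = delta(v, X[j]).norm2();
        if (r2 < rng2) {
          double u = pairU(r2);
          if (u == INF) return INF;
          E += u;
        }
      }
    }
    return E;
  }

  // full local energy of site i at virtual position v: non-bonded +
  // incident bonds + bending triplets containing i + torsions touching i
  double site_local_energy(int i, const Vec3& v) {
    Vec3 old = X[i];
    X[i] = v;
    double E = nb_energy_at(i, v);
    int p = bnd[i][0], q = bnd[i][1];
    if (E != INF) {
      if (p >= 0) E += bond_energy(delta(X[p], v).norm2());
      if (E != INF && q >= 0) E += bond_energy(delta(v, X[q]).norm2());
    }
    if (E != INF && kth > 0) {
      E += bend_energy_at(i);
      if (p >= 0) E += bend_energy_at(p);
      if (q >= 0) E += bend_energy_at(q);
    }
    if (E != INF && ktor > 0) {
      for (int a = 0; a < 2; a++) {
        int m = bnd[i][a];
        if (m < 0) continue;
        E += torsion_energy_at_bond(i, m);
        int m2 = other(m, i);
        if (m2 >= 0) E += torsion_energy_at_bond(m, m2);
      }
    }
    X[i] = old;
    return E;
  }

  double total_energy() {
    double E = 0;
    std::vector<int> bins;
    for (int i = 0; i < n; i++) {
      neighbor_bins(X[i], bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = head[bins[b]]; j >= 0; j = nextp[j]) {
          if (j <= i) continue;
          if (excluded(i, j)) continue;
          double r2 = dist2(i, j);
          if (r2 < rng2) {
            double u = pairU(r2);
            if (u == INF) return INF;
            E += u;
          }
        }
      }
      if (!site_ok(X[i])) return INF;
      for (int a = 0; a < 2; a++) {
        int j = bnd[i][a];
        if (j > i) {
          double eb = bond_energy(dist2(i, j));
          if (eb == INF) return INF;
          E += eb;
          if (ktor > 0) E += torsion_energy_at_bond(i, j);
        }
      }
      if (kth > 0) E += bend_energy_at(i);
    }
    return E;
  }

  bool any_overlap_site(int i) {
    if (!site_ok(X[i])) return true;
    std::vector<int> bins;
    neighbor_bins(X[i], bins);
    for (size_t b = 0; b < bins.size(); b++) {
      for (int j = head[bins[b]]; j >= 0; j = nextp[j]) {
        if (j == i) continue;
        double r2 = dist2(i, j);
        if (bonded12(i, j)) {
          if (bond_energy(r2) == INF) return true;
        } else if (r2 < s2core) return true;
      }
    }
    return false;
  }

  bool any_overlap() {
    // a site overlaps its own periodic image when the cell is thinner
    // than sigma along a periodic dimension
    for (int d = 0; d < dim; d++) {
      if (per[d] && L[d] < sigma * (1 - 1e-12)) return true;
    }
    for (int i = 0; i < n; i++) {
      if (any_overlap_half(i)) return true;
    }
    return false;
  }

  bool any_overlap_half(int i) {
    if (!site_ok(X[i])) return true;
    std::vector<int> bins;
    neighbor_bins(X[i], bins);
    for (size_t b = 0; b < bins.size(); b++) {
      for (int j = head[bins[b]]; j >= 0; j = nextp[j]) {
        if (j <= i) continue;
        double r2 = dist2(i, j);
        if (bonded12(i, j)) {
          if (bond_energy(r2) == INF) return true;
        } else if (r2 < s2core) return true;
      }
    }
    return false;
  }
};

inline Sys make_sys(const Rcpp::List& p) {
  Sys s;
  s.from_packed(p);
  s.build_cells();
  return s;
}

// ---- sampling helpers (R RNG; callers hold an RNGScope) --------------
inline double ru() { return unif_rand(); }

inline Vec3 rand_unit(int dim) {
  if (dim == 2) {
    double a = 2 * M_PI * ru();
    return Vec3(std::cos(a), std::sin(a), 0);
  }
  double z = 2 * ru() - 1;
  double a = 2 * M_PI * ru();
  double r = std::sqrt(std::max(0.0, 1 - z * z));
  return Vec3(r * std::cos(a), r * std::sin(a), z);
}

// bending-angle supplement sample from the Boltzmann density
//   3-d: f(theta) ~ exp(-k (theta_deg - th0)^2) sin(theta)
//   2-d: f(theta) ~ exp(-k (theta_deg - th0)^2)
inline double sample_theta_rad(double kth, double th0, int dim) {
  if (kth <= 0) {
    if (dim == 2) return M_PI * ru();
    return std::acos(1 - 2 * ru());
  }
  double M = 0;
  for (int g = 0; g <= 360; g++) {
    double th = M_PI * g / 360.0;
    double d = th * 180.0 / M_PI - th0;
    double f = std::exp(-kth * d * d);
    if (dim == 3) f *= std::sin(th);
    if (f > M) M = f;
  }
  M *= 1.05;
  for (int it = 0; it < 100000; it++) {
    double th = M_PI * ru();
    double d = th * 180.0 / M_PI - th0;
    double f = std::exp(-kth * d * d);
    if (dim == 3) f *= std::sin(th);
    if (ru() * M < f) return th;
  }
  return th0 * M_PI / 180.0;  // pathological stiffness: return the mode
}

// grow a new bond direction at supplement angle theta from previous bond
// direction u (unit); torsion uniform
inline Vec3 grow_dir(const Vec3& u, double theta, int dim) {
  if (dim == 2) {
    double sgn = (ru() < 0.5) ? 1.0 : -1.0;
    return rotate_about(u, Vec3(0, 0, 1), sgn * theta);
  }
  // orthonormal frame around u
  Vec3 a = (std::fabs(u.x) < 0.9) ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  Vec3 n1 = u.cross(a);
  n1 = n1 * (1.0 / n1.norm());
  Vec3 n2 = u.cross(n1);
  double phi = 2 * M_PI * ru();
  return u * std::cos(theta) +
         (n1 * std::cos(phi) + n2 * std::sin(phi)) * std::sin(theta);
}

#endif
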