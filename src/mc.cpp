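// Monte Carlo driver: local (optionally configurational-bias) moves,
// chain-connectivity-altering and identity-exchange moves with semigrand
// length-distribution weights, rigid cluster moves, volume moves, the
// athermal compression protocol and the dilute-system generator.
#include "polymc_core.h"
#include <functional>
using namespace Rcpp;

enum MoveId {
  M_DISP = 0, M_FLIP, M_ENDROT, M_REPT, M_XREPT, M_REGROW,
  M_SEB, M_SIEB, M_SDB, M_IDEX1, M_IDEX2, M_IDEX3,
  M_CLUDIS, M_CLUROT, M_VOL, N_MOVES
};

struct Schedule {
  double probs[N_MOVES];
  int ntr[N_MOVES];
  double l_disp[3];
  double amp_flip, amp_rot;
  int n_regrow;
  double linkage, amp_cludis, amp_clurot, amp_vol;
  bool vol_aniso;
};

struct Ens {
  int type;  // 0 NVT, 1 NPT, 2 semigrand
  double P;
  int nmin, nmax;
  std::vector<double> wlog;
  bool mono;
  double wl(int N) const {
    if (N < nmin || N > nmax) return -INF;
    return wlog[N - nmin];
  }
};

static Schedule parse_schedule(const List& sc) {
  Schedule o;
  NumericVector pr = sc["probs"];
  IntegerVector nt = sc["n_trials"];
  NumericVector ld = sc["l_disp"];
  for (int k = 0; k < N_MOVES; k++) { o.probs[k] = pr[k]; o.ntr[k] = nt[k]; }
  for (int d = 0; d < 3; d++) o.l_disp[d] = ld[d];
  o.amp_flip = as<double>(sc["amp_flip"]) * M_PI / 180.0;
  o.amp_rot = as<double>(sc["amp_rot"]) * M_PI / 180.0;
  o.n_regrow = as<int>(sc["n_regrow"]);
  o.linkage = as<double>(sc["linkage"]);
  o.amp_cludis = as<double>(sc["amp_cludis"]);
  o.amp_clurot = as<double>(sc["amp_clurot"]) * M_PI / 180.0;
  o.amp_vol = as<double>(sc["amp_vol"]);
  o.vol_aniso = as<bool>(sc["vol_aniso"]);
  return o;
}

static Ens parse_ens(const List& en) {
  Ens o;
  o.type = as<int>(en["type"]);
  o.P = as<double>(en["pressure"]);
  o.nmin = as<int>(en["n_min"]);
  o.nmax = as<int>(en["n_max"]);
  o.wlog = as<std::vector<double> >(en["wlog"]);
  o.mono = as<bool>(en["monodisperse"]);
  return o;
}

struct Driver {
  Sys s;
  Schedule sc;
  Ens en;
  bool debug;
  // topology bookkeeping (rebuilt after connectivity changes)
  std::vector<int> headv, tailv, lenv;  // per chain slot
  std::vector<int> cid, pos;            // slot+1 per site (0 single), 1-based pos
  std::vector<int> singles;
  long att[N_MOVES], acc[N_MOVES], skp[N_MOVES];

  Driver(const List& p, const List& scl, const List& enl, bool dbg) {
    s.from_packed(p);
    s.build_cells();
    sc = parse_schedule(scl);
    en = parse_ens(enl);
    debug = dbg;
    for (int k = 0; k < N_MOVES; k++) att[k] = acc[k] = skp[k] = 0;
    rebuild_topology();
  }

  void rebuild_topology() {
    int n = s.n;
    headv.clear(); tailv.clear(); lenv.clear(); singles.clear();
    cid.assign(n, 0); pos.assign(n, 0);
    std::vector<char> seen(n, 0);
    for (int i = 0; i < n; i++) {
      if (seen[i] || s.nbond(i) != 1) continue;
      int slot = headv.size();
      headv.push_back(i);
      int prev = -1, cur = i, k = 0;
      while (cur >= 0) {
        seen[cur] = 1;
        k++;
        cid[cur] = slot + 1;
        pos[cur] = k;
        int nx = (s.bnd[cur][0] != prev && s.bnd[cur][0] >= 0) ? s.bnd[cur][0]
                 : (s.bnd[cur][1] != prev ? s.bnd[cur][1] : -1);
        prev = cur;
        cur = nx;
      }
      tailv.push_back(prev);
      lenv.push_back(k);
    }
    for (int i = 0; i < n; i++) if (s.nbond(i) == 0) singles.push_back(i);
  }

  int site_at_pos(int slot, int t) const {  // walk from head, O(t)
    int prev = -1, cur = headv[slot];
    for (int k = 1; k < t; k++) {
      int nx = (s.bnd[cur][0] != prev && s.bnd[cur][0] >= 0) ? s.bnd[cur][0]
               : s.bnd[cur][1];
      prev = cur; cur = nx;
    }
    return cur;
  }

  static double wexp(double d) { return (d == INF) ? 0.0 : std::exp(-d); }

  bool metropolis(double dE) {
    if (dE == INF) return false;
    if (dE <= 0) return true;
    return ru() < std::exp(-dE);
  }

  // ---- CB single-site reposition (displacement / flip / end rotation) --
  int cb_reposition(int i, int ntr, const std::function<Vec3(const Vec3&)>& prop) {
    if (ntr == 1) {  // conventional Metropolis execution
      Vec3 v = prop(s.X[i]);
      s.wrap(v);
      double e1 = s.site_local_energy(i, v);
      if (e1 == INF) return 0;
      // athermal hard-core systems: energies are 0 or infinite
      bool athermal = s.mode == MODE_HS && s.kth <= 0 && s.ktor <= 0;
      if (!athermal) {
        double dE = e1 - s.site_local_energy(i, s.X[i]);
        if (dE > 0 && ru() >= std::exp(-dE)) return 0;
      }
      s.X[i] = v;
      s.move_cell(i);
      return 1;
    }
    double Eold = s.site_local_energy(i, s.X[i]);
    std::vector<Vec3> cand(ntr);
    std::vector<double> Ef(ntr);
    double Emin = Eold;
    for (int k = 0; k < ntr; k++) {
      cand[k] = prop(s.X[i]);
      s.wrap(cand[k]);
      Ef[k] = s.site_local_energy(i, cand[k]);
      if (Ef[k] < Emin) Emin = Ef[k];
    }
    if (Emin == INF) return 0;
    double Wf = 0;
    for (int k = 0; k < ntr; k++) Wf += wexp(Ef[k] - Emin);
    if (Wf <= 0) return 0;
    double r = ru() * Wf, cum = 0;
    int ksel = ntr - 1;
    for (int k = 0; k < ntr; k++) { cum += wexp(Ef[k] - Emin); if (r <= cum) { ksel = k; break; } }
    double Wr = wexp(Eold - Emin);
    for (int k = 0; k < ntr - 1; k++) {
      Vec3 y = prop(cand[ksel]);
      s.wrap(y);
      Wr += wexp(s.site_local_energy(i, y) - Emin);
    }
    if (Wr <= 0) return 0;
    if (ru() >= Wf / Wr) return 0;
    s.X[i] = cand[ksel];
    s.move_cell(i);
    return 1;
  }

  int mv_displace() {
    if (s.n == 0) return 2;
    int i = (int)(ru() * s.n);
    const double* ld = sc.l_disp;
    int dim = s.dim;
    return cb_reposition(i, sc.ntr[M_DISP], [&, this](const Vec3& x0) {
      Vec3 v = x0;
      double* c = &v.x;
      for (int d = 0; d < dim; d++) c[d] += (2 * ru() - 1) * ld[d];
      return v;
    });
  }

  int mv_flip() {
    if (headv.empty()) return 2;
    int slot = (int)(ru() * headv.size());
    if (lenv[slot] < 3) return 2;
    int i = site_at_pos(slot, 2 + (int)(ru() * (lenv[slot] - 2)));
    int p = s.bnd[i][0], q = s.bnd[i][1];
    Vec3 ax = s.delta(s.X[p], s.X[q]);
    double an = ax.norm();
    if (an < 1e-9) return 2;
    ax = ax * (1.0 / an);
    Vec3 xp = s.X[p];
    double amp = sc.amp_flip;
    Sys* sp = &s;
    return cb_reposition(i, sc.ntr[M_FLIP], [sp, ax, xp, amp](const Vec3& x0) {
      double ang = (2 * ru() - 1) * amp;
      Vec3 rel = sp->delta(xp, x0);
      return xp + rotate_about(rel, ax, ang);
    });
  }

  int mv_endrot() {
    if (headv.empty()) return 2;
    int slot = (int)(ru() * headv.size());
    int i = (ru() < 0.5) ? headv[slot] : tailv[slot];
    int m = (s.bnd[i][0] >= 0) ? s.bnd[i][0] : s.bnd[i][1];
    if (m < 0) return 2;
    Vec3 xm = s.X[m];
    double amp = sc.amp_rot;
    int dim = s.dim;
    Sys* sp = &s;
    return cb_reposition(i, sc.ntr[M_ENDROT], [sp, xm, amp, dim](const Vec3& x0) {
      Vec3 ax = (dim == 2) ? Vec3(0, 0, 1) : rand_unit(3);
      double ang = (2 * ru() - 1) * amp;
      Vec3 rel = sp->delta(xm, x0);
      return xm + rotate_about(rel, ax, ang);
    });
  }

  // non-bonded energy of a virtual position with an explicit exclusion list
  double nb_pos(const Vec3& v, const int* excl, int nexcl) {
    if (!s.site_ok(v)) return INF;
    double E = 0;
    std::vector<int> bins;
    s.neighbor_bins(v, bins);
    for (size_t b = 0; b < bins.size(); b++) {
      for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
        bool ex = false;
        for (int k = 0; k < nexcl; k++) if (excl[k] == j) { ex = true; break; }
        if (ex) continue;
        double r2 = s.delta(v, s.X[j]).norm2();
        if (r2 < s.rng2) {
          double u = s.pairU(r2);
          if (u == INF) return INF;
          E += u;
        }
      }
    }
    return E;
  }

  // external (weight) energy of placing the transferred monomer `mov` at v,
  // bonded to chain end `att_to` whose inward neighbor is a2 (may be -1)
  double grow_ext_energy(int mov, const Vec3& v, int att_to, int a2) {
    int excl[3];
    int ne = 0;
    excl[ne++] = mov;
    excl[ne++] = att_to;
    if (s.ex13 && a2 >= 0) excl[ne++] = a2;
    double E = nb_pos(v, excl, ne);
    if (E != INF && s.ktor > 0 && a2 >= 0) {
      int a3 = s.other(a2, att_to);
      if (a3 >= 0) E += s.torsion_quad(s.X[a3], s.X[a2], s.X[att_to], v);
    }
    return E;
  }

  Vec3 sample_growth(int att_to, int a2) {
    double blen = s.bond_lo + ru() * (s.sigma + s.dl - s.bond_lo);
    Vec3 dir;
    if (a2 >= 0) {
      Vec3 u = s.delta(s.X[a2], s.X[att_to]);
      u = u * (1.0 / u.norm());
      double th = sample_theta_rad(s.kth, s.th0, s.dim);
      dir = grow_dir(u, th, s.dim);
    } else {
      dir = rand_unit(s.dim);
    }
    Vec3 v = s.X[att_to] + dir * blen;
    s.wrap(v);
    return v;
  }

  // transfer end monomer `rem` (bonded to rnb) to become the new end bonded
  // to `grow`; extra_logw adds semigrand weight ratios. 0 reject, 1 accept.
  int transfer_end(int rem, int grow, int ntr, double extra_logw) {
    if (extra_logw == -INF) return 0;
    int rnb = (s.bnd[rem][0] >= 0) ? s.bnd[rem][0] : s.bnd[rem][1];
    if (rnb < 0) return 0;
    int g2 = s.other(grow, rem);      // grow's inward neighbor in the new state
    if (g2 == -2) g2 = (s.bnd[grow][0] >= 0 && s.bnd[grow][0] != rem)
                         ? s.bnd[grow][0] : s.bnd[grow][1];
    int r2 = s.other(rnb, rem);       // rnb's inward neighbor in the old state
    // forward trials around `grow`
    std::vector<Vec3> cand(ntr);
    std::vector<double> Ef(ntr);
    double Emin = INF;
    for (int k = 0; k < ntr; k++) {
      cand[k] = sample_growth(grow, g2);
      Ef[k] = grow_ext_energy(rem, cand[k], grow, g2);
      if (Ef[k] < Emin) Emin = Ef[k];
    }
    double Eold = grow_ext_energy(rem, s.X[rem], rnb, r2);
    if (Eold < Emin) Emin = Eold;
    if (Emin == INF) return 0;
    double Wf = 0;
    for (int k = 0; k < ntr; k++) Wf += wexp(Ef[k] - Emin);
    if (Wf <= 0) return 0;
    double r = ru() * Wf, cum = 0;
    int ksel = ntr - 1;
    for (int k = 0; k < ntr; k++) { cum += wexp(Ef[k] - Emin); if (r <= cum) { ksel = k; break; } }
    // reverse trials around the vacated end `rnb`
    double Wr = wexp(Eold - Emin);
    for (int k = 0; k < ntr - 1; k++) {
      Vec3 y = sample_growth(rnb, r2);
      Wr += wexp(grow_ext_energy(rem, y, rnb, r2) - Emin);
    }
    if (Wr <= 0) return 0;
    if (ru() >= (Wf / Wr) * std::exp(extra_logw)) return 0;
    s.del_bond(rem, rnb);
    s.add_bond(rem, grow);
    s.X[rem] = cand[ksel];
    s.move_cell(rem);
    rebuild_topology();
    return 1;
  }

  int mv_reptation() {
    if (headv.empty()) return 2;
    int slot = (int)(ru() * headv.size());
    if (lenv[slot] < 2) return 2;
    int rem, grow;
    if (ru() < 0.5) { rem = headv[slot]; grow = tailv[slot]; }
    else { rem = tailv[slot]; grow = headv[slot]; }
    return transfer_end(rem, grow, sc.ntr[M_REPT], 0.0);
  }

  int mv_xreptation() {
    if (en.mono || headv.size() < 2) return 2;
    int sa = (int)(ru() * headv.size());
    int sb = (int)(ru() * (headv.size() - 1));
    if (sb >= sa) sb++;
    int rem = (ru() < 0.5) ? headv[sa] : tailv[sa];
    int grow = (ru() < 0.5) ? headv[sb] : tailv[sb];
    double extra = en.wl(lenv[sa] - 1) + en.wl(lenv[sb] + 1)
                 - en.wl(lenv[sa]) - en.wl(lenv[sb]);
    if (lenv[sa] - 1 < 2) return 0;
    return transfer_end(rem, grow, sc.ntr[M_XREPT], extra);
  }

  // ---- end-segment regrowth (CCB-like) ------------------------------
  int mv_regrow() {
    if (headv.empty()) return 2;
    int slot = (int)(ru() * headv.size());
    int len = lenv[slot];
    if (len < 2) return 2;
    int kmax = std::min(sc.n_regrow, len - 1);
    int k = 1 + (int)(ru() * kmax);
    bool from_tail = ru() < 0.5;
    // segment sites: seg[0] innermost ... seg[k-1] outermost end
    std::vector<int> seg(k);
    for (int j = 0; j < k; j++) {
      int t = from_tail ? (len - k + 1 + j) : (k - j);
      seg[j] = site_at_pos(slot, t);
    }
    int ntr = sc.ntr[M_REGROW];
    std::vector<char> mask(s.n, 0);
    for (int j = 0; j < k; j++) mask[seg[j]] = 1;
    std::vector<Vec3> oldx(k);
    for (int j = 0; j < k; j++) oldx[j] = s.X[seg[j]];

    // helper: external energy of site `it` at v attached to `a` (inward a2),
    // with not-yet-grown segment sites masked out
    auto ext_E = [&](int it, const Vec3& v, int a, int a2) -> double {
      if (!s.site_ok(v)) return INF;
      double E = 0;
      std::vector<int> bins;
      s.neighbor_bins(v, bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
          if (j == it || j == a || mask[j]) continue;
          if (s.ex13 && j == a2) continue;
          double r2 = s.delta(v, s.X[j]).norm2();
          if (r2 < s.rng2) {
            double u = s.pairU(r2);
            if (u == INF) return INF;
            E += u;
          }
        }
      }
      if (s.ktor > 0 && a2 >= 0) {
        int a3 = s.other(a2, a);
        if (a3 >= 0 && !mask[a3]) E += s.torsion_quad(s.X[a3], s.X[a2], s.X[a], v);
      }
      return E;
    };

    double logWf = 0, logWr = 0;
    bool fail = false;
    // forward pass: grow new positions innermost -> outermost
    for (int j = 0; j < k && !fail; j++) {
      int it = seg[j];
      int a = (j == 0) ? site_at_pos(slot, from_tail ? (len - k) : (k + 1))
                       : seg[j - 1];
      int a2 = s.other(a, it);
      if (a2 == -2) a2 = -1;
      std::vector<Vec3> cand(ntr);
      std::vector<double> Ef(ntr);
      double Emin = INF;
      for (int t = 0; t < ntr; t++) {
        double blen = s.bond_lo + ru() * (s.sigma + s.dl - s.bond_lo);
        Vec3 dir;
        if (a2 >= 0 && !mask[a2]) {
          Vec3 u = s.delta(s.X[a2], s.X[a]);
          u = u * (1.0 / u.norm());
          dir = grow_dir(u, sample_theta_rad(s.kth, s.th0, s.dim), s.dim);
        } else dir = rand_unit(s.dim);
        cand[t] = s.X[a] + dir * blen;
        s.wrap(cand[t]);
        Ef[t] = ext_E(it, cand[t], a, (a2 >= 0 && !mask[a2]) ? a2 : -1);
        if (Ef[t] < Emin) Emin = Ef[t];
      }
      if (Emin == INF) { fail = true; break; }
      double W = 0;
      for (int t = 0; t < ntr; t++) W += wexp(Ef[t] - Emin);
      if (W <= 0) { fail = true; break; }
      double r = ru() * W, cum = 0;
      int tsel = ntr - 1;
      for (int t = 0; t < ntr; t++) { cum += wexp(Ef[t] - Emin); if (r <= cum) { tsel = t; break; } }
      logWf += std::log(W) - (Emin);
      // place
      s.X[it] = cand[tsel];
      s.move_cell(it);
      mask[it] = 0;
    }
    std::vector<Vec3> newx(k);
    if (!fail) for (int j = 0; j < k; j++) newx[j] = s.X[seg[j]];
    // restore to old positions for the reverse pass
    for (int j = 0; j < k; j++) {
      s.X[seg[j]] = oldx[j];
      s.move_cell(seg[j]);
      mask[seg[j]] = 1;
    }
    if (fail) return 0;
    // reverse pass: reconstruct the old segment
    for (int j = 0; j < k; j++) {
      int it = seg[j];
      int a = (j == 0) ? site_at_pos(slot, from_tail ? (len - k) : (k + 1))
                       : seg[j - 1];
      int a2 = s.other(a, it);
      if (a2 == -2) a2 = -1;
      bool have_a2 = (a2 >= 0 && !mask[a2]);
      double Eold = ext_E(it, oldx[j], a, have_a2 ? a2 : -1);
      double Emin = Eold;
      std::vector<double> Er(ntr - 1);
      for (int t = 0; t < ntr - 1; t++) {
        double blen = s.bond_lo + ru() * (s.sigma + s.dl - s.bond_lo);
        Vec3 dir;
        if (have_a2) {
          Vec3 u = s.delta(s.X[a2], s.X[a]);
          u = u * (1.0 / u.norm());
          dir = grow_dir(u, sample_theta_rad(s.kth, s.th0, s.dim), s.dim);
        } else dir = rand_unit(s.dim);
        Vec3 y = s.X[a] + dir * blen;
        s.wrap(y);
        Er[t] = ext_E(it, y, a, have_a2 ? a2 : -1);
        if (Er[t] < Emin) Emin = Er[t];
      }
      if (Emin == INF) return 0;  // old state unreachable: keep old (reject)
      double W = wexp(Eold - Emin);
      for (int t = 0; t < ntr - 1; t++) W += wexp(Er[t] - Emin);
      logWr += std::log(W) - Emin;
      mask[it] = 0;  // old position re-placed (already at oldx)
    }
    if (std::log(ru()) < logWf - logWr) {
      for (int j = 0; j < k; j++) {
        s.X[seg[j]] = newx[j];
        s.move_cell(seg[j]);
      }
      return 1;
    }
    return 0;
  }

  // ---- local bonded+nb energy over an affected set -------------------
  double local_energy_set(std::vector<int>& S2) {
    std::sort(S2.begin(), S2.end());
    S2.erase(std::unique(S2.begin(), S2.end()), S2.end());
    std::vector<char> in(s.n, 0);
    for (size_t k = 0; k < S2.size(); k++) in[S2[k]] = 1;
    double E = 0;
    std::vector<int> bins;
    for (size_t k = 0; k < S2.size(); k++) {
      int i = S2[k];
      s.neighbor_bins(s.X[i], bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
          if (j == i) continue;
          if (in[j] && j < i) continue;  // count in-set pairs once
          if (s.excluded(i, j)) continue;
          double r2 = s.dist2(i, j);
          if (r2 < s.rng2) {
            double u = s.pairU(r2);
            if (u == INF) return INF;
            E += u;
          }
        }
      }
      for (int a = 0; a < 2; a++) {
        int m = s.bnd[i][a];
        if (m < 0) continue;
        if (in[m] && m < i) continue;
        double eb = s.bond_energy(s.dist2(i, m));
        if (eb == INF) return INF;
        E += eb;
        if (s.ktor > 0) E += s.torsion_energy_at_bond(i, m);
      }
      if (s.kth > 0) E += s.bend_energy_at(i);
    }
    return E;
  }

  std::vector<int> with_neighbors(const std::vector<int>& S) {
    std::vector<int> S2 = S;
    for (size_t k = 0; k < S.size(); k++) {
      for (int a = 0; a < 2; a++) {
        int m = s.bnd[S[k]][a];
        if (m >= 0) S2.push_back(m);
      }
    }
    return S2;
  }

  bool bridgeable(int i, int j) {
    double r2 = s.dist2(i, j);
    double lo = s.bond_lo - 1e-9, hi = s.sigma + s.dl + 1e-9;
    return r2 >= lo * lo && r2 <= hi * hi;
  }

  // sites within bridge range of position v (via cell list)
  void bridge_neighbors(const Vec3& v, std::vector<int>& out) {
    out.clear();
    std::vector<int> bins;
    s.neighbor_bins(v, bins);
    double lo = s.bond_lo - 1e-9, hi = s.sigma + s.dl + 1e-9;
    for (size_t b = 0; b < bins.size(); b++) {
      for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
        double r2 = s.delta(v, s.X[j]).norm2();
        if (r2 >= lo * lo && r2 <= hi * hi) out.push_back(j);
      }
    }
  }

  // ---- simplified end-bridging --------------------------------------
  struct Cand3 { int a, b, c; };

  std::vector<Cand3> seb_candidates() {
    std::vector<Cand3> out;
    std::vector<int> nbrs;
    for (size_t slot = 0; slot < headv.size(); slot++) {
      int ends[2] = {headv[slot], tailv[slot]};
      for (int w = 0; w < 2; w++) {
        int e = ends[w];
        if (w == 1 && ends[1] == ends[0]) break;
        bridge_neighbors(s.X[e], nbrs);
        for (size_t q = 0; q < nbrs.size(); q++) {
          int j = nbrs[q];
          if (cid[j] == 0 || cid[j] == cid[e] || s.nbond(j) != 2) continue;
          int slotB = cid[j] - 1;
          int m = lenv[slotB], t = pos[j], la = lenv[slot];
          for (int side = 0; side < 2; side++) {
            int del = s.bnd[j][side];
            int lnew, lrem;
            if (pos[del] == t - 1) { lnew = la + (m - t + 1); lrem = t - 1; }
            else { lnew = la + t; lrem = m - t; }
            if (lrem < en.nmin || lrem > en.nmax) continue;
            if (lnew < en.nmin || lnew > en.nmax) continue;
            Cand3 c; c.a = e; c.b = j; c.c = del;
            out.push_back(c);
          }
        }
      }
    }
    return out;
  }

  int mv_seb() {
    if (en.mono || headv.size() < 2) return 2;
    std::vector<Cand3> cands = seb_candidates();
    if (cands.empty()) return 2;
    int kc = (int)(ru() * cands.size());
    int e = cands[kc].a, j = cands[kc].b, del = cands[kc].c;
    int slotA = cid[e] - 1, slotB = cid[j] - 1;
    int la = lenv[slotA], m = lenv[slotB], t = pos[j];
    int lnew, lrem;
    if (pos[del] == t - 1) { lnew = la + (m - t + 1); lrem = t - 1; }
    else { lnew = la + t; lrem = m - t; }
    double extra = en.wl(lnew) + en.wl(lrem) - en.wl(la) - en.wl(m);
    if (extra == -INF) return 0;
    std::vector<int> S;
    S.push_back(e); S.push_back(j); S.push_back(del);
    std::vector<int> S2 = with_neighbors(S);
    s.del_bond(j, del);
    s.add_bond(e, j);
    std::vector<int> S2b = with_neighbors(S);
    S2.insert(S2.end(), S2b.begin(), S2b.end());
    double Ea = local_energy_set(S2);
    s.del_bond(e, j);
    s.add_bond(j, del);
    double Eb = local_energy_set(S2);
    double nold = cands.size();
    // tentative apply to recount candidates
    s.del_bond(j, del);
    s.add_bond(e, j);
    rebuild_topology();
    double nnew = seb_candidates().size();
    double a = std::exp(-(Ea - Eb) + extra) * (nold / nnew);
    if (Ea == INF || !(ru() < a)) {
      s.del_bond(e, j);
      s.add_bond(j, del);
      rebuild_topology();
      return 0;
    }
    return 1;
  }

  // ---- simplified intramolecular end-bridging ------------------------
  std::vector<Cand3> sieb_candidates() {
    std::vector<Cand3> out;
    std::vector<int> nbrs;
    for (size_t slot = 0; slot < headv.size(); slot++) {
      int len = lenv[slot];
      if (len < 4) continue;
      int ends[2] = {headv[slot], tailv[slot]};
      for (int w = 0; w < 2; w++) {
        int e = ends[w];
        bridge_neighbors(s.X[e], nbrs);
        for (size_t q = 0; q < nbrs.size(); q++) {
          int j = nbrs[q];
          if (cid[j] != (int)slot + 1 || s.nbond(j) != 2) continue;
          int t = pos[j];
          int del = -1;
          if (w == 1 && t <= len - 2) del = site_at_pos(slot, t + 1);
          if (w == 0 && t >= 3) del = site_at_pos(slot, t - 1);
          if (del < 0) continue;
          Cand3 c; c.a = e; c.b = j; c.c = del;
          out.push_back(c);
        }
      }
    }
    return out;
  }

  int mv_sieb() {
    if (headv.empty()) return 2;
    std::vector<Cand3> cands = sieb_candidates();
    if (cands.empty()) return 2;
    int kc = (int)(ru() * cands.size());
    int e = cands[kc].a, j = cands[kc].b, del = cands[kc].c;
    std::vector<int> S;
    S.push_back(e); S.push_back(j); S.push_back(del);
    std::vector<int> S2 = with_neighbors(S);
    s.del_bond(j, del);
    s.add_bond(e, j);
    std::vector<int> S2b = with_neighbors(S);
    S2.insert(S2.end(), S2b.begin(), S2b.end());
    double Ea = local_energy_set(S2);
    s.del_bond(e, j);
    s.add_bond(j, del);
    double Eb = local_energy_set(S2);
    double nold = cands.size();
    s.del_bond(j, del);
    s.add_bond(e, j);
    rebuild_topology();
    double nnew = sieb_candidates().size();
    double a = std::exp(-(Ea - Eb)) * (nold / nnew);
    if (Ea == INF || !(ru() < a)) {
      s.del_bond(e, j);
      s.add_bond(j, del);
      rebuild_topology();
      return 0;
    }
    return 1;
  }

  // ---- simplified double bridging ------------------------------------
  struct Cand4 { int i, j, bi, bj; };  // del (i,bi), (j,bj); add (i,bj'), ...

  std::vector<Cand4> sdb_candidates() {
    // exchange of equal-length tail segments between two chains:
    //   aligned:  del (i,ni), (j,nj); add (i,nj), (j,ni); need pos_i == pos_j
    //   reversed: del (i,ni), (pj,j); add (i,pj), (j,ni); need pos_j == len+1-pos_i
    std::vector<Cand4> out;
    std::vector<int> nbrs;
    for (int i = 0; i < s.n; i++) {
      if (cid[i] == 0) continue;
      int slotA = cid[i] - 1, la = lenv[slotA], pi = pos[i];
      if (pi >= la) continue;
      int ni = -1;
      for (int a = 0; a < 2; a++) {
        int m = s.bnd[i][a];
        if (m >= 0 && pos[m] == pi + 1) ni = m;
      }
      if (ni < 0) continue;
      bridge_neighbors(s.X[ni], nbrs);  // j candidates near ni (new bond j-ni)
      for (size_t q = 0; q < nbrs.size(); q++) {
        int j = nbrs[q];
        if (cid[j] == 0 || cid[j] == cid[i]) continue;
        int slotB = cid[j] - 1, lb = lenv[slotB], pj = pos[j];
        if (lb != la) continue;
        if (pj == pi && pj < lb) {
          int nj = -1;
          for (int a = 0; a < 2; a++) {
            int m = s.bnd[j][a];
            if (m >= 0 && pos[m] == pj + 1) nj = m;
          }
          if (nj >= 0 && bridgeable(i, nj)) {
            Cand4 c; c.i = i; c.j = j; c.bi = ni; c.bj = nj;
            out.push_back(c);
          }
        }
        if (pj == la + 1 - pi && pj >= 2) {
          int pjm = -1;
          for (int a = 0; a < 2; a++) {
            int m = s.bnd[j][a];
            if (m >= 0 && pos[m] == pj - 1) pjm = m;
          }
          if (pjm >= 0 && bridgeable(i, pjm)) {
            Cand4 c; c.i = i; c.j = j; c.bi = ni; c.bj = pjm;
            out.push_back(c);
          }
        }
      }
    }
    return out;
  }

  int mv_sdb() {
    if (headv.size() < 2) return 2;
    std::vector<Cand4> cands = sdb_candidates();
    if (cands.empty()) return 2;
    int kc = (int)(ru() * cands.size());
    int i = cands[kc].i, j = cands[kc].j, bi = cands[kc].bi, bj = cands[kc].bj;
    std::vector<int> S;
    S.push_back(i); S.push_back(j); S.push_back(bi); S.push_back(bj);
    std::vector<int> S2 = with_neighbors(S);
    s.del_bond(i, bi);
    s.del_bond(j, bj);
    s.add_bond(i, bj);
    s.add_bond(j, bi);
    std::vector<int> S2b = with_neighbors(S);
    S2.insert(S2.end(), S2b.begin(), S2b.end());
    double Ea = local_energy_set(S2);
    s.del_bond(i, bj);
    s.del_bond(j, bi);
    s.add_bond(i, bi);
    s.add_bond(j, bj);
    double Eb = local_energy_set(S2);
    double nold = cands.size();
    s.del_bond(i, bi);
    s.del_bond(j, bj);
    s.add_bond(i, bj);
    s.add_bond(j, bi);
    rebuild_topology();
    double nnew = sdb_candidates().size();
    double a = std::exp(-(Ea - Eb)) * (nold / nnew);
    if (Ea == INF || !(ru() < a)) {
      s.del_bond(i, bj);
      s.del_bond(j, bi);
      s.add_bond(i, bi);
      s.add_bond(j, bj);
      rebuild_topology();
      return 0;
    }
    return 1;
  }

  // ---- identity-exchange moves ---------------------------------------
  // candidates: (single monomer, target chain site) pairs
  std::vector<Cand3> idex_candidates(int variant) {
    std::vector<Cand3> out;
    std::vector<int> nbrs;
    for (size_t q = 0; q < singles.size(); q++) {
      int sg = singles[q];
      bridge_neighbors(s.X[sg], nbrs);
      for (size_t w = 0; w < nbrs.size(); w++) {
        int a = nbrs[w];
        if (cid[a] == 0) continue;
        int slot = cid[a] - 1, len = lenv[slot], t = pos[a];
        if (variant == 1 || variant == 3) {
          if (t == 1 || t == len) {  // chain end
            Cand3 c; c.a = sg; c.b = a; c.c = 0;
            out.push_back(c);
          }
        } else {
          if (t == 2 || t == len - 1) {  // second or penultimate
            Cand3 c; c.a = sg; c.b = a; c.c = 0;
            out.push_back(c);
          }
        }
      }
    }
    return out;
  }

  int mv_idex(int variant) {
    if (singles.empty() || headv.empty()) return 2;
    if (variant == 3 && (en.mono || headv.size() < 2)) return 2;
    std::vector<Cand3> cands = idex_candidates(variant);
    if (cands.empty()) return 2;
    int kc = (int)(ru() * cands.size());
    int sg = cands[kc].a, a = cands[kc].b;
    int slot = cid[a] - 1, len = lenv[slot], t = pos[a];
    int rel, relnb;  // released site and its bond partner
    double extra = 0;
    if (variant == 1) {
      rel = (t == 1) ? tailv[slot] : headv[slot];
      relnb = (s.bnd[rel][0] >= 0) ? s.bnd[rel][0] : s.bnd[rel][1];
      if (len == 2 && rel == a) return 0;  // degenerate: absorbing both ends
    } else if (variant == 2) {
      rel = (t == 2) ? headv[slot] : tailv[slot];
      if (t == 2 && t == len - 1 && ru() < 0.5) rel = tailv[slot];  // len 3 tie
      relnb = a;
      if (!s.bonded12(rel, a)) return 0;
    } else {
      int slotD = (int)(ru() * (headv.size() - 1));
      if (slotD >= slot) slotD++;
      rel = (ru() < 0.5) ? headv[slotD] : tailv[slotD];
      relnb = (s.bnd[rel][0] >= 0) ? s.bnd[rel][0] : s.bnd[rel][1];
      int ld = lenv[slotD];
      if (ld - 1 < 2) return 0;
      extra = en.wl(len + 1) + en.wl(ld - 1) - en.wl(len) - en.wl(ld);
      if (extra == -INF) return 0;
    }
    if (variant != 2 && s.nbond(a) != 1) return 0;
    std::vector<int> S;
    S.push_back(sg); S.push_back(a); S.push_back(rel); S.push_back(relnb);
    std::vector<int> S2 = with_neighbors(S);
    // delete before adding: the absorbing site may hold two bonds (IdEx2)
    s.del_bond(rel, relnb);
    s.add_bond(sg, a);
    std::vector<int> S2b = with_neighbors(S);
    S2.insert(S2.end(), S2b.begin(), S2b.end());
    double Ea = local_energy_set(S2);
    s.del_bond(sg, a);
    s.add_bond(rel, relnb);
    double Eb = local_energy_set(S2);
    double nold = cands.size();
    s.del_bond(rel, relnb);
    s.add_bond(sg, a);
    rebuild_topology();
    double nnew = idex_candidates(variant).size();
    double acc_p = std::exp(-(Ea - Eb) + extra) * (nold / nnew);
    if (Ea == INF || !(ru() < acc_p)) {
      s.del_bond(sg, a);
      s.add_bond(rel, relnb);
      rebuild_topology();
      return 0;
    }
    return 1;
  }

  // ---- cluster moves --------------------------------------------------
  // proximity clusters (no label condition) by brute-force union-find
  int proximity_clusters(std::vector<int>& memb) {
    int n = s.n;
    std::vector<int> par(n);
    for (int i = 0; i < n; i++) par[i] = i;
    std::function<int(int)> find = [&](int i) {
      while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
      return i;
    };
    double l2 = sc.linkage * sc.linkage;
    std::vector<int> bins;
    for (int i = 0; i < n; i++) {
      s.neighbor_bins(s.X[i], bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
          if (j <= i) continue;
          if (s.dist2(i, j) <= l2) {
            int a = find(i), c = find(j);
            if (a != c) par[a] = c;
          }
        }
      }
    }
    memb.assign(n, 0);
    std::vector<int> remap(n, -1);
    int nc = 0;
    for (int i = 0; i < n; i++) {
      int r = find(i);
      if (remap[r] < 0) remap[r] = nc++;
      memb[i] = remap[r];
    }
    return nc;
  }

  int mv_cluster(bool rot) {
    if (s.n == 0) return 2;
    if (sc.linkage < s.sigma + s.dl) return 2;  // bonds could cross clusters
    std::vector<int> memb;
    int nc = proximity_clusters(memb);
    if (nc < 2) return 2;  // automatic deactivation with a single cluster
    int pick = (int)(ru() * nc);
    std::vector<int> mem;
    for (int i = 0; i < s.n; i++) if (memb[i] == pick) mem.push_back(i);
    std::vector<char> inmem(s.n, 0);
    for (size_t k = 0; k < mem.size(); k++) inmem[mem[k]] = 1;
    for (size_t k = 0; k < mem.size(); k++) {  // no bond may cross the boundary
      for (int a = 0; a < 2; a++) {
        int m = s.bnd[mem[k]][a];
        if (m >= 0 && !inmem[m]) return 0;
      }
    }
    // unwrap members relative to the first member (min-image chaining)
    std::vector<Vec3> un(mem.size());
    un[0] = s.X[mem[0]];
    Vec3 com = un[0];
    for (size_t k = 1; k < mem.size(); k++) {
      un[k] = un[0] + s.delta(s.X[mem[0]], s.X[mem[k]]);
      com = com + un[k];
    }
    com = com * (1.0 / mem.size());
    std::vector<Vec3> nw(mem.size());
    if (!rot) {
      Vec3 dsp = rand_unit(s.dim) * (ru() * sc.amp_cludis);
      for (size_t k = 0; k < mem.size(); k++) nw[k] = un[k] + dsp;
    } else {
      Vec3 ax = (s.dim == 2) ? Vec3(0, 0, 1) : rand_unit(3);
      double ang = (2 * ru() - 1) * sc.amp_clurot;
      for (size_t k = 0; k < mem.size(); k++) {
        nw[k] = com + rotate_about(un[k] - com, ax, ang);
      }
    }
    for (size_t k = 0; k < mem.size(); k++) s.wrap(nw[k]);
    // energy with non-members, before
    double E1 = 0, E2 = 0;
    double l2 = sc.linkage * sc.linkage;
    std::vector<int> bins;
    for (size_t k = 0; k < mem.size(); k++) {
      s.neighbor_bins(s.X[mem[k]], bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
          if (inmem[j]) continue;
          double r2 = s.delta(s.X[mem[k]], s.X[j]).norm2();
          if (r2 < s.rng2) E1 += s.pairU(r2);
        }
      }
    }
    // after: clearance, overlap, merge rejection
    for (size_t k = 0; k < mem.size(); k++) {
      if (!s.site_ok(nw[k])) return 0;
      s.neighbor_bins(nw[k], bins);
      for (size_t b = 0; b < bins.size(); b++) {
        for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
          if (inmem[j]) continue;
          double r2 = s.delta(nw[k], s.X[j]).norm2();
          if (r2 <= l2) return 0;  // would merge clusters: reject outright
          if (r2 < s.rng2) {
            double u = s.pairU(r2);
            if (u == INF) return 0;
            E2 += u;
          }
        }
      }
    }
    if (!metropolis(E2 - E1)) return 0;
    for (size_t k = 0; k < mem.size(); k++) {
      s.X[mem[k]] = nw[k];
      s.move_cell(mem[k]);
    }
    return 1;
  }

  // ---- volume move ----------------------------------------------------
  int mv_volume() {
    if (en.type != 1) return 2;
    std::vector<int> free;
    for (int d = 0; d < s.dim; d++) if (s.per[d]) free.push_back(d);
    if (free.empty()) return 2;
    double V = s.volume();
    double dV = (2 * ru() - 1) * sc.amp_vol * V;
    double V2 = V + dV;
    if (V2 <= 0) return 0;
    double E1 = s.total_energy();
    std::vector<Vec3> oldX = s.X;
    double oldL[3] = {s.L[0], s.L[1], s.L[2]};
    if (sc.vol_aniso) {
      int d = free[(int)(ru() * free.size())];
      double f = V2 / V;
      s.L[d] *= f;
      for (int i = 0; i < s.n; i++) (&s.X[i].x)[d] *= f;
    } else {
      double f = std::pow(V2 / V, 1.0 / free.size());
      for (size_t q = 0; q < free.size(); q++) {
        int d = free[q];
        s.L[d] *= f;
        for (int i = 0; i < s.n; i++) (&s.X[i].x)[d] *= f;
      }
    }
    s.build_cells();
    double E2 = s.total_energy();
    double lnacc = -en.P * dV + s.n * std::log(V2 / V) - (E2 - E1);
    if (E2 != INF && std::log(ru()) < lnacc) return 1;
    s.X = oldX;
    for (int d = 0; d < 3; d++) s.L[d] = oldL[d];
    s.build_cells();
    return 0;
  }

  int dispatch(int mv) {
    switch (mv) {
      case M_DISP: return mv_displace();
      case M_FLIP: return mv_flip();
      case M_ENDROT: return mv_endrot();
      case M_REPT: return mv_reptation();
      case M_XREPT: return mv_xreptation();
      case M_REGROW: return mv_regrow();
      case M_SEB: return mv_seb();
      case M_SIEB: return mv_sieb();
      case M_SDB: return mv_sdb();
      case M_IDEX1: return mv_idex(1);
      case M_IDEX2: return mv_idex(2);
      case M_IDEX3: return mv_idex(3);
      case M_CLUDIS: return mv_cluster(false);
      case M_CLUROT: return mv_cluster(true);
      default: return mv_volume();
    }
  }
};

// [[Rcpp::export]]
List cpp_run_mc(List p, List scl, List enl, int n_steps, int sample_every,
                bool debug) {
  Driver d(p, scl, enl, debug);
  double cum[N_MOVES];
  double tot = 0;
  for (int k = 0; k < N_MOVES; k++) { tot += d.sc.probs[k]; cum[k] = tot; }
  std::vector<double> s_step, s_phi, s_energy;
  for (long step = 0; step < n_steps; step++) {
    double r = ru() * tot;
    int mv = 0;
    while (mv < N_MOVES - 1 && r > cum[mv]) mv++;
    d.att[mv]++;
    int res = d.dispatch(mv);
    if (res == 1) {
      d.acc[mv]++;
      if (debug && d.s.any_overlap()) {
        stop("invariant violated after accepted move %d", mv);
      }
    } else if (res == 2) d.skp[mv]++;
    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      s_step.push_back(step + 1);
      s_phi.push_back(d.s.phi());
      s_energy.push_back(d.s.total_energy());
    }
    if ((step & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List st = d.s.to_state();
  st["attempts"] = NumericVector(d.att, d.att + N_MOVES);
  st["accepts"] = NumericVector(d.acc, d.acc + N_MOVES);
  st["skips"] = NumericVector(d.skp, d.skp + N_MOVES);
  st["s_step"] = s_step;
  st["s_phi"] = s_phi;
  st["s_energy"] = s_energy;
  return st;
}

// [[Rcpp::export]]
List cpp_compress(List p, int sweeps_per_block, double shrink0,
                  double shrink_min, double decay, double tol, int window,
                  int max_blocks, double amp0, double phi_stop) {
  Sys s = make_sys(p);
  if (s.any_overlap()) stop("initial configuration has overlaps");
  std::vector<int> free;
  for (int d = 0; d < s.dim; d++) if (s.per[d]) free.push_back(d);
  if (free.empty()) stop("no unconfined dimension to compress");
  double amp = amp0, shrink = shrink0;
  std::vector<double> s_block, s_phi, s_acc;
  std::vector<double> dv_hist;
  bool converged = false;
  int n = s.n;
  for (int blk = 0; blk < max_blocks && !converged; blk++) {
    long a = 0, t = 0;
    for (int sw = 0; sw < sweeps_per_block; sw++) {
      for (int m = 0; m < n; m++) {
        int i = (int)(ru() * n);
        Vec3 v = s.X[i];
        double* c = &v.x;
        for (int d = 0; d < s.dim; d++) c[d] += (2 * ru() - 1) * amp;
        s.wrap(v);
        double e0 = s.site_local_energy(i, s.X[i]);
        double e1 = s.site_local_energy(i, v);
        t++;
        double dE = e1 - e0;
        if (e1 != INF && (dE <= 0 || ru() < std::exp(-dE))) {
          s.X[i] = v;
          s.move_cell(i);
          a++;
        }
      }
    }
    double fr = (double)a / t;
    if (fr > 0.45) amp = std::min(amp * 1.1, 2.0);
    else if (fr < 0.35) amp = std::max(amp * 0.9, 1e-6);
    // shrink attempts: contract towards the tightest pair contact
    double V0 = s.volume();
    for (int trial = 0; trial < 4; trial++) {
      // smallest admissible isotropic linear factor from current contacts
      double f0 = 0;
      {
        std::vector<int> bins;
        for (int i = 0; i < n; i++) {
          s.neighbor_bins(s.X[i], bins);
          for (size_t b = 0; b < bins.size(); b++) {
            for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
              if (j <= i) continue;
              double r = std::sqrt(s.dist2(i, j));
              double req = s.bonded12(i, j) ? s.bond_lo / r : s.sigma / r;
              if (req > f0) f0 = req;
            }
          }
        }
      }
      for (size_t q = 0; q < free.size(); q++) {
        // self-image contact: the cell cannot shrink below sigma
        double req = s.sigma / s.L[free[q]];
        if (req > f0) f0 = req;
      }
      double f = std::pow(1 - shrink, 1.0 / free.size());
      if (f0 * (1 + 1e-9) > f) f = f0 * (1 + 1e-9);
      if (f >= 1 - 1e-15) continue;  // no room: a pair is exactly at contact
      std::vector<Vec3> oldX = s.X;
      double oldL[3] = {s.L[0], s.L[1], s.L[2]};
      for (size_t q = 0; q < free.size(); q++) {
        int d = free[q];
        s.L[d] *= f;
        for (int i = 0; i < n; i++) (&s.X[i].x)[d] *= f;
      }
      s.build_cells();
      if (s.any_overlap()) {  // missed pair outside the stencil, or fillers
        s.X = oldX;
        for (int d = 0; d < 3; d++) s.L[d] = oldL[d];
        s.build_cells();
        shrink = std::max(shrink * decay, shrink_min);
      } else {
        shrink = std::min(shrink / decay, shrink0);
      }
    }
    double V1 = s.volume();
    double rel = (V0 - V1) / V0;
    dv_hist.push_back(rel);
    s_block.push_back(blk + 1);
    s_phi.push_back(s.phi());
    s_acc.push_back(fr);
    if ((int)dv_hist.size() >= window) {
      double m = 0;
      for (int k = 0; k < window; k++) m += dv_hist[dv_hist.size() - 1 - k];
      m /= window;
      if (m < tol) converged = true;
    }
    if (phi_stop < 1 && s.phi() >= phi_stop) {
      // expand affinely back to the exact target density (always valid)
      double fx = std::pow(s.phi() / phi_stop, 1.0 / free.size());
      for (size_t q = 0; q < free.size(); q++) {
        int d = free[q];
        s.L[d] *= fx;
        for (int i = 0; i < n; i++) (&s.X[i].x)[d] *= fx;
      }
      s.build_cells();
      converged = true;
    }
    Rcpp::checkUserInterrupt();
  }
  List st = s.to_state();
  st["converged"] = converged;
  st["s_block"] = s_block;
  st["s_phi"] = s_phi;
  st["s_acc"] = s_acc;
  return st;
}

// [[Rcpp::export]]
List cpp_generate_dilute(List p, IntegerVector chain_lens, int n_s,
                         int max_retry) {
  Sys s;
  s.from_packed(p);
  int ntot = 0;
  for (int k = 0; k < chain_lens.size(); k++) ntot += chain_lens[k];
  ntot += n_s;
  s.n = ntot;
  s.X.assign(ntot, Vec3());
  std::array<int, 2> none = {{-1, -1}};
  s.bnd.assign(ntot, none);
  int at = 0;
  for (int k = 0; k < chain_lens.size(); k++) {
    for (int m = 1; m < chain_lens[k]; m++) s.add_bond(at + m - 1, at + m);
    at += chain_lens[k];
  }
  s.build_cells();
  // empty the cell list; sites are inserted as they are placed
  std::fill(s.head.begin(), s.head.end(), -1);
  std::fill(s.binof.begin(), s.binof.end(), -1);

  double h = s.sigma / 2;
  auto rand_pos = [&]() {
    Vec3 v;
    double* c = &v.x;
    for (int it = 0; it < 10000; it++) {
      for (int d = 0; d < s.dim; d++) {
        double lo = s.per[d] ? 0 : h, hi = s.per[d] ? s.L[d] : s.L[d] - h;
        c[d] = lo + ru() * (hi - lo);
      }
      if (s.dim == 2) v.z = 0;
      if (s.site_ok(v)) return v;
    }
    return Vec3(-1e9, 0, 0);
  };
  auto clash = [&](const Vec3& v, int excl) {
    std::vector<int> bins;
    s.neighbor_bins(v, bins);
    for (size_t b = 0; b < bins.size(); b++) {
      for (int j = s.head[bins[b]]; j >= 0; j = s.nextp[j]) {
        if (j == excl) continue;
        if (s.delta(v, s.X[j]).norm2() < s.s2core) return true;
      }
    }
    return false;
  };

  bool ok = true;
  at = 0;
  for (int k = 0; k < chain_lens.size() && ok; k++) {
    int len = chain_lens[k];
    int restarts = 0;
    while (restarts < 100) {
      int placed = 0;
      bool fail = false;
      for (int m = 0; m < len && !fail; m++) {
        int i = at + m;
        bool done = false;
        for (int tr = 0; tr < max_retry; tr++) {
          Vec3 v;
          if (m == 0) {
            v = rand_pos();
            if (v.x < -1e8) { fail = true; break; }
          } else {
            int a = i - 1;
            double blen = s.bond_lo + ru() * (s.sigma + s.dl - s.bond_lo);
            Vec3 dir;
            if (m >= 2) {
              Vec3 u = s.delta(s.X[a - 1], s.X[a]);
              u = u * (1.0 / u.norm());
              dir = grow_dir(u, sample_theta_rad(s.kth, s.th0, s.dim), s.dim);
            } else dir = rand_unit(s.dim);
            v = s.X[a] + dir * blen;
            s.wrap(v);
            if (!s.site_ok(v)) continue;
          }
          if (!clash(v, (m > 0) ? i - 1 : -1)) {
            s.X[i] = v;
            s.insert_cell(i);
            placed++;
            done = true;
            break;
          }
        }
        if (!done) fail = true;
      }
      if (!fail) break;
      for (int m = 0; m < placed; m++) s.remove_cell(at + m);
      restarts++;
      if (restarts >= 100) ok = false;
    }
    at += len;
  }
  for (int q = 0; q < n_s && ok; q++) {
    int i = at + q;
    bool done = false;
    for (int tr = 0; tr < max_retry; tr++) {
      Vec3 v = rand_pos();
      if (v.x < -1e8) break;
      if (!clash(v, -1)) {
        s.X[i] = v;
        s.insert_cell(i);
        done = true;
        break;
      }
    }
    if (!done) ok = false;
  }
  NumericMatrix co(ntot, 3);
  for (int i = 0; i < ntot; i++) {
    co(i, 0) = s.X[i].x; co(i, 1) = s.X[i].y; co(i, 2) = s.X[i].z;
  }
  return List::create(Named("coords") = co, Named("ok") = ok);
}
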