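// Voronoi neighbors by half-space cell construction: for each site the
// bisector planes of nearby candidate images (plus wall/bounding planes)
// define a convex cell; candidates whose plane carries a face of
// non-negligible area are the Voronoi neighbors.  Exactly degenerate
// (co-spherical) inputs are broken by a deterministic 1e-9 jitter.
#include "polymc_core.h"
using namespace Rcpp;

struct Plane {
  Vec3 n;      // unit outward normal
  double h;    // x . n <= h
  int cand;    // candidate index, -1 for wall/bounding planes
  int kind;    // 0 candidate, 1 real wall, 2 bounding box, 3 out-of-plane slab
};

struct Cand {
  Vec3 d;      // displacement from the site (specific periodic image)
  double dist;
  int j;       // site index
};

// deterministic per-coordinate jitter in [-0.5, 0.5]
static double djit(int i, int d) {
  double v = std::sin(i * 12.9898 + d * 78.233 + 0.5) * 43758.5453;
  return v - std::floor(v) - 0.5;
}

static bool solve3(const Plane& a, const Plane& b, const Plane& c, Vec3& v) {
  double m[9] = {a.n.x, a.n.y, a.n.z, b.n.x, b.n.y, b.n.z, c.n.x, c.n.y, c.n.z};
  double det = m[0] * (m[4] * m[8] - m[5] * m[7])
             - m[1] * (m[3] * m[8] - m[5] * m[6])
             + m[2] * (m[3] * m[7] - m[4] * m[6]);
  if (std::fabs(det) < 1e-10) return false;
  double r[3] = {a.h, b.h, c.h};
  double inv[9];
  inv[0] = (m[4] * m[8] - m[5] * m[7]) / det;
  inv[1] = (m[2] * m[7] - m[1] * m[8]) / det;
  inv[2] = (m[1] * m[5] - m[2] * m[4]) / det;
  inv[3] = (m[5] * m[6] - m[3] * m[8]) / det;
  inv[4] = (m[0] * m[8] - m[2] * m[6]) / det;
  inv[5] = (m[2] * m[3] - m[0] * m[5]) / det;
  inv[6] = (m[3] * m[7] - m[4] * m[6]) / det;
  inv[7] = (m[1] * m[6] - m[0] * m[7]) / det;
  inv[8] = (m[0] * m[4] - m[1] * m[3]) / det;
  v = Vec3(inv[0] * r[0] + inv[1] * r[1] + inv[2] * r[2],
           inv[3] * r[0] + inv[4] * r[1] + inv[5] * r[2],
           inv[6] * r[0] + inv[7] * r[1] + inv[8] * r[2]);
  return true;
}

// [[Rcpp::export]]
List cpp_voronoi(List p, IntegerVector sites) {
  Sys s;
  s.from_packed(p);
  int n = s.n;
  if (n < 2) stop("Voronoi tessellation needs at least 2 sites");
  // deterministic jitter to break co-spherical degeneracies
  std::vector<Vec3> X(n);
  for (int i = 0; i < n; i++) {
    X[i] = s.X[i] + Vec3(djit(i, 0), djit(i, 1), (s.dim == 3) ? djit(i, 2) : 0) * 1e-9;
  }
  int ns = sites.size();
  List out_nb(ns), out_disp(ns), out_dists(ns);
  IntegerVector out_nvor(ns), out_nfaces(ns);
  NumericVector out_vol(ns);

  int off_lo[3], off_hi[3];
  for (int d = 0; d < 3; d++) {
    off_lo[d] = (d < s.dim && s.per[d]) ? -1 : 0;
    off_hi[d] = (d < s.dim && s.per[d]) ? 1 : 0;
  }

  for (int q = 0; q < ns; q++) {
    int i = sites[q];
    if (i < 0 || i >= n) stop("site index out of range");
    // ---- gather candidate images, sorted by distance ----
    std::vector<Cand> all;
    all.reserve(27 * n / 8);
    for (int j = 0; j < n; j++) {
      for (int ox = off_lo[0]; ox <= off_hi[0]; ox++) {
        for (int oy = off_lo[1]; oy <= off_hi[1]; oy++) {
          for (int oz = off_lo[2]; oz <= off_hi[2]; oz++) {
            if (j == i && ox == 0 && oy == 0 && oz == 0) continue;
            Cand c;
            c.d = Vec3(X[j].x + ox * s.L[0] - X[i].x,
                       X[j].y + oy * s.L[1] - X[i].y,
                       X[j].z + oz * s.L[2] - X[i].z);
            c.dist = c.d.norm();
            c.j = j;
            all.push_back(c);
          }
        }
      }
    }
    std::sort(all.begin(), all.end(),
              [](const Cand& a, const Cand& b) { return a.dist < b.dist; });

    int K = std::min((size_t)40, all.size());
    std::vector<int> nb_faces;
    std::vector<double> face_area, face_h;
    double volume = 0;
    int n_wall_faces = 0;
    bool ok = false;

    while (!ok) {
      nb_faces.clear(); face_area.clear(); face_h.clear();
      volume = 0;
      n_wall_faces = 0;
      double hfar = all[K - 1].dist / 2;
      double scale = hfar;
      double tol = 1e-10 * scale;
      std::vector<Plane> P;
      for (int k = 0; k < K; k++) {
        Plane pl;
        pl.n = all[k].d * (1.0 / all[k].dist);
        pl.h = all[k].dist / 2;
        pl.cand = k;
        pl.kind = 0;
        P.push_back(pl);
      }
      // wall / bounding / slab planes
      for (int d = 0; d < 3; d++) {
        int kind = (d < s.dim) ? 2 : 3;
        double hup = hfar * 1.5, hdn = hfar * 1.5;
        if (d < s.dim && !s.per[d]) {
          if (s.conf == CONF_WALLS ||
              (s.conf == CONF_CYL && d == s.caxis)) {
            kind = 1;
            const double* c = &X[i].x;
            hup = s.L[d] - c[d];
            hdn = c[d];
          }
        }
        Plane up; up.n = Vec3(d == 0, d == 1, d == 2); up.h = hup;
        up.cand = -1; up.kind = kind;
        Plane dn; dn.n = Vec3(-(d == 0), -(d == 1), -(d == 2)); dn.h = hdn;
        dn.cand = -1; dn.kind = kind;
        P.push_back(up); P.push_back(dn);
      }
      if (s.conf == CONF_CYL || s.conf == CONF_SPH) {
        // tangent plane at the nearest point of the curved boundary
        Vec3 r(0, 0, 0);
        double* rc = &r.x;
        const double* c = &X[i].x;
        for (int d = 0; d < s.dim; d++) {
          if (s.conf == CONF_CYL && d == s.caxis) continue;
          rc[d] = c[d] - s.L[d] / 2;
        }
        double rn = r.norm();
        int t = (s.conf == CONF_CYL) ? ((s.caxis == 0) ? 1 : 0) : 0;
        double R = s.L[t] / 2;
        Plane w;
        w.n = (rn > 1e-9) ? r * (1.0 / rn) : Vec3(1, 0, 0);
        w.h = R - rn;
        w.cand = -1; w.kind = 1;
        P.push_back(w);
      }
      int np = P.size();
      // ---- vertices: feasible intersections of plane triples ----
      std::vector<Vec3> verts;
      std::vector<char> vert_on_bound;
      double maxv = 0;
      for (int a = 0; a < np; a++) {
        for (int b = a + 1; b < np; b++) {
          for (int c = b + 1; c < np; c++) {
            Vec3 v;
            if (!solve3(P[a], P[b], P[c], v)) continue;
            if (v.norm() > 4 * hfar) continue;
            bool feas = true;
            for (int u = 0; u < np; u++) {
              if (v.dot(P[u].n) > P[u].h + tol) { feas = false; break; }
            }
            if (!feas) continue;
            verts.push_back(v);
            bool onb = P[a].kind == 2 || P[b].kind == 2 || P[c].kind == 2;
            vert_on_bound.push_back(onb);
            if (v.norm() > maxv) maxv = v.norm();
          }
        }
      }
      // ---- adequacy: excluded candidates must not be able to cut ----
      bool truncated_by_bound = false;
      for (size_t w = 0; w < verts.size(); w++) {
        if (vert_on_bound[w]) truncated_by_bound = true;
      }
      // cap the candidate set: cells still open beyond the cap (vacuum
      // interfaces) are truncated by the bounding box and their box faces
      // are not counted as neighbors
      if ((size_t)K < all.size() && K < 160 &&
          (truncated_by_bound || 2 * maxv > all[K].dist)) {
        K = std::min(all.size(), (size_t)(2 * K));
        continue;  // rebuild with more candidates
      }
      // ---- faces ----
      double ton = 1e-8 * scale;
      for (int a = 0; a < np; a++) {
        std::vector<Vec3> fv;
        for (size_t w = 0; w < verts.size(); w++) {
          if (std::fabs(verts[w].dot(P[a].n) - P[a].h) <= ton) fv.push_back(verts[w]);
        }
        // deduplicate
        std::vector<Vec3> uq;
        for (size_t w = 0; w < fv.size(); w++) {
          bool dup = false;
          for (size_t u = 0; u < uq.size(); u++) {
            if ((fv[w] - uq[u]).norm2() < 1e-14 * scale * scale) { dup = true; break; }
          }
          if (!dup) uq.push_back(fv[w]);
        }
        if (uq.size() < 3) continue;
        // polygon area on the plane
        Vec3 ctr(0, 0, 0);
        for (size_t u = 0; u < uq.size(); u++) ctr = ctr + uq[u];
        ctr = ctr * (1.0 / uq.size());
        Vec3 ref = (std::fabs(P[a].n.x) < 0.9) ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
        Vec3 t1 = P[a].n.cross(ref);
        t1 = t1 * (1.0 / t1.norm());
        Vec3 t2 = P[a].n.cross(t1);
        std::vector<std::pair<double, int> > ang(uq.size());
        for (size_t u = 0; u < uq.size(); u++) {
          Vec3 rr = uq[u] - ctr;
          ang[u] = std::make_pair(std::atan2(rr.dot(t2), rr.dot(t1)), (int)u);
        }
        std::sort(ang.begin(), ang.end());
        double area = 0;
        for (size_t u = 0; u < uq.size(); u++) {
          const Vec3& v1 = uq[ang[u].second] - ctr;
          const Vec3& v2 = uq[ang[(u + 1) % uq.size()].second] - ctr;
          area += 0.5 * v1.cross(v2).norm();
        }
        if (area <= 1e-5 * scale * scale) continue;
        volume += P[a].h * area / 3.0;
        if (P[a].cand >= 0) {
          nb_faces.push_back(P[a].cand);
          face_area.push_back(area);
          face_h.push_back(P[a].h);
        } else if (P[a].kind == 1) n_wall_faces++;
      }
      ok = true;
    }
    std::sort(nb_faces.begin(), nb_faces.end());  // by distance (cand order)
    int nv = nb_faces.size();
    IntegerVector nbv(nv);
    NumericVector dsv(nv);
    NumericMatrix dpv(nv, 3);
    for (int k = 0; k < nv; k++) {
      const Cand& c = all[nb_faces[k]];
      nbv[k] = c.j;
      dsv[k] = c.dist;
      dpv(k, 0) = c.d.x; dpv(k, 1) = c.d.y; dpv(k, 2) = c.d.z;
    }
    out_nb[q] = nbv;
    out_disp[q] = dpv;
    out_dists[q] = dsv;
    out_nvor[q] = nv;
    out_nfaces[q] = nv + n_wall_faces;
    out_vol[q] = volume;
    if (s.dim == 2) {
      // the slab construction yields area * slab height; recover the cell
      // area from the neighbor faces (edge length = face area / height)
      double hz = 2 * (1.5 * all[K - 1].dist / 2);
      double area2 = 0;
      for (size_t k = 0; k < face_area.size(); k++) {
        area2 += 0.5 * face_h[k] * (face_area[k] / hz);
      }
      out_vol[q] = area2;
    }
    if ((q & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("neighbors") = out_nb, Named("disp") = out_disp,
                      Named("dists") = out_dists, Named("n_vor") = out_nvor,
                      Named("n_faces") = out_nfaces, Named("volume") = out_vol);
}
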