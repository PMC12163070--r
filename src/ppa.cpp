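// Geometric primitive-path contraction: with chain ends held fixed, each
// interior node is pulled toward the chord between its neighbours; a move
// is accepted only if the swept triangles intersect no segment of any
// other chain, so topological uncrossability is preserved. Nearly
// collinear nodes are removed. Deterministic: chains are processed in
// index order, nodes in rank order.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct V3 {
  double x, y, z;
};
static inline V3 sub(const V3& a, const V3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 add(const V3& a, const V3& b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline V3 scl(const V3& a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 crs(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double nrm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Seg {
  V3 a, b;
};

// squared distance between two segments (for conservative coplanar cases)
static double seg_seg_d2(const V3& p1, const V3& q1, const V3& p2,
                         const V3& q2) {
  V3 d1 = sub(q1, p1), d2 = sub(q2, p2), r = sub(p1, p2);
  double A = dot(d1, d1), E = dot(d2, d2), F = dot(d2, r);
  double s = 0, t = 0;
  const double EPS = 1e-30;
  if (A <= EPS && E <= EPS) {
  } else if (A <= EPS) {
    t = std::min(1.0, std::max(0.0, F / E));
  } else {
    double C = dot(d1, r);
    if (E <= EPS) {
      s = std::min(1.0, std::max(0.0, -C / A));
    } else {
      double B = dot(d1, d2), den = A * E - B * B;
      if (den > EPS) s = std::min(1.0, std::max(0.0, (B * F - C * E) / den));
      t = (B * s + F) / E;
      if (t < 0) {
        t = 0;
        s = std::min(1.0, std::max(0.0, -C / A));
      } else if (t > 1) {
        t = 1;
        s = std::min(1.0, std::max(0.0, (B - C) / A));
      }
    }
  }
  V3 c1 = add(p1, scl(d1, s)), c2 = add(p2, scl(d2, t));
  V3 dd = sub(c1, c2);
  return dot(dd, dd);
}

// does segment (s0,s1) cross triangle (v0,v1,v2)?
static bool tri_seg_hit(const V3& v0, const V3& v1, const V3& v2,
                        const V3& s0, const V3& s1) {
  V3 e1 = sub(v1, v0), e2 = sub(v2, v0);
  V3 nn = crs(e1, e2);
  double area2 = nrm(nn);
  if (area2 < 1e-24) return false;  // degenerate sliver: no swept area
  V3 dir = sub(s1, s0);
  double den = dot(nn, dir);
  if (std::fabs(den) < 1e-12 * area2) {
    // segment nearly parallel to the triangle plane: block only if it
    // comes essentially into contact with the triangle edges/interior
    double h = dot(nn, sub(s0, v0)) / area2;
    if (std::fabs(h) > 1e-7) return false;
    double d2a = seg_seg_d2(s0, s1, v0, v1);
    double d2b = seg_seg_d2(s0, s1, v1, v2);
    double d2c = seg_seg_d2(s0, s1, v2, v0);
    return std::min(d2a, std::min(d2b, d2c)) < 1e-12;
  }
  double t = dot(nn, sub(v0, s0)) / den;
  if (t < -1e-6 || t > 1.0 + 1e-6) return false;
  V3 p = add(s0, scl(dir, t));
  // barycentric inside test, deliberately conservative: a segment that
  // merely grazes the swept triangle's boundary counts as a hit, so
  // uncrossability can never be lost to roundoff
  V3 w = sub(p, v0);
  double d00 = dot(e1, e1), d01 = dot(e1, e2), d11 = dot(e2, e2);
  double d20 = dot(w, e1), d21 = dot(w, e2);
  double den2 = d00 * d11 - d01 * d01;
  if (den2 <= 0) return false;
  double v = (d11 * d20 - d01 * d21) / den2;
  double u = (d00 * d21 - d01 * d20) / den2;
  return v >= -1e-6 && u >= -1e-6 && v + u <= 1.0 + 1e-6;
}

// swept-triangle tests are unreliable for slivers much thinner than the
// pivot standoff (barycentric cancellation amplified by the squared
// long-edge/thin-edge ratio), so a direct proximity guard backs them up:
// a move whose displacement or new segments pass within EPS_GUARD of an
// obstacle is blocked outright.
static const double EPS_GUARD2 = 3e-6 * 3e-6;

static bool sweep_blocked(const V3& A, const V3& B, const V3& P, const V3& Pn,
                          const std::vector<Seg>& obs) {
  for (size_t k = 0; k < obs.size(); ++k) {
    if (tri_seg_hit(A, P, Pn, obs[k].a, obs[k].b)) return true;
    if (tri_seg_hit(B, P, Pn, obs[k].a, obs[k].b)) return true;
    if (seg_seg_d2(P, Pn, obs[k].a, obs[k].b) < EPS_GUARD2) return true;
    if (seg_seg_d2(A, Pn, obs[k].a, obs[k].b) < EPS_GUARD2) return true;
    if (seg_seg_d2(B, Pn, obs[k].a, obs[k].b) < EPS_GUARD2) return true;
  }
  return false;
}

static double path_len(const std::vector<V3>& p) {
  double L = 0;
  for (size_t i = 0; i + 1 < p.size(); ++i) L += nrm(sub(p[i + 1], p[i]));
  return L;
}

// interior angle deviation from straight (radians) at node k
static double kink_angle(const std::vector<V3>& p, size_t k) {
  V3 u = sub(p[k], p[k - 1]), v = sub(p[k + 1], p[k]);
  double ru = nrm(u), rv = nrm(v);
  if (ru < 1e-14 || rv < 1e-14) return 0.0;
  double c = dot(u, v) / (ru * rv);
  c = std::min(1.0, std::max(-1.0, c));
  return std::acos(c);
}

// Collect obstacle segments of all chains except `self`, replicated over
// periodic images whose bounding box comes within `shell` of the bounding
// box of the contracting chain.
static void gather_obstacles(const std::vector<std::vector<V3> >& paths,
                             size_t self, double box, bool periodic,
                             double shell, std::vector<Seg>& obs) {
  obs.clear();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (size_t i = 0; i < paths[self].size(); ++i) {
    const V3& p = paths[self][i];
    double c[3] = {p.x, p.y, p.z};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], c[d]);
      hi[d] = std::max(hi[d], c[d]);
    }
  }
  for (int d = 0; d < 3; ++d) {
    lo[d] -= shell;
    hi[d] += shell;
  }
  for (size_t c = 0; c < paths.size(); ++c) {
    if (c == self) continue;
    const std::vector<V3>& q = paths[c];
    for (size_t i = 0; i + 1 < q.size(); ++i) {
      double smin[3] = {std::min(q[i].x, q[i + 1].x),
                        std::min(q[i].y, q[i + 1].y),
                        std::min(q[i].z, q[i + 1].z)};
      double smax[3] = {std::max(q[i].x, q[i + 1].x),
                        std::max(q[i].y, q[i + 1].y),
                        std::max(q[i].z, q[i + 1].z)};
      if (!periodic) {
        bool ok = true;
        for (int d = 0; d < 3; ++d)
          if (smax[d] < lo[d] || smin[d] > hi[d]) ok = false;
        if (ok) obs.push_back({q[i], q[i + 1]});
        continue;
      }
      int n0[3], n1[3];
      for (int d = 0; d < 3; ++d) {
        n0[d] = (int)std::ceil((lo[d] - smax[d]) / box);
        n1[d] = (int)std::floor((hi[d] - smin[d]) / box);
      }
      for (int ax = n0[0]; ax <= n1[0]; ++ax)
        for (int ay = n0[1]; ay <= n1[1]; ++ay)
          for (int az = n0[2]; az <= n1[2]; ++az) {
            V3 sh = {ax * box, ay * box, az * box};
            obs.push_back({add(q[i], sh), add(q[i + 1], sh)});
          }
    }
  }
}

// [[Rcpp::export]]
List cpp_ppa_contract(NumericMatrix posU, IntegerVector chain, double box,
                      bool periodic, bool fixed_obstacles, double kink_thresh,
                      double tol, int max_sweeps, double shell) {
  int n = posU.nrow();
  std::vector<std::vector<V3> > paths;
  std::vector<int> chain_ids;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || chain[i] != chain[i - 1]) {
      paths.push_back(std::vector<V3>());
      chain_ids.push_back(chain[i]);
    }
    paths.back().push_back({posU(i, 0), posU(i, 1), posU(i, 2)});
  }
  size_t nch = paths.size();
  std::vector<std::vector<V3> > ref = paths;  // obstacles in fixed mode

  std::vector<double> trace;
  trace.push_back(0);
  {
    double L0 = 0;
    for (size_t c = 0; c < nch; ++c) L0 += path_len(paths[c]);
    trace[0] = L0;
  }
  bool converged = false;
  int sweep;
  std::vector<Seg> obs;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double before = trace.back();
    bool removed_any = false;
    for (size_t c = 0; c < nch; ++c) {
      if (paths[c].size() < 3) continue;
      gather_obstacles(fixed_obstacles ? ref : paths, c, box, periodic, shell,
                       obs);
      std::vector<V3>& p = paths[c];
      // shortening moves
      for (size_t k = 1; k + 1 < p.size(); ++k) {
        const V3 A = p[k - 1];
        const V3 B = p[k + 1];
        V3 P = p[k];
        // closest point to P on chord AB
        V3 ab = sub(B, A);
        double ab2 = dot(ab, ab);
        double tt = ab2 > 1e-28 ? dot(sub(P, A), ab) / ab2 : 0.5;
        tt = std::min(1.0, std::max(0.0, tt));
        V3 T = add(A, scl(ab, tt));
        V3 dPT = sub(T, P);
        if (dot(dPT, dPT) < 1e-28) continue;
        double lam = 1.0;
        bool moved = false;
        for (int half = 0; half < 45; ++half) {
          V3 Pn = add(P, scl(dPT, lam));
          if (!sweep_blocked(A, B, P, Pn, obs)) {
            p[k] = Pn;
            moved = true;
            break;
          }
          lam *= 0.5;
        }
        if (!moved || lam < 1e-3) {
          // pinned (or creeping): the taut path passes over an obstacle
          // segment. Slide the node to the point on the blocking segment
          // that minimises |A-q| + |q-B| (the taut-string pivot), offset
          // 1e-5 sigma towards the old node (a standoff large enough that
          // the sliver intersection tests stay numerically reliable).
          P = p[k];
          double lam_probe = moved ? std::min(1.0, lam * 2) : 1e-6;
          V3 probe = add(P, scl(dPT, lam_probe));
          long blk = -1;
          for (size_t q = 0; q < obs.size(); ++q) {
            if (tri_seg_hit(A, P, probe, obs[q].a, obs[q].b) ||
                tri_seg_hit(B, P, probe, obs[q].a, obs[q].b)) {
              blk = (long)q;
              break;
            }
          }
          if (blk >= 0) {
            const V3 S0 = obs[blk].a, S1 = obs[blk].b;
            auto flen = [&](double u) {
              V3 q = add(S0, scl(sub(S1, S0), u));
              return nrm(sub(A, q)) + nrm(sub(q, B));
            };
            double lo = 0.0, hi = 1.0;
            const double gr = 0.6180339887498949;
            double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
            double f1 = flen(x1), f2 = flen(x2);
            for (int it = 0; it < 80; ++it) {
              if (f1 < f2) {
                hi = x2; x2 = x1; f2 = f1;
                x1 = hi - gr * (hi - lo); f1 = flen(x1);
              } else {
                lo = x1; x1 = x2; f1 = f2;
                x2 = lo + gr * (hi - lo); f2 = flen(x2);
              }
            }
            double ustar = (lo + hi) / 2;
            V3 qs = add(S0, scl(sub(S1, S0), ustar));
            V3 back = sub(P, qs);
            double nb = nrm(back);
            if (nb > 1e-12) {
              V3 Pn = add(qs, scl(back, 1e-5 / nb));
              double oldlen = nrm(sub(A, P)) + nrm(sub(P, B));
              double newlen = nrm(sub(A, Pn)) + nrm(sub(Pn, B));
              if (newlen < oldlen - 1e-15) {
                bool ok = true;
                for (size_t q = 0; q < obs.size() && ok; ++q) {
                  if ((long)q == blk) continue;
                  if (tri_seg_hit(A, P, Pn, obs[q].a, obs[q].b) ||
                      tri_seg_hit(B, P, Pn, obs[q].a, obs[q].b))
                    ok = false;
                }
                if (ok) p[k] = Pn;
              }
            }
          }
        }
      }
      // remove nearly collinear interior nodes (sliver sweep must be free)
      for (size_t k = 1; k + 1 < p.size();) {
        if (kink_angle(p, k) < kink_thresh) {
          bool blocked = false;
          for (size_t q = 0; q < obs.size() && !blocked; ++q)
            if (tri_seg_hit(p[k - 1], p[k], p[k + 1], obs[q].a, obs[q].b))
              blocked = true;
          if (!blocked) {
            p.erase(p.begin() + k);
            removed_any = true;
            continue;
          }
        }
        ++k;
      }
    }
    double after = 0;
    for (size_t c = 0; c < nch; ++c) after += path_len(paths[c]);
    trace.push_back(after);
    // a sweep that only merged duplicate nodes changes no length but can
    // unlock further shortening: never declare convergence on it
    if (before - after < tol && !removed_any) {
      converged = true;
      break;
    }
  }

  NumericVector Lpp(nch), Ree(nch);
  IntegerVector Z(nch), ids(nch), nnode(nch);
  List out_paths(nch);
  for (size_t c = 0; c < nch; ++c) {
    const std::vector<V3>& p = paths[c];
    Lpp[c] = path_len(p);
    Ree[c] = nrm(sub(p.back(), p.front()));
    int z = 0;
    for (size_t k = 1; k + 1 < p.size(); ++k)
      if (kink_angle(p, k) >= kink_thresh) ++z;
    Z[c] = z;
    ids[c] = chain_ids[c];
    nnode[c] = (int)p.size();
    NumericMatrix m((int)p.size(), 3);
    for (size_t i = 0; i < p.size(); ++i) {
      m((int)i, 0) = p[i].x;
      m((int)i, 1) = p[i].y;
      m((int)i, 2) = p[i].z;
    }
    out_paths[c] = m;
  }
  return List::create(_["chain"] = ids, _["Lpp"] = Lpp, _["Z"] = Z,
                      _["Ree"] = Ree, _["n_nodes"] = nnode,
                      _["paths"] = out_paths,
                      _["length_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["sweeps"] = sweep + (converged ? 1 : 0),
                      _["converged"] = converged);
}
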