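// Space-filling placement engine: assigns 3D coordinates to tree nodes via
// branching angles, self-avoidance and boundary avoidance with iterative
// repair. Mirrors the R reference primitives exactly (same formulas, probe
// deltas and bisection schedules) so the two engines can be cross-checked.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double BTOL = 1e-9;

struct Wall {
  int type;           // 0 ellipsoid, 1 plane
  double p1[3], p2[3]; // center,semi | point,normal
};

struct Anatomy {
  std::vector<Wall> walls;
  std::vector<std::vector<int>> regions; // condition per wall: -1,0,+1
};

static double wall_value(const Wall& w, const double* p) {
  if (w.type == 0) {
    double s = 0;
    for (int i = 0; i < 3; i++) {
      double t = (p[i] - w.p1[i]) / w.p2[i];
      s += t * t;
    }
    return s - 1.0;
  }
  double s = 0;
  for (int i = 0; i < 3; i++) s += (p[i] - w.p1[i]) * w.p2[i];
  return s;
}

static bool inside_tissue(const Anatomy& a, const double* p) {
  int nw = a.walls.size();
  std::vector<double> vals(nw);
  for (int j = 0; j < nw; j++) vals[j] = wall_value(a.walls[j], p);
  for (size_t r = 0; r < a.regions.size(); r++) {
    bool ok = true;
    for (int j = 0; j < nw; j++) {
      int c = a.regions[r][j];
      if (c < 0 && !(vals[j] <= BTOL)) { ok = false; break; }
      if (c > 0 && !(vals[j] >= -BTOL)) { ok = false; break; }
    }
    if (ok) return true;
  }
  return false;
}

// nearest surface point on a wall; returns distance, fills xn[3]
static double wall_nearest(const Wall& w, const double* p, double* xn) {
  if (w.type == 1) {
    double g = 0;
    for (int i = 0; i < 3; i++) g += (p[i] - w.p1[i]) * w.p2[i];
    for (int i = 0; i < 3; i++) xn[i] = p[i] - g * w.p2[i];
    return std::fabs(g);
  }
  double q[3], a2[3], amin2 = 1e300, amax2 = 0, qn = 0;
  for (int i = 0; i < 3; i++) {
    q[i] = p[i] - w.p1[i];
    if (std::fabs(q[i]) < 1e-9) q[i] = 1e-9;
    a2[i] = w.p2[i] * w.p2[i];
    if (a2[i] < amin2) amin2 = a2[i];
    if (a2[i] > amax2) amax2 = a2[i];
    qn += q[i] * q[i];
  }
  qn = std::sqrt(qn);
  double amax = std::sqrt(amax2);
  double lo = -amin2 + 1e-12 * amax2;
  double hi = std::max(qn * amax, amax2);
  auto f = [&](double t) {
    double s = 0;
    for (int i = 0; i < 3; i++) {
      double u = w.p2[i] * q[i] / (t + a2[i]);
      s += u * u;
    }
    return s - 1.0;
  };
  for (int k = 0; k < 60 && f(hi) > 0; k++) hi *= 2;
  for (int k = 0; k < 100; k++) {
    double mid = 0.5 * (lo + hi);
    if (f(mid) > 0) lo = mid; else hi = mid;
  }
  double t = 0.5 * (lo + hi), d2 = 0;
  for (int i = 0; i < 3; i++) {
    xn[i] = w.p1[i] + a2[i] * q[i] / (t + a2[i]);
    double dd = p[i] - xn[i];
    d2 += dd * dd;
  }
  return std::sqrt(d2);
}

static void wall_gradient(const Wall& w, const double* p, double* g) {
  if (w.type == 0) {
    double n = 0;
    for (int i = 0; i < 3; i++) {
      g[i] = 2.0 * (p[i] - w.p1[i]) / (w.p2[i] * w.p2[i]);
      n += g[i] * g[i];
    }
    n = std::sqrt(n);
    for (int i = 0; i < 3; i++) g[i] /= (n > 0 ? n : 1.0);
  } else {
    for (int i = 0; i < 3; i++) g[i] = w.p2[i];
  }
}

// Boundary direction at p: sum over walls of the tissue-side unit normal at
// the nearest surface point, weighted exp(-d/(2L)). Tissue side is resolved
// by probing both sides of the surface (deltas 0.5 and 1.5 mm).
static void boundary_dir(const Anatomy& a, const double* p, double L,
                         bool probe_side, double* D) {
  D[0] = D[1] = D[2] = 0;
  for (size_t j = 0; j < a.walls.size(); j++) {
    double xn[3];
    double d = wall_nearest(a.walls[j], p, xn);
    double g[3];
    if (d > 1e-12) {
      for (int i = 0; i < 3; i++) g[i] = (p[i] - xn[i]) / d;
    } else {
      wall_gradient(a.walls[j], p, g);
    }
    double n[3] = { g[0], g[1], g[2] };
    if (probe_side) {
      // resolve which side of the wall is tissue; a wall with no tissue on
      // either side nearby carries no usable direction and is skipped
      bool resolved = false;
      static const double deltas[2] = { 0.5, 1.5 };
      for (int k = 0; k < 2; k++) {
        double pp[3], pm[3];
        for (int i = 0; i < 3; i++) {
          pp[i] = xn[i] + deltas[k] * g[i];
          pm[i] = xn[i] - deltas[k] * g[i];
        }
        bool ip = inside_tissue(a, pp), im = inside_tissue(a, pm);
        if (ip && !im) { resolved = true; break; }
        if (im && !ip) {
          n[0] = -g[0]; n[1] = -g[1]; n[2] = -g[2];
          resolved = true; break;
        }
      }
      if (!resolved) continue;
    }
    double wgt = std::exp(-d / (2.0 * L));
    for (int i = 0; i < 3; i++) D[i] += wgt * n[i];
  }
}

static double norm3(const double* v) {
  return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
}

static void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// Rodrigues rotation of v about unit axis k by angle th
static void rotate3(const double* v, const double* k, double th, double* out) {
  double c = std::cos(th), s = std::sin(th);
  double kx[3];
  cross3(k, v, kx);
  double kd = k[0] * v[0] + k[1] * v[1] + k[2] * v[2];
  for (int i = 0; i < 3; i++) {
    out[i] = v[i] * c + kx[i] * s + k[i] * kd * (1.0 - c);
  }
}

static double branch_angle(double Qp, double rp, double Qs, double rs,
                           double Qo, double ro, bool corrected) {
  // same-side daughter (s) vs other daughter (o); corrected convention keeps
  // the same-side term positive in the numerator
  double up = (Qp * Qp) / std::pow(rp, 4);
  double us = (Qs * Qs) / std::pow(rs, 4);
  double uo = (Qo * Qo) / std::pow(ro, 4);
  double num = corrected ? (up + us - uo) : (up + uo - us);
  double den = 2.0 * Qp * Qs / (rp * rp * rs * rs);
  double c = (den > 0) ? num / den : 1.0;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c);
}

// [[Rcpp::export(name = ".cpp_place_tree")]]
List cpp_place_tree(IntegerVector parent, IntegerVector ch1, IntegerVector ch2,
                    NumericVector radius, NumericVector flow,
                    NumericVector seg_len, NumericVector ls_junction,
                    LogicalVector preplaced, NumericMatrix pos0,
                    NumericVector root_prox,
                    IntegerVector proc_order,
                    NumericMatrix ext_pos, NumericVector ext_rad,
                    List anat, List par) {
  int n = parent.size();
  Anatomy A;
  IntegerVector types = anat["types"];
  NumericMatrix wpar = anat["params"];
  IntegerMatrix reg = anat["regions"];
  for (int j = 0; j < types.size(); j++) {
    Wall w;
    w.type = types[j];
    for (int i = 0; i < 3; i++) { w.p1[i] = wpar(j, i); w.p2[i] = wpar(j, i + 3); }
    A.walls.push_back(w);
  }
  for (int r = 0; r < reg.nrow(); r++) {
    std::vector<int> cond(types.size());
    for (int j = 0; j < types.size(); j++) cond[j] = reg(r, j);
    A.regions.push_back(cond);
  }
  double xi = par["xi"], cs = par["cs"], cb = par["cb"];
  int max_iter = par["max_repair_iterations"];
  double step_frac = par["step_frac"];
  int recompute_every = par["recompute_every"];
  bool corrected = par["corrected"];

  NumericMatrix pos(n, 3);
  LogicalVector placed(n);
  LogicalVector repaired(n);
  for (int i = 0; i < n; i++) {
    if (preplaced[i]) {
      placed[i] = true;
      for (int k = 0; k < 3; k++) pos(i, k) = pos0(i, k);
    }
  }
  int next = ext_pos.nrow();
  // contributor store: external nodes first, then own nodes as they place
  std::vector<double> cx, cy, cz, cr;
  cx.reserve(n + next); cy.reserve(n + next);
  cz.reserve(n + next); cr.reserve(n + next);
  for (int i = 0; i < next; i++) {
    cx.push_back(ext_pos(i, 0)); cy.push_back(ext_pos(i, 1));
    cz.push_back(ext_pos(i, 2)); cr.push_back(ext_rad[i]);
  }
  for (int i = 0; i < n; i++) {
    if (placed[i]) {
      cx.push_back(pos(i, 0)); cy.push_back(pos(i, 1));
      cz.push_back(pos(i, 2)); cr.push_back(radius[i]);
    }
  }

  // repair: move x along the probe-resolved boundary direction
  auto repair = [&](double* x, double L) {
    double dir[3] = { 0, 0, 0 };
    for (int it = 0; it < max_iter; it++) {
      if (inside_tissue(A, x)) return true;
      if (it % recompute_every == 0) {
        boundary_dir(A, x, L, true, dir);
        double nd = norm3(dir);
        if (nd < 1e-12) {
          // no usable direction: aim at the first region's first wall centre
          dir[0] = -x[0]; dir[1] = -x[1]; dir[2] = -x[2];
          nd = norm3(dir);
          if (nd < 1e-12) return false;
        }
        for (int i = 0; i < 3; i++) dir[i] /= nd;
      }
      for (int i = 0; i < 3; i++) x[i] += step_frac * L * dir[i];
    }
    return inside_tissue(A, x);
  };

  auto place_child = [&](int c, const double* xc, const double* vdir) {
    double x[3];
    for (int i = 0; i < 3; i++) x[i] = xc[i] + seg_len[c] * vdir[i];
    bool ok = inside_tissue(A, x);
    if (!ok) {
      ok = repair(x, seg_len[c]);
      if (ok) repaired[c] = true;
    }
    if (ok) {
      placed[c] = true;
      for (int i = 0; i < 3; i++) pos(c, i) = x[i];
      cx.push_back(x[0]); cy.push_back(x[1]); cz.push_back(x[2]);
      cr.push_back(radius[c]);
    }
  };

  for (int oi = 0; oi < proc_order.size(); oi++) {
    int s = proc_order[oi];
    if (!placed[s]) continue;
    int a = ch1[s], b = ch2[s];
    if (a < 0) continue;
    bool need_a = (a >= 0) && !preplaced[a];
    bool need_b = (b >= 0) && !preplaced[b];
    if (!need_a && !need_b) continue;

    double xc[3] = { pos(s, 0), pos(s, 1), pos(s, 2) };
    double sp[3];
    if (parent[s] < 0) {
      for (int i = 0; i < 3; i++) sp[i] = pos(s, i) - root_prox[i];
    } else {
      for (int i = 0; i < 3; i++) sp[i] = pos(s, i) - pos(parent[s], i);
    }
    double nsp = norm3(sp);
    if (nsp < 1e-12) { sp[0] = 0; sp[1] = 0; sp[2] = -1; nsp = 1; }
    for (int i = 0; i < 3; i++) sp[i] /= nsp;

    // daughter L = larger radius (ch1 by construction)
    double rL = radius[a], QL = flow[a];
    double rR = (b >= 0) ? radius[b] : radius[a];
    double QR = (b >= 0) ? flow[b] : 0.0;
    double thL = branch_angle(flow[s], radius[s], QL, rL, QR, rR, corrected);
    double thR = branch_angle(flow[s], radius[s], QR, rR, QL, rL, corrected);
    double rmin = (b >= 0) ? std::min(rL, rR) : rL;
    double Ls = ls_junction[s];

    // self-avoidance vector over placed contributor nodes
    double vs[3] = { 0, 0, 0 };
    for (size_t i = 0; i < cx.size(); i++) {
      if (cr[i] < rmin - 1e-12) continue;
      double sx = xc[0] - cx[i], sy = xc[1] - cy[i], sz = xc[2] - cz[i];
      double d = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (d < 1e-9) continue;
      double u = std::pow(Ls / d, xi);
      double w = (u / (1.0 + u)) / d;
      vs[0] += w * sx; vs[1] += w * sy; vs[2] += w * sz;
    }
    // boundary avoidance (interior point: normals point away from walls)
    double D[3];
    boundary_dir(A, xc, Ls, !inside_tissue(A, xc), D);

    double vd[3] = { 0, 0, 0 };
    double nvs = norm3(vs), nD = norm3(D);
    if (nvs > 1e-12) for (int i = 0; i < 3; i++) vd[i] += cs * vs[i] / nvs;
    if (nD > 1e-12) for (int i = 0; i < 3; i++) vd[i] += cb * D[i] / nD;
    double nvd = norm3(vd);
    if (nvd < 1e-12) { for (int i = 0; i < 3; i++) vd[i] = sp[i]; nvd = 1.0; }
    for (int i = 0; i < 3; i++) vd[i] /= nvd;

    // branching plane normal (s_p x v_d) x v_d, with deterministic fallback
    double t1[3], nb[3];
    cross3(sp, vd, t1);
    cross3(t1, vd, nb);
    double nnb = norm3(nb);
    if (nnb < 1e-9) {
      double ref[3] = { 1, 0, 0 };
      double dp = vd[0];
      for (int i = 0; i < 3; i++) nb[i] = ref[i] - dp * vd[i];
      nnb = norm3(nb);
      if (nnb < 1e-9) {
        double ref2[3] = { 0, 1, 0 };
        dp = vd[1];
        for (int i = 0; i < 3; i++) nb[i] = ref2[i] - dp * vd[i];
        nnb = norm3(nb);
      }
    }
    for (int i = 0; i < 3; i++) nb[i] /= nnb;

    double vL[3], vR[3];
    rotate3(vd, nb, thL, vL);
    rotate3(vd, nb, -thR, vR);
    if (need_a) place_child(a, xc, vL);
    if (need_b) place_child(b, xc, vR);
  }

  return List::create(_["pos"] = pos, _["placed"] = placed,
                      _["repaired"] = repaired);
}
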