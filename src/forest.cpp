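#include "vasc.h"

int VForest::add_vessel(Vec3 p, Vec3 d, int par, int role_, int beh,
                        int stage_, double outfrac) {
  int id = n();
  xp.push_back(p); xd.push_back(d);
  double l = dist(p, d);
  len.push_back(l);
  r.push_back(0.0); q.push_back(0.0);
  eta.push_back(3.6);
  rc.push_back(0.0);
  Rstar.push_back(0.0); Vstar.push_back(l);
  tq.push_back(0.0); tgam.push_back(0.0);
  sumTgam.push_back(0.0); sumW.push_back(0.0); sumQ.push_back(0.0);
  r_chk.push_back(0.0);
  rmax.push_back(0.0);
  parent.push_back(par);
  role.push_back(role_); behaviour.push_back(beh);
  stage.push_back(stage_);
  children.push_back(std::vector<int>());
  bool isout = R_finite(outfrac) && outfrac > 0;
  is_outlet.push_back(isout ? 1 : 0);
  out_frac.push_back(isout ? outfrac : 0.0);
  if (par >= 0) {
    children[par].push_back(id);
    tree.push_back(tree[par]);
  } else {
    tree.push_back(-1); // set by add_root
  }
  flows_valid = false;
  return id;
}

int VForest::add_root(Vec3 p, Vec3 d, double r1, double Q,
                      int role_, int beh, int stage_) {
  if (!(r1 > 0) || !(Q > 0)) Rcpp::stop("root radius and inflow must be positive");
  int id = add_vessel(p, d, -1, role_, beh, stage_, NA_REAL);
  tree[id] = (int)root_idx.size();
  root_idx.push_back(id);
  root_r.push_back(r1);
  root_q.push_back(Q);
  r[id] = r1;
  return id;
}

void VForest::postorder(std::vector<int>& order) const {
  order.clear();
  order.reserve(n());
  std::vector<std::pair<int, size_t> > stack;
  for (size_t t = 0; t < root_idx.size(); ++t) {
    stack.push_back(std::make_pair(root_idx[t], (size_t)0));
    while (!stack.empty()) {
      int v = stack.back().first;
      size_t ci = stack.back().second;
      if (ci < children[v].size()) {
        ++stack.back().second;
        stack.push_back(std::make_pair(children[v][ci], (size_t)0));
      } else {
        order.push_back(v);
        stack.pop_back();
      }
    }
  }
}

int VForest::n_terminals() const {
  int k = 0;
  for (int i = 0; i < n(); ++i) if (is_leaf(i)) ++k;
  return k;
}

int VForest::n_free_terminals() const {
  int k = 0;
  for (int i = 0; i < n(); ++i) if (is_leaf(i) && !is_outlet[i]) ++k;
  return k;
}

double VForest::total_inflow() const {
  double s = 0.0;
  for (size_t t = 0; t < root_q.size(); ++t) s += root_q[t];
  return s;
}

int VForest::bif_level(int i) const {
  int lv = 0;
  int a = parent[i];
  while (a >= 0) {
    if (children[a].size() >= 2) ++lv;
    a = parent[a];
  }
  return lv;
}

double VForest::assign_flows() {
  if (root_idx.empty()) Rcpp::stop("empty forest");
  double Q = total_inflow();
  double out = 0.0;
  int nfree = 0;
  for (int i = 0; i < n(); ++i) {
    if (!is_leaf(i)) continue;
    if (is_outlet[i]) out += out_frac[i] * Q; else ++nfree;
  }
  if (nfree == 0) {
    if (std::fabs(out - Q) > 1e-9 * Q)
      Rcpp::stop("no free terminals and outlet fractions do not sum to 1");
    qf = 0.0;
  } else {
    if (out >= Q)
      Rcpp::stop("prescribed outlet fractions consume the whole inflow");
    qf = (Q - out) / nfree;
  }
  std::vector<int> order;
  postorder(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int v = order[k];
    if (is_leaf(v)) {
      q[v] = is_outlet[v] ? out_frac[v] * Q : qf;
    } else {
      double s = 0.0;
      for (size_t c = 0; c < children[v].size(); ++c) s += q[children[v][c]];
      q[v] = s;
    }
  }
  flows_valid = true;
  return qf;
}

// one bottom-up sweep of reduced resistances / volume factors / sibling caches
// at the current radii (viscosity frozen at eta[], or eta_const if finite)
void VForest::refresh_reduced(double eta_const) {
  GammaOps G(gamma);
  std::vector<int> order;
  postorder(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int v = order[k];
    double ev = R_finite(eta_const) ? eta_const : eta[v];
    rc[v] = res_const(ev, len[v]);
    if (is_leaf(v)) {
      Rstar[v] = rc[v];
      Vstar[v] = len[v];
      sumTgam[v] = sumW[v] = sumQ[v] = 0.0;
    } else {
      double sg = 0.0, sw = 0.0, sq = 0.0;
      for (size_t c = 0; c < children[v].size(); ++c) {
        int ch = children[v][c];
        sg += tgam[ch];
        sw += tq[ch] * tq[ch] * Vstar[ch];
        sq += q[ch];
      }
      sumTgam[v] = sg; sumW[v] = sw; sumQ[v] = sq;
      double p1, p2, p4;
      G.powers(sg, p1, p2, p4);
      Rstar[v] = rc[v] + p4 / sq;
      Vstar[v] = len[v] + sw / p2;
    }
    tq[v] = fourth_root(q[v] * Rstar[v]);
    tgam[v] = G.pg(tq[v]);
  }
}

// Fixed-point radius update: bottom-up reduced resistances, sibling ratios
// equalising distal pressure drops under Murray's law, top-down radii from
// the fixed root radius, then viscosity refresh; iterate to tolerance.
Rcpp::List VForest::update_radii(double tol, int max_iter, double eta_const) {
  if (!flows_valid) assign_flows();
  GammaOps G(gamma);
  double resid = R_PosInf;
  int it = 0;
  while (it < max_iter) {
    ++it;
    refresh_reduced(eta_const);
    // top-down radii (preorder: parent before child)
    resid = 0.0;
    std::vector<int> stack;
    for (size_t t = 0; t < root_idx.size(); ++t) {
      int rt = root_idx[t];
      double old = r[rt];
      r[rt] = root_r[t];
      if (old > 0) {
        double d = std::fabs(r[rt] - old) / old;
        if (d > resid) resid = d;
      }
      stack.push_back(rt);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        if (children[v].empty()) continue;
        double S = G.p1g(sumTgam[v]);
        for (size_t c = 0; c < children[v].size(); ++c) {
          int ch = children[v][c];
          double rn = r[v] * tq[ch] / S;
          double oldc = r[ch];
          if (oldc > 0) {
            double d = std::fabs(rn - oldc) / oldc;
            if (d > resid) resid = d;
          } else resid = R_PosInf;
          r[ch] = rn;
          stack.push_back(ch);
        }
      }
    }
    if (!R_finite(eta_const))
      for (int v = 0; v < n(); ++v) eta[v] = fl_viscosity(r[v]);
    if (resid < tol) break;
  }
  // sync reduced state with the final radii/viscosities
  refresh_reduced(eta_const);
  for (int v = 0; v < n(); ++v) if (r[v] > rmax[v]) rmax[v] = r[v];
  if (resid >= tol && max_iter > 1)
    Rcpp::stop("radius fixed point did not converge in %d iterations (residual %g)",
               max_iter, resid);
  return Rcpp::List::create(Rcpp::Named("iterations") = it,
                            Rcpp::Named("residual") = resid);
}

double VForest::total_volume() const {
  double s = 0.0;
  for (int i = 0; i < n(); ++i) s += len[i] * M_PI * r[i] * r[i];
  return s;
}

double VForest::min_point_distance(const Vec3& x, Vec3* closest) const {
  double best = R_PosInf;
  double t;
  for (int i = 0; i < n(); ++i) {
    double d = point_segment_distance(x, xp[i], xd[i], &t);
    if (d < best) {
      best = d;
      if (closest) *closest = xp[i] + t * (xd[i] - xp[i]);
    }
  }
  return best;
}

void VForest::neighbourhood(const Vec3& x, double radius, std::vector<int>& out) const {
  out.clear();
  for (int i = 0; i < n(); ++i)
    if (point_segment_distance(x, xp[i], xd[i]) <= radius) out.push_back(i);
}

// cylinder-cylinder clash test against all non-exempt vessels.
// Adjacent vessels (sharing an endpoint with the trial segment) are exempt.
bool VForest::intersects_any(const Vec3& a, const Vec3& b, double rad,
                             const std::vector<int>& exempt,
                             double margin) const {
  for (int i = 0; i < n(); ++i) {
    bool skip = false;
    for (size_t k = 0; k < exempt.size(); ++k)
      if (exempt[k] == i) { skip = true; break; }
    if (skip) continue;
    if (same_point(xp[i], a) || same_point(xd[i], a) ||
        same_point(xp[i], b) || same_point(xd[i], b)) continue;
    double d = segment_segment_distance(a, b, xp[i], xd[i]);
    if (d < margin * (rad + r[i])) return true;
  }
  return false;
}

// Arc length along the tree between two points of the network. The point
// on edge a at parameter s reaches a's proximal node at cost s*len and its
// distal node at cost (1-s)*len; junction-to-junction steps cost the edge
// length. Arc lengths are invariant under splitting an edge, which makes
// the junction-region exemption stable over a whole run.
static std::vector<int> arc_stamp;
static std::vector<double> arc_cost;
static int arc_version = 0;

// seed the ancestor-node chain starting from a point on edge a located
// lp_cost from a's proximal node and ld_cost from its distal node
static void arc_seed(const VForest& fo, int a, double lp_cost, double ld_cost) {
  if ((int)arc_stamp.size() < fo.n()) {
    arc_stamp.assign(fo.n(), 0);
    arc_cost.assign(fo.n(), 0.0);
    arc_version = 0;
  }
  ++arc_version;
  arc_stamp[a] = arc_version;
  arc_cost[a] = ld_cost;                         // node D(a)
  double c = lp_cost;
  for (int p = fo.parent[a]; p >= 0; p = fo.parent[p]) {
    if (arc_stamp[p] != arc_version || c < arc_cost[p]) {
      arc_stamp[p] = arc_version;
      arc_cost[p] = c;                           // node D(p)
    }
    c += fo.len[p];
  }
}

// climb from a point on edge b (t*len from its proximal node) and return
// the minimal total arc to the seeded chain
static double arc_climb(const VForest& fo, int b, double t) {
  double best = std::numeric_limits<double>::infinity();
  double down = (1.0 - t) * fo.len[b];           // to node D(b)
  if (arc_stamp[b] == arc_version) best = arc_cost[b] + down;
  double up = t * fo.len[b];                     // to node P(b) and beyond
  for (int p = fo.parent[b]; p >= 0; p = fo.parent[p]) {
    if (arc_stamp[p] == arc_version) {
      double tot = arc_cost[p] + up;
      if (tot < best) best = tot;
    }
    up += fo.len[p];
  }
  return best;
}

double VForest::arc_gap(int a, double s, int b, double t) const {
  if (tree[a] != tree[b]) return std::numeric_limits<double>::infinity();
  arc_seed(*this, a, s * len[a], (1.0 - s) * len[a]);
  return arc_climb(*this, b, t);
}

double VForest::arc_gap_from_axis(int j, double lp, int b, double t) const {
  if (tree[j] != tree[b]) return std::numeric_limits<double>::infinity();
  arc_seed(*this, j, lp, len[j] - lp);
  return arc_climb(*this, b, t);
}

bool VForest::overlap_clash(const Vec3& a0, const Vec3& a1, double ra, int b,
                            double margin, double thr_a,
                            const std::function<double(double, double)>& arc_fn) const {
  double s_min, t_min;
  double d = segment_segment_distance(a0, a1, xp[b], xd[b], &s_min, &t_min);
  double bound = margin * (ra + r[b]);
  if (d >= bound) return false;
  // a proper interior-interior crossing of the two axes is always an
  // inter-penetration, junction-near or not (legitimate daughters touch
  // another axis only at their own endpoint)
  if (d < 1e-7 && s_min > 1e-6 && s_min < 1.0 - 1e-6 &&
      t_min > 1e-6 && t_min < 1.0 - 1e-6) return true;
  double rbm = rmax[b] > r[b] ? rmax[b] : r[b];
  double thr = 2.0 * (thr_a + rbm);
  Vec3 dir = a1 - a0;
  auto gd = [&](double s, double* t) {
    return point_segment_distance(a0 + s * dir, xp[b], xd[b], t);
  };
  auto bad = [&](double s) {
    double t;
    gd(s, &t);
    return arc_fn(s, t) > thr;
  };
  // distance to b is convex along the segment, so the violating range is
  // an interval; bisect its boundaries around the closest approach
  double sl = 0.0;
  if (!(gd(0.0, 0) < bound)) {
    double lo = 0.0, hi = s_min;
    for (int it = 0; it < 20; ++it) {
      double m = 0.5 * (lo + hi);
      if (gd(m, 0) < bound) hi = m; else lo = m;
    }
    sl = hi;
  }
  double sh = 1.0;
  if (!(gd(1.0, 0) < bound)) {
    double lo = s_min, hi = 1.0;
    for (int it = 0; it < 20; ++it) {
      double m = 0.5 * (lo + hi);
      if (gd(m, 0) < bound) lo = m; else hi = m;
    }
    sh = lo;
  }
  // a deep overlap (axes nearly touching) is a crossing, not a tangential
  // junction wedge: judge it at its own closest point (split-invariant)
  if (d < 0.5 * (ra + r[b]) && bad(s_min)) return true;
  // junction contiguity: the overlap is continuous lumen if any part of
  // the violating interval lies within the junction region
  return bad(sl) && bad(sh) && bad(s_min);
}

// Clash test for a trial terminal [xb, xt] attached to vessel j at axis
// position l_p from j's proximal node (l_p = len[j] for a distal
// attachment). The point at parameter u on the new vessel reaches the
// attachment point at arc u * |xt - xb|, which sits on j's axis, so the
// pre-commit arc machinery applies unchanged.
bool VForest::new_vessel_clash(int j, const Vec3& xb, const Vec3& xt,
                               double r_new, double l_p, bool distal,
                               double margin) const {
  double l_new = dist(xb, xt);
  for (int b = 0; b < n(); ++b) {
    if (b == j) continue;                    // v_p / v_s share the node xb
    if (tree[b] != tree[j]) {
      // other trees never share a lumen: plain clearance test
      double d = segment_segment_distance(xb, xt, xp[b], xd[b]);
      if (d < margin * (r_new + r[b])) return true;
      continue;
    }
    auto arc_fn = [&](double u, double t) {
      return u * l_new + arc_gap_from_axis(j, l_p, b, t);
    };
    if (overlap_clash(xb, xt, r_new, b, margin, r_new, arc_fn)) return true;
  }
  return false;
}

bool VForest::axis_clash(int j, double lp0, double lp1, double rad,
                         double margin) const {
  double lj = len[j];
  Vec3 dirv = (1.0 / lj) * (xd[j] - xp[j]);
  Vec3 a0 = xp[j] + lp0 * dirv;
  Vec3 a1 = xp[j] + lp1 * dirv;
  double rj = rmax[j] > rad ? rmax[j] : rad;
  for (int b = 0; b < n(); ++b) {
    if (b == j) continue;
    if (tree[b] != tree[j]) {
      double d = segment_segment_distance(a0, a1, xp[b], xd[b]);
      if (d < margin * (rad + r[b])) return true;
      continue;
    }
    auto arc_fn = [&](double s, double t) {
      return arc_gap_from_axis(j, lp0 + s * (lp1 - lp0), b, t);
    };
    if (overlap_clash(a0, a1, rad, b, margin, rj, arc_fn)) return true;
  }
  return false;
}

bool VForest::audit_pair_deep(int a, int b) const {
  double s, t;
  double d = segment_segment_distance(xp[a], xd[a], xp[b], xd[b], &s, &t);
  if (d < 1e-7 && s > 1e-6 && s < 1.0 - 1e-6 && t > 1e-6 && t < 1.0 - 1e-6)
    return true;                                   // proper axis crossing
  if (d >= 0.5 * (r[a] + r[b])) return false;      // graze, not penetration
  if (tree[a] != tree[b]) return true;
  double ra = rmax[a] > r[a] ? rmax[a] : r[a];
  double rb = rmax[b] > r[b] ? rmax[b] : r[b];
  return arc_gap(a, s, b, t) > 2.0 * (ra + rb);
}

bool VForest::audit_delta(const std::vector<int>& changed, int n_clash,
                          double margin, int* why, int* who_a, int* who_b,
                          double* info) const {
  for (size_t k = 0; k < changed.size(); ++k) {
    int a = changed[k];
    if (!(len[a] / r[a] > 2.0)) {                       // aspect ratio
      if (why) { *why = 1; *who_a = a; }
      return false;
    }
    for (int b = 0; b < n(); ++b) {
      if (b == a) continue;
      if (!audit_pair_deep(a, b)) continue;
      if (why) { *why = 2; *who_a = a; *who_b = b; }
      if (info) {
        double s, t;
        info[0] = segment_segment_distance(xp[a], xd[a], xp[b], xd[b], &s, &t);
        info[1] = r[a]; info[2] = r[b];
        info[3] = arc_gap(a, s, b, t);
        info[4] = s; info[5] = t;
      }
      return false;
    }
  }
  return true;
}
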