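#include "vasc.h"
#include <climits>

StagePars parse_stage(const Rcpp::List& s) {
  StagePars st;
  st.dom = parse_domain(Rcpp::as<Rcpp::List>(s["domain"]));
  st.gamma = Rcpp::as<double>(s["gamma"]);
  Rcpp::List del = s["delta"];
  st.delta_lo = Rcpp::as<double>(del["low"]);
  st.delta_hi = Rcpp::as<double>(del["high"]);
  st.delta_level = Rcpp::as<int>(del["level"]);
  st.nu = Rcpp::as<double>(s["nu"]);
  st.f_r = Rcpp::as<double>(s["f_r"]);
  st.f_n = Rcpp::as<double>(s["f_n"]);
  st.delta_v = Rcpp::as<int>(s["delta_v"]);
  st.n_fail = Rcpp::as<int>(s["n_fail"]);
  st.max_attempts = Rcpp::as<double>(s["max_attempts"]);
  Rcpp::List ang = s["angles"];
  st.ang.enabled = Rcpp::as<bool>(ang["enabled"]);
  st.ang.theta_min = Rcpp::as<double>(ang["theta_min"]);
  st.ang.theta_max = Rcpp::as<double>(ang["theta_max"]);
  st.ang.phi_min = Rcpp::as<double>(ang["phi_min"]);
  st.ang.phi_max = Rcpp::as<double>(ang["phi_max"]);
  st.cost = Rcpp::as<int>(s["cost"]);
  st.c_v = Rcpp::as<double>(s["c_v"]);
  st.c_p = Rcpp::as<double>(s["c_p"]);
  st.c_d = Rcpp::as<double>(s["c_d"]);
  st.Vref = Rcpp::as<double>(s["V_ref"]);
  st.lref = Rcpp::as<double>(s["l_ref"]);
  st.role = Rcpp::as<int>(s["role"]);
  st.behaviour = Rcpp::as<int>(s["behaviour"]);
  st.label = Rcpp::as<int>(s["label"]);
  st.l_c = Rcpp::as<double>(s["l_c"]);
  if (s.containsElementNamed("seed_stages") && !Rf_isNull(s["seed_stages"]))
    st.seed_stages = Rcpp::as<std::vector<int> >(s["seed_stages"]);
  st.dens = parse_density(Rcpp::as<Rcpp::List>(s["density"]));
  st.search_iters = Rcpp::as<int>(s["search_iters"]);
  st.nchecks_frac = Rcpp::as<double>(s["nchecks_frac"]);
  return st;
}

// Barycentric lattice over the triangle (x_t, xp_j, xd_j) with dv points per
// side, vertices excluded: dv(dv+1)/2 - 3 points for versatile vessels, only
// the xp_j - xd_j edge for fixed vessels, the single distal point for distal
// vessels, empty for non-branching vessels. Enumeration order is the
// deterministic tie-break order.
void lattice_points(const Vec3& xt, const Vec3& xpj, const Vec3& xdj, int dv,
                    int behaviour, std::vector<Vec3>& out) {
  out.clear();
  if (behaviour == 0) return;
  if (behaviour == 1) { out.push_back(xdj); return; }
  int nm1 = dv - 1;
  bool axis_only = (behaviour == 2);
  if (!axis_only) {
    // degenerate (collinear) triangle: fall back to the vessel axis
    Vec3 n = cross(xpj - xt, xdj - xt);
    double l1 = dist(xpj, xt), l2 = dist(xdj, xt);
    if (norm(n) <= 1e-12 * l1 * l2) axis_only = true;
  }
  for (int i = 0; i <= nm1; ++i) {          // weight of x_t
    if (axis_only && i > 0) break;
    for (int j = 0; j <= nm1 - i; ++j) {    // weight of xp_j
      int k = nm1 - i - j;                  // weight of xd_j
      if (i == nm1 || j == nm1 || k == nm1) continue; // vertices
      double a = (double)i / nm1, b = (double)j / nm1, c = (double)k / nm1;
      out.push_back(Vec3(a * xt.x + b * xpj.x + c * xdj.x,
                         a * xt.y + b * xpj.y + c * xdj.y,
                         a * xt.z + b * xpj.z + c * xdj.z));
    }
  }
}

// Evaluate a trial connection of terminal xt to vessel j at bifurcation xb
// without touching the forest. Flows are frozen at the current q_f, only the
// path to the root is re-reduced (closed-form O(1) ancestor updates), and a
// short local fixed point refreshes viscosities of the new vessels.
Candidate eval_candidate(const VForest& fo, int j, const Vec3& xb, const Vec3& xt,
                         bool distal, double gamma, int iters, bool freeze_eta) {
  Candidate cd;
  cd.j = j; cd.xb = xb; cd.xt = xt; cd.distal = distal;
  GammaOps G(gamma);
  double l_new = dist(xb, xt);
  double l_p = distal ? 0.0 : dist(fo.xp[j], xb);
  double l_s = distal ? 0.0 : dist(xb, fo.xd[j]);
  if (l_new <= 0.0 || (!distal && (l_p <= 0.0 || l_s <= 0.0))) return cd;
  double qf = fo.qf;
  double q_s = fo.q[j], q_new = qf;

  // path from j to its root
  static std::vector<int> path;       // ancestors of j, bottom-up
  static std::vector<double> beta_path;
  path.clear();
  for (int a = fo.parent[j]; a >= 0; a = fo.parent[a]) path.push_back(a);
  int rt = path.empty() ? j : path.back();
  int tr = fo.tree[j];

  double eta_p = fo.eta[j], eta_s = fo.eta[j], eta_new = fo.eta[j];

  // subtree aggregates of j, reused across passes
  double sub_p4 = 0.0, sub_p2 = 1.0;
  if (!fo.is_leaf(j)) {
    double p1;
    G.powers(fo.sumTgam[j], p1, sub_p2, sub_p4);
  }

  // local junction quantities for the current viscosities
  double t_n = 0, t_s = 0, curR = 0, curV = 0, curQ = 0, S_loc = 1;
  auto local_pass = [&]() {
    double Rn = res_const(eta_new, l_new);
    t_n = fourth_root(q_new * Rn);
    double tg_n = G.pg(t_n);
    double Sg, p1, p2, p4;
    if (distal) {
      Sg = fo.sumTgam[j] + tg_n;
      G.powers(Sg, p1, p2, p4);
      curR = fo.rc[j] + p4 / (fo.sumQ[j] + q_new);
      curV = fo.len[j] + (fo.sumW[j] + t_n * t_n * l_new) / p2;
    } else {
      double Rs = res_const(eta_s, l_s) +
        (fo.is_leaf(j) ? 0.0 : sub_p4 / fo.sumQ[j]);
      double Vs = l_s + (fo.is_leaf(j) ? 0.0 : fo.sumW[j] / sub_p2);
      t_s = fourth_root(q_s * Rs);
      Sg = G.pg(t_s) + tg_n;
      G.powers(Sg, p1, p2, p4);
      curR = res_const(eta_p, l_p) + p4 / (q_s + q_new);
      curV = l_p + (t_s * t_s * Vs + t_n * t_n * l_new) / p2;
    }
    curQ = fo.q[j] + q_new;
    S_loc = p1;
  };

  // Pass 1 (when two search iterations are requested): refresh the new
  // vessels' viscosities from radii estimated with the parent's current
  // scale, avoiding a second full path walk.
  if (iters >= 2 && !freeze_eta) {
    local_pass();
    double rr = fo.r[j];
    double e_s = distal ? rr : rr * t_s / S_loc;
    double e_n = rr * t_n / S_loc;
    if (!(e_n > 5.5e-4) || !(e_s > 5.5e-4)) return cd;
    eta_new = fl_viscosity(e_n);
    if (!distal) eta_s = fl_viscosity(e_s);
  }

  // final pass: full incremental path walk to the root
  local_pass();
  size_t np = path.size();
  if (beta_path.size() < np) beta_path.resize(np);
  // raw pointers hoisted so the loop carries no vector indirection
  const int* P = path.data();
  double* BP = beta_path.data();
  const double* aTgam = fo.sumTgam.data();
  const double* aQsum = fo.sumQ.data();
  const double* aWsum = fo.sumW.data();
  const double* aLen = fo.len.data();
  const double* aRc = fo.rc.data();
  const double* aQ = fo.q.data();
  const double* aTg = fo.tgam.data();
  const double* aTq = fo.tq.data();
  const double* aVs = fo.Vstar.data();
  int child = j;
  for (size_t k = 0; k < np; ++k) {
    int a = P[k];
    double tNew = fourth_root(curQ * curR);
    double Sg = aTgam[a] - aTg[child] + G.pg(tNew);
    double p1, p2, p4;
    G.powers(Sg, p1, p2, p4);
    double inv1 = 1.0 / p1;
    double wNew = tNew * tNew * curV;
    double wOld = aTq[child] * aTq[child] * aVs[child];
    curR = aRc[a] + p4 / (aQsum[a] + qf);
    curV = aLen[a] + (aWsum[a] - wOld + wNew) * (inv1 * inv1);
    curQ = aQ[a] + qf;
    BP[k] = tNew * inv1;
    child = a;
  }
  double r1 = fo.root_r[tr];
  cd.Rstar_root = curR;
  cd.Vstar_root = curV;
  double dvol = M_PI * r1 * r1 * (curV - fo.Vstar[rt]);
  // top-down along the path to the actual radii of the new vessels
  double rr = r1;
  for (size_t k = np; k-- > 0;) rr *= BP[k];
  double r_p, r_s, r_new;
  if (distal) {
    r_p = rr;                       // new radius of v_j itself (parent of v_new)
    r_s = rr;
    r_new = rr * t_n / S_loc;
  } else {
    r_p = rr;
    r_s = rr * t_s / S_loc;
    r_new = rr * t_n / S_loc;
  }
  if (!(r_new > 5.5e-4) || !(r_s > 5.5e-4)) return cd; // below viscosity pole
  cd.ok = true;
  cd.r_p = r_p; cd.r_s = r_s; cd.r_new = r_new;
  cd.dvol = dvol;
  cd.cost = dvol; // volume cost by default; sprouting applied by the caller
  return cd;
}

static double angle_deg(const Vec3& u, const Vec3& v) {
  double c = dot(u, v) / (norm(u) * norm(v));
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) * 180.0 / M_PI;
}

// n equally spaced membership checks along [a,b] (both endpoints included)
static bool segment_inside(const Domain& dom, const Vec3& a, const Vec3& b, int nchecks) {
  if (nchecks < 2) nchecks = 2;
  for (int i = 0; i < nchecks; ++i) {
    double t = (double)i / (nchecks - 1);
    if (!dom.inside(a + t * (b - a))) return false;
  }
  return true;
}

static int nchecks_for(const StagePars& st, double l) {
  int k = (int)std::ceil(l / (st.nchecks_frac * st.l_c)) + 1;
  return k < 2 ? 2 : k;
}

// Rejection reasons: 0 admissible, 1 eligibility, 2 bifurcation-site
// containment, 3 new-segment containment, 4 intersection, 5 symmetry,
// 6 aspect, 7 angle, 8 degenerate/eval failure
int gate_candidate(const VForest& fo, const StagePars& st, Candidate& c) {
  if (!c.ok) return 8;
  int j = c.j;
  // (2) bifurcation site containment by the parent vessel's role
  if ((fo.role[j] == 0 || fo.role[j] == 2) && !st.dom.inside(c.xb)) return 2;
  // (5) aspect ratio l/r > 2 for the new vessels
  double l_new = dist(c.xb, c.xt);
  if (!(l_new / c.r_new > 2.0)) return 6;
  if (!c.distal) {
    double l_p = dist(fo.xp[j], c.xb), l_s = dist(c.xb, fo.xd[j]);
    if (!(l_p / c.r_p > 2.0) || !(l_s / c.r_s > 2.0)) return 6;
  }
  // (5) symmetry ratio at the new bifurcation, level-dependent bound
  int lev = fo.bif_level(j);
  double delta = (lev < st.delta_level) ? st.delta_lo : st.delta_hi;
  if (delta > 0) {
    if (!c.distal) {
      double a = c.r_s, b = c.r_new;
      double ratio = a < b ? a / b : b / a;
      if (!(ratio > delta)) return 5;
    } else if (!fo.children[j].empty()) {
      // distal attachment to a vessel with children: compare v_new with the
      // existing siblings (pre-insertion radii as the reference)
      for (size_t k = 0; k < fo.children[j].size(); ++k) {
        double a = fo.r[fo.children[j][k]], b = c.r_new;
        double ratio = a < b ? a / b : b / a;
        if (!(ratio > delta)) return 5;
      }
    } // unary continuation of a leaf: no bifurcation, Eq (4) vacuous
  }
  // (6) angle constraints (split bifurcations only; the distal attachment has
  // no surviving v_s arm so the bifurcation plane is undefined)
  if (st.ang.enabled && !c.distal) {
    double th = angle_deg(fo.xd[j] - c.xb, c.xt - c.xb);
    if (!(th > st.ang.theta_min && th < st.ang.theta_max)) return 7;
    Vec3 nrm = cross(fo.xd[j] - c.xb, fo.xp[j] - c.xb);
    double nn = norm(nrm);
    if (nn > 1e-12 * dist(fo.xd[j], c.xb) * dist(fo.xp[j], c.xb)) {
      double s = std::fabs(dot(nrm, c.xt - c.xb)) / (nn * l_new);
      if (s > 1.0) s = 1.0;
      double phi = 90.0 - std::acos(s) * 180.0 / M_PI;
      if (!(phi > st.ang.phi_min && phi < st.ang.phi_max)) return 7;
    } // collinear plane: opening constraint skipped
  }
  // (3) new-segment containment by the stage's vessel type
  if (st.role == 0) {
    if (!segment_inside(st.dom, c.xb, c.xt, nchecks_for(st, l_new))) return 3;
  } else if (st.role == 2) {
    if (!st.dom.inside(c.xt)) return 3;  // perforator: distal end in the domain
  }
  // (4) cylinder intersection of the new vessel against all vessels outside
  // its (post-split) junction region; the split halves occupy v_j's
  // original footprint and their radii are re-audited after commit
  double l_pj = c.distal ? fo.len[j] : dist(fo.xp[j], c.xb);
  if (fo.new_vessel_clash(j, c.xb, c.xt, c.r_new, l_pj, c.distal, 1.0))
    return 4;
  return 0;
}

static double stage_cost(const VForest& fo, const StagePars& st, const Candidate& c) {
  if (st.cost == 0) return c.dvol;
  double rp = c.distal ? c.r_s : c.r_p;   // radius of the parent of v_new
  double rref = fo.root_r[fo.tree[c.j]];
  double lnew = dist(c.xb, c.xt);
  return st.c_v * c.dvol / st.Vref + st.c_p * rp / rref +
         st.c_d * (lnew / st.lref) * (lnew / st.lref);
}

// Brute-force optimal connection: all eligible vessels within f_n l_c of the
// terminal, all lattice points, deterministic enumeration order. The shared
// root path of one target vessel is walked for all its lattice candidates at
// once (independent per-candidate chains pipeline through the CPU), cheap
// geometric prefilters run before any hemodynamic work, and the expensive
// containment/intersection gates run only on cost-improving candidates.
Candidate best_connection(const VForest& fo, const StagePars& st, const Vec3& xt,
                          const std::vector<Candidate>* excluded,
                          std::vector<Candidate>* kept, int topk) {
  Candidate best;
  best.cost = R_PosInf;
  static std::vector<Candidate> keep_local;
  std::vector<Candidate>& keep = kept ? *kept : keep_local;
  keep.clear();
  GammaOps G(st.gamma);
  const double qf = fo.qf;
  // sprouting references: the currently vascularised volume (total tree
  // volume before the insertion) and its equivalent-sphere radius
  double Vref = 1.0, lref = 1.0;
  if (st.cost == 1) {
    Vref = fo.total_volume();
    lref = std::cbrt(3.0 * Vref / (4.0 * M_PI));
  }
  std::vector<int> nbr;
  fo.neighbourhood(xt, st.f_n * st.l_c, nbr);
  static std::vector<Vec3> pts;
  static std::vector<int> path;
  static std::vector<double> LR, LV, LS, Ltn, Lts, Llp, Lls, Lln, Brr;
  static std::vector<char> alive;
  static std::vector<double> betas;   // path.size() x lanes
  static std::vector<int> exempt;

  for (size_t vv = 0; vv < nbr.size(); ++vv) {
    int j = nbr[vv];
    if (fo.behaviour[j] == 0) continue;          // non-branching: ineligible
    if (!st.seed_stages.empty()) {
      bool okst = false;
      for (size_t k = 0; k < st.seed_stages.size(); ++k)
        if (st.seed_stages[k] == fo.stage[j]) { okst = true; break; }
      if (!okst) continue;
    }
    bool distal = fo.behaviour[j] == 1;
    lattice_points(xt, fo.xp[j], fo.xd[j], st.delta_v, fo.behaviour[j], pts);
    int NL = (int)pts.size();
    if (NL == 0) continue;

    path.clear();
    for (int a = fo.parent[j]; a >= 0; a = fo.parent[a]) path.push_back(a);
    size_t np = path.size();
    int rt = np ? path.back() : j;
    double r1 = fo.root_r[fo.tree[j]];
    double etaj = fo.eta[j];
    double q_s = fo.q[j];
    double curQ0 = fo.q[j] + qf;

    double sub_p4 = 0.0, sub_p2 = 1.0;
    if (!fo.is_leaf(j)) {
      double p1;
      G.powers(fo.sumTgam[j], p1, sub_p2, sub_p4);
    }

    LR.assign(NL, 0); LV.assign(NL, 0); LS.assign(NL, 0);
    Ltn.assign(NL, 0); Lts.assign(NL, 0);
    Llp.assign(NL, 0); Lls.assign(NL, 0); Lln.assign(NL, 0);
    alive.assign(NL, 1);
    int n_alive = 0;

    for (int ln = 0; ln < NL; ++ln) {
      const Vec3& xb = pts[ln];
      double l_new = dist(xb, xt);
      double l_p = distal ? 0.0 : dist(fo.xp[j], xb);
      double l_s = distal ? 0.0 : dist(xb, fo.xd[j]);
      if (l_new <= 0.0 || (!distal && (l_p <= 0.0 || l_s <= 0.0))) {
        alive[ln] = 0; continue;
      }
      if (excluded) {
        bool out = false;
        for (size_t q = 0; q < excluded->size(); ++q)
          if ((*excluded)[q].j == j && same_point((*excluded)[q].xb, xb)) {
            out = true; break;
          }
        if (out) { alive[ln] = 0; continue; }
      }
      // bifurcation-site containment by the parent vessel's role
      if ((fo.role[j] == 0 || fo.role[j] == 2) && !st.dom.inside(xb)) {
        alive[ln] = 0; continue;
      }
      // angle constraints are pure geometry: prefilter
      if (st.ang.enabled && !distal) {
        Vec3 u = fo.xd[j] - xb, w = xt - xb;
        double cth = dot(u, w) / (l_s * l_new);
        if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
        double th = std::acos(cth) * 180.0 / M_PI;
        if (!(th > st.ang.theta_min && th < st.ang.theta_max)) {
          alive[ln] = 0; continue;
        }
        Vec3 nrm = cross(fo.xd[j] - xb, fo.xp[j] - xb);
        double nn = norm(nrm);
        if (nn > 1e-12 * l_s * l_p) {
          double sph = std::fabs(dot(nrm, w)) / (nn * l_new);
          if (sph > 1.0) sph = 1.0;
          double phi = 90.0 - std::acos(sph) * 180.0 / M_PI;
          if (!(phi > st.ang.phi_min && phi < st.ang.phi_max)) {
            alive[ln] = 0; continue;
          }
        }
      }
      Llp[ln] = l_p; Lls[ln] = l_s; Lln[ln] = l_new;
      ++n_alive;
    }
    if (!n_alive) continue;

    // local junction state per lane, with a one-shot viscosity refinement of
    // the new vessels from radii estimated at the parent's current scale
    for (int ln = 0; ln < NL; ++ln) {
      if (!alive[ln]) continue;
      double eta_new = etaj, eta_s = etaj, eta_p = etaj;
      double l_new = Lln[ln], l_p = Llp[ln], l_s = Lls[ln];
      for (int pass = 0; pass < 2; ++pass) {
        double t_n = fourth_root(qf * res_const(eta_new, l_new));
        double tg_n = G.pg(t_n);
        double Sg, p1, p2, p4, t_s = 0;
        if (distal) {
          Sg = fo.sumTgam[j] + tg_n;
          G.powers(Sg, p1, p2, p4);
          LR[ln] = fo.rc[j] + p4 / (fo.sumQ[j] + qf);
          LV[ln] = fo.len[j] + (fo.sumW[j] + t_n * t_n * l_new) / p2;
        } else {
          double Rs = res_const(eta_s, l_s) +
            (fo.is_leaf(j) ? 0.0 : sub_p4 / fo.sumQ[j]);
          double Vs = l_s + (fo.is_leaf(j) ? 0.0 : fo.sumW[j] / sub_p2);
          t_s = fourth_root(q_s * Rs);
          Sg = G.pg(t_s) + tg_n;
          G.powers(Sg, p1, p2, p4);
          LR[ln] = res_const(eta_p, l_p) + p4 / (q_s + qf);
          LV[ln] = l_p + (t_s * t_s * Vs + t_n * t_n * l_new) / p2;
        }
        LS[ln] = p1; Ltn[ln] = t_n; Lts[ln] = t_s;
        if (pass == 1 || st.search_iters < 2) break;
        double rr = fo.r[j];
        double e_s = distal ? rr : rr * t_s / p1;
        double e_n = rr * Ltn[ln] / p1;
        if (!(e_n > 5.5e-4) || !(e_s > 5.5e-4)) { alive[ln] = 0; break; }
        eta_new = fl_viscosity(e_n);
        if (!distal) { eta_s = fl_viscosity(e_s); }
      }
    }

    // batched incremental walk to the root for all surviving lanes
    betas.assign(np * NL, 0.0);
    {
      const double* aTgam = fo.sumTgam.data();
      const double* aQsum = fo.sumQ.data();
      const double* aWsum = fo.sumW.data();
      const double* aLen = fo.len.data();
      const double* aRc = fo.rc.data();
      const double* aQ = fo.q.data();
      const double* aTg = fo.tgam.data();
      const double* aTq = fo.tq.data();
      const double* aVs = fo.Vstar.data();
      int child = j;
      double curQ = curQ0;
      for (size_t k = 0; k < np; ++k) {
        int a = path[k];
        double sTg = aTgam[a] - aTg[child];
        double sq = aQsum[a] + qf;
        double wOld = aTq[child] * aTq[child] * aVs[child];
        double sW = aWsum[a] - wOld;
        double rc_a = aRc[a], len_a = aLen[a];
        double* B = &betas[k * NL];
        for (int ln = 0; ln < NL; ++ln) {
          if (!alive[ln]) continue;
          double tNew = fourth_root(curQ * LR[ln]);
          double Sg = sTg + G.pg(tNew);
          double p1, p2, p4;
          G.powers(Sg, p1, p2, p4);
          double inv1 = 1.0 / p1;
          LR[ln] = rc_a + p4 / sq;
          LV[ln] = len_a + (sW + tNew * tNew * LV[ln]) * (inv1 * inv1);
          B[ln] = tNew * inv1;
        }
        curQ = aQ[a] + qf;
        child = a;
      }
    }

    // per-lane finish: radii, cheap constraints, cost, deep gates
    int lev = fo.bif_level(j);
    double delta = (lev < st.delta_level) ? st.delta_lo : st.delta_hi;
    for (int ln = 0; ln < NL; ++ln) {
      if (!alive[ln]) continue;
      double dvol = M_PI * r1 * r1 * (LV[ln] - fo.Vstar[rt]);
      // top-down along the path: re-scaled ancestors must keep the aspect
      // constraint (radius of ancestor path[k] is the beta product above it)
      double rr = r1;
      bool ok = true;
      for (size_t k = np; k-- > 0;) {
        if (!(fo.len[path[k]] / rr > 2.02)) { ok = false; break; }
        rr *= betas[k * NL + ln];
      }
      if (!ok) continue;      // rr is now the radius of v_p (v_j if distal)
      double r_p = rr;
      double r_s = distal ? rr : rr * Lts[ln] / LS[ln];
      double r_new = rr * Ltn[ln] / LS[ln];
      if (!(r_new > 5.5e-4) || !(r_s > 5.5e-4)) continue;
      // aspect of the new trio (with the clearance margin, so the
      // constraint survives subsequent radius drift)
      if (!(Lln[ln] / r_new > 2.02)) continue;
      if (!distal && (!(Llp[ln] / r_p > 2.02) || !(Lls[ln] / r_s > 2.02)))
        continue;
      // symmetry bound at the new junction
      if (delta > 0) {
        if (!distal) {
          double ratio = r_s < r_new ? r_s / r_new : r_new / r_s;
          if (!(ratio > delta)) continue;
        } else if (!fo.children[j].empty()) {
          bool bad = false;
          for (size_t k = 0; k < fo.children[j].size(); ++k) {
            double a = fo.r[fo.children[j][k]], b = r_new;
            double ratio = a < b ? a / b : b / a;
            if (!(ratio > delta)) { bad = true; break; }
          }
          if (bad) continue;
        }
      }
      double cost;
      if (st.cost == 0) cost = dvol;
      else {
        double rp_of_new = distal ? r_s : r_p;
        cost = st.c_v * dvol / Vref + st.c_p * rp_of_new / r1 +
          st.c_d * (Lln[ln] / lref) * (Lln[ln] / lref);
      }
      // ties keep the earlier candidate in enumeration order
      double worst = ((int)keep.size() < topk) ? R_PosInf
                                               : keep.back().cost;
      if (!(cost < worst)) continue;
      const Vec3& xb = pts[ln];
      // deep gates: new-segment containment by the stage's vessel type
      if (st.role == 0) {
        if (!segment_inside(st.dom, xb, xt, nchecks_for(st, Lln[ln])))
          continue;
      } else if (st.role == 2) {
        if (!st.dom.inside(xt)) continue;
      }
      // cylinder clash of the new vessel: arc-length junction exemption,
      // 1% clearance margin
      double lpj = distal ? fo.len[j] : Llp[ln];
      if (fo.new_vessel_clash(j, xb, xt, r_new, lpj, distal, 1.05)) continue;
      // the re-sized split halves must clear their surroundings as well
      if (!distal) {
        if (fo.axis_clash(j, 0.0, Llp[ln], r_p, 1.03)) continue;
        if (fo.axis_clash(j, Llp[ln], fo.len[j], r_s, 1.03)) continue;
      }
      Candidate c;
      c.ok = true;
      c.j = j; c.distal = distal;
      c.xb = xb; c.xt = xt;
      c.cost = cost; c.dvol = dvol;
      c.r_p = r_p; c.r_s = r_s; c.r_new = r_new;
      c.Rstar_root = LR[ln]; c.Vstar_root = LV[ln];
      // stable sorted insert (equal costs stay behind earlier candidates)
      size_t pos = keep.size();
      while (pos > 0 && keep[pos - 1].cost > cost) --pos;
      keep.insert(keep.begin() + pos, c);
      if ((int)keep.size() > topk) keep.pop_back();
    }
  }
  if (!keep.empty()) best = keep.front();
  return best;
}

void commit_candidate(VForest& fo, const StagePars& st, const Candidate& c,
                      int* id_s, int* id_new) {
  int j = c.j;
  if (c.distal) {
    if (id_s) *id_s = -1;
    int vn = fo.add_vessel(c.xb, c.xt, j, st.role, st.behaviour, st.label, NA_REAL);
    if (id_new) *id_new = vn;
  } else {
    // split: j keeps its proximal half (v_p); v_s inherits children/role/
    // behaviour/outlet identity; a non-branching parent leaves both halves
    // non-branching, otherwise v_p becomes versatile with its original role
    int vs = fo.add_vessel(c.xb, fo.xd[j], -1, fo.role[j], fo.behaviour[j],
                           fo.stage[j], fo.is_outlet[j] ? fo.out_frac[j] : NA_REAL);
    fo.parent[vs] = j;
    fo.tree[vs] = fo.tree[j];
    fo.children[vs] = fo.children[j];
    for (size_t k = 0; k < fo.children[vs].size(); ++k)
      fo.parent[fo.children[vs][k]] = vs;
    fo.children[j].clear();
    fo.children[j].push_back(vs);
    int vn = fo.add_vessel(c.xb, c.xt, j, st.role, st.behaviour, st.label, NA_REAL);
    fo.xd[j] = c.xb;
    fo.len[j] = dist(fo.xp[j], c.xb);
    if (fo.behaviour[j] != 0) fo.behaviour[j] = 3;
    fo.is_outlet[j] = 0;
    fo.out_frac[j] = 0.0;
    if (id_s) *id_s = vs;
    if (id_new) *id_new = vn;
  }
  fo.flows_valid = false;
}
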