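#include "vasc.h"
#include <chrono>

using namespace Rcpp;

static Vec3 as_vec3(const NumericVector& x) {
  if (x.size() == 2) return Vec3(x[0], x[1], 0.0);
  if (x.size() != 3) stop("point must have 2 or 3 coordinates");
  return Vec3(x[0], x[1], x[2]);
}

// ------------------------------------------------------------- forest basics

// [[Rcpp::export]]
SEXP vt_new_forest(double gamma) {
  VForest* f = new VForest();
  f->gamma = gamma;
  return XPtr<VForest>(f, true);
}

// [[Rcpp::export]]
SEXP vt_copy_forest(SEXP ptr) {
  XPtr<VForest> f(ptr);
  return XPtr<VForest>(new VForest(*f), true);
}

// [[Rcpp::export]]
void vt_restore_forest(SEXP ptr, SEXP snapshot) {
  XPtr<VForest> f(ptr), s(snapshot);
  *f = *s;
}

// [[Rcpp::export]]
int vt_size(SEXP ptr) { return XPtr<VForest>(ptr)->n(); }

// [[Rcpp::export]]
double vt_gamma(SEXP ptr) { return XPtr<VForest>(ptr)->gamma; }

// [[Rcpp::export]]
void vt_set_gamma(SEXP ptr, double g) { XPtr<VForest>(ptr)->gamma = g; }

// [[Rcpp::export]]
int vt_add_root(SEXP ptr, NumericVector xp, NumericVector xd, double r1, double Q,
                int role, int behaviour, int stage) {
  XPtr<VForest> f(ptr);
  return f->add_root(as_vec3(xp), as_vec3(xd), r1, Q, role, behaviour, stage) + 1;
}

// [[Rcpp::export]]
int vt_add_vessel(SEXP ptr, NumericVector xp, NumericVector xd, int parent,
                  int role, int behaviour, int stage, double out_frac) {
  XPtr<VForest> f(ptr);
  int p = parent - 1;
  if (p < 0 || p >= f->n()) stop("parent vessel %d not in forest", parent);
  Vec3 a = as_vec3(xp);
  if (!same_point(a, f->xd[p]))
    stop("child proximal point must coincide with the parent distal point");
  return f->add_vessel(a, as_vec3(xd), p, role, behaviour, stage, out_frac) + 1;
}

// [[Rcpp::export]]
List vt_table(SEXP ptr) {
  XPtr<VForest> f(ptr);
  int n = f->n();
  NumericMatrix XP(n, 3), XD(n, 3);
  NumericVector R(n), Q(n), ETA(n), OF(n), LEN(n), RMX(n);
  IntegerVector PAR(n), ROLE(n), BEH(n), STG(n), TRE(n), LVL(n), NCH(n);
  LogicalVector OUT(n), LEAF(n);
  for (int i = 0; i < n; ++i) {
    XP(i, 0) = f->xp[i].x; XP(i, 1) = f->xp[i].y; XP(i, 2) = f->xp[i].z;
    XD(i, 0) = f->xd[i].x; XD(i, 1) = f->xd[i].y; XD(i, 2) = f->xd[i].z;
    R[i] = f->r[i]; Q[i] = f->q[i]; ETA[i] = f->eta[i]; LEN[i] = f->len[i];
    RMX[i] = f->rmax[i] > f->r[i] ? f->rmax[i] : f->r[i];
    PAR[i] = f->parent[i] + 1;
    ROLE[i] = f->role[i]; BEH[i] = f->behaviour[i];
    STG[i] = f->stage[i]; TRE[i] = f->tree[i] + 1;
    LVL[i] = f->bif_level(i);
    NCH[i] = (int)f->children[i].size();
    OUT[i] = f->is_outlet[i] != 0;
    OF[i] = f->out_frac[i];
    LEAF[i] = f->is_leaf(i);
  }
  return List::create(_["xp"] = XP, _["xd"] = XD, _["radius"] = R, _["flow"] = Q,
                      _["eta"] = ETA, _["length"] = LEN, _["parent"] = PAR,
                      _["role"] = ROLE, _["behaviour"] = BEH, _["stage"] = STG,
                      _["tree"] = TRE, _["level"] = LVL, _["n_children"] = NCH,
                      _["outlet"] = OUT, _["outlet_fraction"] = OF,
                      _["terminal"] = LEAF, _["rmax"] = RMX);
}

// [[Rcpp::export]]
List vt_roots(SEXP ptr) {
  XPtr<VForest> f(ptr);
  int m = (int)f->root_idx.size();
  IntegerVector id(m); NumericVector rr(m), qq(m);
  for (int t = 0; t < m; ++t) {
    id[t] = f->root_idx[t] + 1; rr[t] = f->root_r[t]; qq[t] = f->root_q[t];
  }
  return List::create(_["id"] = id, _["radius"] = rr, _["inflow"] = qq);
}

// [[Rcpp::export]]
IntegerVector vt_children(SEXP ptr, int id) {
  XPtr<VForest> f(ptr);
  const std::vector<int>& ch = f->children[id - 1];
  IntegerVector out(ch.size());
  for (size_t k = 0; k < ch.size(); ++k) out[k] = ch[k] + 1;
  return out;
}

// [[Rcpp::export]]
int vt_n_terminals(SEXP ptr) { return XPtr<VForest>(ptr)->n_terminals(); }

// [[Rcpp::export]]
int vt_bif_level(SEXP ptr, int id) { return XPtr<VForest>(ptr)->bif_level(id - 1); }

// [[Rcpp::export]]
void vt_set_outlet(SEXP ptr, int id, double fraction) {
  XPtr<VForest> f(ptr);
  int i = id - 1;
  if (i < 0 || i >= f->n()) stop("vessel %d not in forest", id);
  if (!(fraction > 0 && fraction < 1)) stop("outlet fraction must lie in (0, 1)");
  f->is_outlet[i] = 1;
  f->out_frac[i] = fraction;
  f->flows_valid = false;
}

// ------------------------------------------------------------- spatial queries

// [[Rcpp::export]]
IntegerVector vt_neighbourhood(SEXP ptr, NumericVector x, double radius) {
  XPtr<VForest> f(ptr);
  std::vector<int> out;
  f->neighbourhood(as_vec3(x), radius, out);
  IntegerVector res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = out[k] + 1;
  return res;
}

// [[Rcpp::export]]
List vt_min_point_distance(SEXP ptr, NumericVector x) {
  XPtr<VForest> f(ptr);
  if (f->n() == 0) stop("empty forest");
  Vec3 cl;
  double d = f->min_point_distance(as_vec3(x), &cl);
  return List::create(_["distance"] = d,
                      _["point"] = NumericVector::create(cl.x, cl.y, cl.z));
}

// [[Rcpp::export]]
double vt_segseg_distance(NumericVector a0, NumericVector a1,
                          NumericVector b0, NumericVector b1) {
  return segment_segment_distance(as_vec3(a0), as_vec3(a1), as_vec3(b0), as_vec3(b1));
}

// ------------------------------------------------------------- hemodynamics

// [[Rcpp::export]]
double vt_assign_flows(SEXP ptr) { return XPtr<VForest>(ptr)->assign_flows(); }

// [[Rcpp::export]]
List vt_update_radii(SEXP ptr, double tol, int max_iter, double eta_const) {
  return XPtr<VForest>(ptr)->update_radii(tol, max_iter, eta_const);
}

// [[Rcpp::export]]
double vt_total_volume(SEXP ptr) { return XPtr<VForest>(ptr)->total_volume(); }

// [[Rcpp::export]]
NumericVector vt_viscosity(NumericVector r) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = fl_viscosity(r[i]);
  return out;
}

// ------------------------------------------------------------- domain / density

// [[Rcpp::export]]
LogicalVector vt_domain_contains(List domain, NumericMatrix X) {
  Domain dom = parse_domain(domain);
  LogicalVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = dom.inside(Vec3(X(i, 0), X(i, 1), X(i, 2)));
  return out;
}

// [[Rcpp::export]]
NumericMatrix vt_sample_points(List domain, List density, int n, int max_attempts) {
  Domain dom = parse_domain(domain);
  Density dens = parse_density(density);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p = dens.sample(dom, max_attempts);
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
  }
  return out;
}

// [[Rcpp::export]]
bool vt_segment_in_domain(List domain, NumericVector a, NumericVector b, int n_checks) {
  Domain dom = parse_domain(domain);
  if (n_checks < 2) stop("n_checks must be at least 2");
  Vec3 va = as_vec3(a), vb = as_vec3(b);
  for (int i = 0; i < n_checks; ++i) {
    double t = n_checks == 1 ? 0.0 : (double)i / (n_checks - 1);
    if (!dom.inside(va + t * (vb - va))) return false;
  }
  return true;
}

// [[Rcpp::export]]
double vt_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  // divergence theorem over a closed triangulated surface
  double vol = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    Vec3 a(V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2));
    Vec3 b(V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2));
    Vec3 c(V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2));
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return std::fabs(vol);
}

// ------------------------------------------------------------- growth engine

// [[Rcpp::export]]
NumericMatrix vt_lattice(NumericVector xt, NumericVector xpj, NumericVector xdj,
                         int delta_v, int behaviour) {
  std::vector<Vec3> pts;
  if (delta_v < 3) stop("delta_v must be at least 3");
  lattice_points(as_vec3(xt), as_vec3(xpj), as_vec3(xdj), delta_v, behaviour, pts);
  NumericMatrix out(pts.size(), 3);
  for (size_t k = 0; k < pts.size(); ++k) {
    out(k, 0) = pts[k].x; out(k, 1) = pts[k].y; out(k, 2) = pts[k].z;
  }
  return out;
}

// [[Rcpp::export]]
List vt_eval_candidate(SEXP ptr, int j, NumericVector xb, NumericVector xt,
                       bool distal, int iters, bool freeze_eta) {
  XPtr<VForest> f(ptr);
  if (!f->flows_valid) stop("flows not assigned; run assign_flows/update_radii first");
  Candidate c = eval_candidate(*f, j - 1, as_vec3(xb), as_vec3(xt), distal,
                               f->gamma, iters, freeze_eta);
  return List::create(_["ok"] = c.ok, _["dvol"] = c.dvol, _["r_p"] = c.r_p,
                      _["r_s"] = c.r_s, _["r_new"] = c.r_new,
                      _["Rstar_root"] = c.Rstar_root, _["Vstar_root"] = c.Vstar_root);
}

static List candidate_to_list(const VForest& f, const Candidate& c) {
  if (!c.ok || !R_finite(c.cost))
    return List::create(_["found"] = false);
  return List::create(
    _["found"] = true, _["vessel"] = c.j + 1, _["distal"] = c.distal,
    _["x_b"] = NumericVector::create(c.xb.x, c.xb.y, c.xb.z),
    _["x_t"] = NumericVector::create(c.xt.x, c.xt.y, c.xt.z),
    _["cost"] = c.cost, _["dvol"] = c.dvol,
    _["r_p"] = c.r_p, _["r_s"] = c.r_s, _["r_new"] = c.r_new);
}

// [[Rcpp::export]]
List vt_best_connection(SEXP ptr, List stage, NumericVector xt) {
  XPtr<VForest> f(ptr);
  StagePars st = parse_stage(stage);
  if (!f->flows_valid) stop("flows not assigned; run update_radii first");
  f->gamma = st.gamma;
  Candidate best = best_connection(*f, st, as_vec3(xt));
  return candidate_to_list(*f, best);
}

// [[Rcpp::export]]
List vt_admissible(SEXP ptr, List stage, int j, NumericVector xb, NumericVector xt,
                   bool distal) {
  XPtr<VForest> f(ptr);
  StagePars st = parse_stage(stage);
  if (!f->flows_valid) stop("flows not assigned; run update_radii first");
  int jj = j - 1;
  int why;
  Candidate c;
  if (f->behaviour[jj] == 0) {
    why = 1; // non-branching vessels are not eligible parents
  } else if (f->behaviour[jj] == 1 && !(distal && same_point(as_vec3(xb), f->xd[jj]))) {
    why = 1; // distal vessels only accept their distal point
  } else {
    c = eval_candidate(*f, jj, as_vec3(xb), as_vec3(xt), distal, st.gamma,
                       st.search_iters, false);
    if (c.ok) c.cost = 0.0;
    why = gate_candidate(*f, st, c);
  }
  const char* reasons[] = {"admissible", "eligibility", "role-containment",
                           "segment-containment", "intersection", "symmetry",
                           "aspect", "angle", "degenerate"};
  return List::create(_["admissible"] = (why == 0), _["reason"] = reasons[why],
                      _["code"] = why);
}

// [[Rcpp::export]]
List vt_commit_candidate(SEXP ptr, List stage, int j, NumericVector xb,
                         NumericVector xt, bool distal) {
  XPtr<VForest> f(ptr);
  StagePars st = parse_stage(stage);
  Candidate c;
  c.ok = true; c.j = j - 1; c.xb = as_vec3(xb); c.xt = as_vec3(xt); c.distal = distal;
  int id_s, id_new;
  commit_candidate(*f, st, c, &id_s, &id_new);
  return List::create(_["v_p"] = j, _["v_s"] = id_s + 1, _["v_new"] = id_new + 1);
}

// [[Rcpp::export]]
int vt_create_root(SEXP ptr, List stage, NumericVector inlet, double r1, double Q,
                   int role, int behaviour) {
  XPtr<VForest> f(ptr);
  StagePars st = parse_stage(stage);
  f->gamma = st.gamma;
  Vec3 p0 = as_vec3(inlet);
  double relax = 1.0;
  int fails = 0;
  double attempts = 0;
  std::vector<int> exempt;
  while (attempts < st.max_attempts) {
    ++attempts;
    if (((long)attempts) % 256 == 0) checkUserInterrupt();
    Vec3 x = st.dens.sample(st.dom, 1000000);
    double l = dist(p0, x);
    bool ok = l / r1 > 2.0;
    if (ok && f->n() > 0) {
      int NT = f->n_terminals();
      double llim = relax * st.l_c *
        (st.dom.D == 2 ? std::sqrt(st.nu / (NT + 1)) : std::cbrt(st.nu / (NT + 1)));
      ok = f->min_point_distance(x) >= llim;
    }
    if (ok && role != 1) {
      if (role == 0) ok = [&]() {
        int nc = (int)std::ceil(l / (st.nchecks_frac * st.l_c)) + 1;
        if (nc < 2) nc = 2;
        for (int i = 0; i < nc; ++i) {
          double t = (double)i / (nc - 1);
          if (!st.dom.inside(p0 + t * (x - p0))) return false;
        }
        return true;
      }();
      else ok = st.dom.inside(x); // perforator: distal end inside
    }
    if (ok && f->n() > 0 && f->intersects_any(p0, x, r1, exempt)) ok = false;
    if (ok) {
      int id = f->add_root(p0, x, r1, Q, role, behaviour,
                           Rcpp::as<int>(stage["label"]));
      return id + 1;
    }
    if (++fails % st.n_fail == 0) relax *= st.f_r;
  }
  stop("root creation failed: attempt budget exhausted");
}

// Clearance margin: pairs are re-validated whenever a radius grows beyond
// this factor of its last-checked value, so enforcing the clash constraint
// with the same margin keeps the nominal constraint valid at all times.
static const double kClashMargin = 1.01;

// [[Rcpp::export]]
List vt_grow_stage(SEXP ptr, List stage, int budget, double tol, int max_iter) {
  XPtr<VForest> f(ptr);
  StagePars st = parse_stage(stage);
  f->gamma = st.gamma;
  if (f->n() == 0) stop("empty forest: create roots before growing a stage");
  f->assign_flows();
  f->update_radii(tol, max_iter, NA_REAL);

  // baseline for growth-triggered intersection re-checks
  f->r_chk = f->r;
  double relax = 1.0;
  int fails = 0, committed = 0;
  double attempts = 0;
  int dist_rej = 0, conn_rej = 0, grown_rej = 0, relaxations = 0;
  int rb_aspect = 0, rb_clash_new = 0, rb_clash_old = 0;
  std::vector<int> rb_wa, rb_wb, rb_jv, rb_new, rb_vs;
  std::vector<double> rb_info;
  double t_sample = 0, t_search = 0, t_update = 0, t_audit = 0;
  using clk = std::chrono::steady_clock;
  std::vector<int> new_ids;
  std::vector<double> relax_at;

  while (committed < budget) {
    if (attempts >= st.max_attempts)
      stop("stage '%d' aborted: attempt budget exhausted after %d of %d terminals "
           "(distance rejections %d, connection failures %d)",
           st.label, committed, budget, dist_rej, conn_rej);
    ++attempts;
    if (((long)attempts) % 64 == 0) checkUserInterrupt();
    clk::time_point c0 = clk::now();
    Vec3 x = st.dens.sample(st.dom, 1000000);
    int NT = f->n_terminals();
    double llim = relax * st.l_c *
      (st.dom.D == 2 ? std::sqrt(st.nu / (NT + 1)) : std::cbrt(st.nu / (NT + 1)));
    bool failed = false;
    bool was_far = f->min_point_distance(x) < llim;
    t_sample += std::chrono::duration<double>(clk::now() - c0).count();
    if (was_far) {
      ++dist_rej;
      failed = true;
    } else {
      // The min-cost candidate whose committed, fully re-converged tree
      // passes the constraint audit wins: audited failures are rolled
      // back, excluded, and the search repeats for the same terminal.
      clk::time_point c1 = clk::now();
      static std::vector<Candidate> excluded;
      static std::vector<Candidate> kept;
      excluded.clear();
      bool connected = false, exhausted = false;
      size_t cursor = 0;
      best_connection(*f, st, x, &excluded, &kept, 25);
      while (!connected && !exhausted) {
        // next cheapest candidate; refill with a fresh (exclusion-aware)
        // search when the collected batch is used up
        if (cursor >= kept.size()) {
          best_connection(*f, st, x, &excluded, &kept, 25);
          cursor = 0;
          if (kept.empty()) { exhausted = true; break; }
        }
        Candidate best = kept[cursor++];
        if (!best.ok || !R_finite(best.cost)) { exhausted = true; break; }
        VForest snapshot(*f);
        int id_s, id_new;
        commit_candidate(*f, st, best, &id_s, &id_new);
        f->assign_flows();
        f->update_radii(tol, max_iter, NA_REAL);
        std::vector<int> changed;
        changed.push_back(id_new);
        if (id_s >= 0) changed.push_back(id_s);
        for (int a = best.j; a >= 0; a = f->parent[a]) changed.push_back(a);
        // off-path radii drift as junction ratios shift: re-check every
        // vessel whose radius grew in this commit, so the nominal
        // constraints hold for the whole tree at all times
        for (int i = 0; i < f->n(); ++i)
          if (f->r[i] > f->r_chk[i] && i != best.j && i != id_new && i != id_s)
            changed.push_back(i);
        int why = 0, wa = -1, wb = -1;
        double info[6] = {0, 0, 0, 0, 0, 0};
        int n_clash = id_s >= 0 ? 2 : 1;
        bool okd = f->audit_delta(changed, n_clash, 1.0, &why, &wa, &wb, info);
        if (okd) {
          f->r_chk = f->r;
          new_ids.push_back(id_new + 1);
          if (id_s >= 0) new_ids.push_back(id_s + 1);
          connected = true;
        } else {
          if ((int)rb_wa.size() < 40) {
            rb_wa.push_back(wa + 1); rb_wb.push_back(wb + 1);
            rb_jv.push_back(best.j + 1); rb_new.push_back(id_new + 1);
            rb_vs.push_back(id_s + 1);
            for (int q = 0; q < 6; ++q) rb_info.push_back(info[q]);
          }
          if (why == 1) ++rb_aspect;
          else if (wa == id_new || wa == id_s || wb == id_new || wb == id_s)
            ++rb_clash_new;
          else ++rb_clash_old;
          *f = snapshot;
          ++grown_rej;
          excluded.push_back(best);
          if (excluded.size() > 24) exhausted = true;
        }
      }
      t_search += std::chrono::duration<double>(clk::now() - c1).count();
      if (connected) {
        ++committed;
        relax = 1.0;   // relaxation is a local escape hatch; reset on success
        fails = 0;
      } else {
        ++conn_rej;
        failed = true;
      }
    }
    if (failed && ++fails % st.n_fail == 0) {
      relax *= st.f_r;
      ++relaxations;
      relax_at.push_back(attempts);
    }
  }
  return List::create(
    _["terminals_added"] = committed, _["attempts"] = attempts,
    _["distance_rejections"] = dist_rej, _["connection_failures"] = conn_rej,
    _["growth_rollbacks"] = grown_rej,
    _["rollback_aspect"] = rb_aspect, _["rollback_clash_new"] = rb_clash_new,
    _["rollback_clash_old"] = rb_clash_old,
    _["rb_pairs"] = DataFrame::create(_["a"] = rb_wa, _["b"] = rb_wb,
                                      _["j"] = rb_jv, _["v_new"] = rb_new,
                                      _["v_s"] = rb_vs),
    _["rb_info"] = rb_info,
    _["relaxations"] = relaxations, _["relaxation_at_attempt"] = relax_at,
    _["t_sample"] = t_sample, _["t_search"] = t_search,
    _["t_update"] = t_update, _["t_audit"] = t_audit,
    _["final_relaxation"] = relax, _["new_vessels"] = new_ids);
}

// [[Rcpp::export]]
double vt_bench_eval(SEXP ptr, int j, NumericVector xb, NumericVector xt, int n) {
  XPtr<VForest> f(ptr);
  double acc = 0;
  for (int k = 0; k < n; ++k) {
    Candidate c = eval_candidate(*f, j - 1, as_vec3(xb), as_vec3(xt), false,
                                 f->gamma, 2, false);
    acc += c.dvol;
  }
  return acc;
}

// [[Rcpp::export]]
void vt_restore_state(SEXP ptr, IntegerVector id, NumericVector radius,
                      NumericVector flow) {
  XPtr<VForest> f(ptr);
  for (int k = 0; k < id.size(); ++k) {
    int i = id[k] - 1;
    if (i < 0 || i >= f->n()) stop("vessel %d not in forest", id[k]);
    if (R_finite(radius[k]) && radius[k] > 0) {
      f->r[i] = radius[k];
      if (radius[k] > 5.5e-4) f->eta[i] = fl_viscosity(radius[k]);
    }
    if (R_finite(flow[k])) f->q[i] = flow[k];
  }
}
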