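#include "vasc.h"

// The R-side descriptor is a list: type (string), D, params, bbox (lo, hi),
// and for mesh-backed shapes V (n x 3) and F (m x 3, 1-based from R).
Domain parse_domain(const Rcpp::List& d) {
  Domain out;
  std::string ty = Rcpp::as<std::string>(d["type"]);
  if (ty == "disc") out.type = 0;
  else if (ty == "annulus") out.type = 1;
  else if (ty == "sphere") out.type = 2;
  else if (ty == "shell") out.type = 3;
  else if (ty == "box") out.type = 4;
  else if (ty == "mesh") out.type = 5;
  else if (ty == "extruded_shell") out.type = 6;
  else if (ty == "union") out.type = 7;
  else Rcpp::stop("unknown domain type '%s'", ty.c_str());
  out.D = Rcpp::as<int>(d["D"]);
  if (d.containsElementNamed("params") && !Rf_isNull(d["params"]))
    out.par = Rcpp::as<std::vector<double> >(d["params"]);
  Rcpp::NumericVector lo = d["lo"], hi = d["hi"];
  for (int k = 0; k < 3; ++k) { out.lo[k] = lo[k]; out.hi[k] = hi[k]; }
  if (out.type == 5 || out.type == 6) {
    out.V = Rcpp::as<Rcpp::NumericMatrix>(d["V"]);
    Rcpp::IntegerMatrix F1 = Rcpp::as<Rcpp::IntegerMatrix>(d["F"]);
    Rcpp::IntegerMatrix F0(F1.nrow(), 3);
    for (int i = 0; i < F1.nrow(); ++i)
      for (int k = 0; k < 3; ++k) F0(i, k) = F1(i, k) - 1;
    out.F = F0;
  }
  if (out.type == 7) {
    Rcpp::List subs = d["subdomains"];
    for (int i = 0; i < subs.size(); ++i)
      out.subs.push_back(parse_domain(Rcpp::as<Rcpp::List>(subs[i])));
  }
  return out;
}

// parity ray cast along a fixed irrational direction (watertight meshes)
bool Domain::mesh_parity_inside(const Vec3& p) const {
  const Vec3 dir(0.57735026918962573, 0.52573111211913359, 0.62480994843655996);
  int crossings = 0;
  const double eps = 1e-12;
  for (int f = 0; f < F.nrow(); ++f) {
    Vec3 v0(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
    Vec3 v1(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
    Vec3 v2(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
    // Moller-Trumbore
    Vec3 e1 = v1 - v0, e2 = v2 - v0;
    Vec3 h = cross(dir, e2);
    double a = dot(e1, h);
    if (std::fabs(a) < eps) continue;
    double finv = 1.0 / a;
    Vec3 s = p - v0;
    double u = finv * dot(s, h);
    if (u < 0.0 || u > 1.0) continue;
    Vec3 qv = cross(s, e1);
    double v = finv * dot(dir, qv);
    if (v < 0.0 || u + v > 1.0) continue;
    double t = finv * dot(e2, qv);
    if (t > eps) ++crossings;
  }
  return (crossings % 2) == 1;
}

double Domain::mesh_distance(const Vec3& p) const {
  double best = std::numeric_limits<double>::infinity();
  for (int f = 0; f < F.nrow(); ++f) {
    Vec3 v0(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
    Vec3 v1(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
    Vec3 v2(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
    double d = point_triangle_distance(p, v0, v1, v2);
    if (d < best) best = d;
  }
  return best;
}

// closed regions: boundary points count as inside
bool Domain::inside(const Vec3& p) const {
  switch (type) {
  case 0: { // disc: cx cy radius (z = 0 plane; z ignored for membership)
    double dx = p.x - par[0], dy = p.y - par[1];
    return dx * dx + dy * dy <= par[2] * par[2];
  }
  case 1: { // annulus: cx cy r_inner r_outer
    double dx = p.x - par[0], dy = p.y - par[1];
    double d2 = dx * dx + dy * dy;
    return d2 >= par[2] * par[2] && d2 <= par[3] * par[3];
  }
  case 2: { // sphere: cx cy cz radius
    Vec3 c(par[0], par[1], par[2]);
    return dot(p - c, p - c) <= par[3] * par[3];
  }
  case 3: { // spherical shell: cx cy cz r_inner r_outer
    Vec3 c(par[0], par[1], par[2]);
    double d2 = dot(p - c, p - c);
    return d2 >= par[3] * par[3] && d2 <= par[4] * par[4];
  }
  case 4: // box: xlo ylo zlo xhi yhi zhi
    return p.x >= par[0] && p.y >= par[1] && p.z >= par[2] &&
           p.x <= par[3] && p.y <= par[4] && p.z <= par[5];
  case 5:
    return mesh_parity_inside(p);
  case 6: { // extruded shell around a surface: par = {d_in, d_out}
    double d = mesh_distance(p);
    if (mesh_parity_inside(p)) return d <= par[0];
    return d <= par[1];
  }
  case 7:
    for (size_t i = 0; i < subs.size(); ++i)
      if (subs[i].inside(p)) return true;
    return false;
  }
  return false;
}

// ---------------------------------------------------------------- density

Density parse_density(const Rcpp::List& d) {
  Density out;
  std::string ty = Rcpp::as<std::string>(d["type"]);
  if (ty == "uniform") out.type = 0;
  else if (ty == "gaussian") out.type = 1;
  else if (ty == "mixture") out.type = 2;
  else if (ty == "function") out.type = 3;
  else Rcpp::stop("unknown density type '%s'", ty.c_str());
  if (out.type == 1 || out.type == 2) {
    Rcpp::NumericMatrix mu = d["mean"], sd = d["sd"];
    Rcpp::NumericVector w = d["weights"];
    double acc = 0.0;
    for (int i = 0; i < mu.nrow(); ++i) {
      out.mu.push_back(Vec3(mu(i, 0), mu(i, 1), mu(i, 2)));
      out.sigma.push_back(Vec3(sd(i, 0), sd(i, 1), sd(i, 2)));
      acc += w[i];
      out.w.push_back(acc);
    }
    for (size_t i = 0; i < out.w.size(); ++i) out.w[i] /= acc;
  }
  if (out.type == 3) {
    out.fn = d["fn"];
    out.pmax = Rcpp::as<double>(d["pmax"]);
    if (!(out.pmax > 0)) Rcpp::stop("density upper bound pmax must be > 0");
  }
  return out;
}

Vec3 Density::sample(const Domain& dom, int max_attempts) const {
  for (int it = 0; it < max_attempts; ++it) {
    Vec3 p;
    if (type == 0) {
      p.x = dom.lo[0] + unif_rand() * (dom.hi[0] - dom.lo[0]);
      p.y = dom.lo[1] + unif_rand() * (dom.hi[1] - dom.lo[1]);
      p.z = dom.D == 2 ? 0.0 : dom.lo[2] + unif_rand() * (dom.hi[2] - dom.lo[2]);
    } else if (type == 1 || type == 2) {
      size_t k = 0;
      if (w.size() > 1) {
        double u = unif_rand();
        while (k + 1 < w.size() && u > w[k]) ++k;
      }
      p.x = mu[k].x + sigma[k].x * norm_rand();
      p.y = mu[k].y + sigma[k].y * norm_rand();
      p.z = dom.D == 2 ? 0.0 : mu[k].z + sigma[k].z * norm_rand();
    } else { // user density: bounded rejection against the bounding box
      p.x = dom.lo[0] + unif_rand() * (dom.hi[0] - dom.lo[0]);
      p.y = dom.lo[1] + unif_rand() * (dom.hi[1] - dom.lo[1]);
      p.z = dom.D == 2 ? 0.0 : dom.lo[2] + unif_rand() * (dom.hi[2] - dom.lo[2]);
      Rcpp::NumericVector xx = Rcpp::NumericVector::create(p.x, p.y, p.z);
      Rcpp::Function f(fn);
      double pv = Rcpp::as<double>(f(xx));
      if (pv < 0) Rcpp::stop("placement density returned a negative value");
      if (unif_rand() * pmax > pv) continue;
    }
    if (dom.inside(p)) return p;
  }
  Rcpp::stop("terminal sampling failed: acceptance rate below floor "
             "(degenerate density/domain pair?)");
}
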