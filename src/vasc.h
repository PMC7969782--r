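#ifndef VASCTREE_VASC_H
#define VASCTREE_VASC_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <functional>

// ---------------------------------------------------------------- geometry

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline double dist(const Vec3& a, const Vec3& b) { return norm(a - b); }
inline bool same_point(const Vec3& a, const Vec3& b) {
  return a.x == b.x && a.y == b.y && a.z == b.z;
}

// distance from point p to segment [a,b]; t_out gets the segment parameter
double point_segment_distance(const Vec3& p, const Vec3& a, const Vec3& b, double* t_out = 0);
// minimum distance between segments [a0,a1] and [b0,b1]
double segment_segment_distance(const Vec3& a0, const Vec3& a1, const Vec3& b0, const Vec3& b1,
                                double* s_out = 0, double* t_out = 0);
// distance from point to triangle (v0,v1,v2)
double point_triangle_distance(const Vec3& p, const Vec3& v0, const Vec3& v1, const Vec3& v2);

// ---------------------------------------------------------------- domain

// type codes: 0 disc, 1 annulus, 2 sphere, 3 shell, 4 box, 5 mesh,
//             6 extruded shell, 7 union
struct Domain {
  int type;
  int D;                      // spatial dimension (2 or 3)
  std::vector<double> par;    // shape parameters
  Rcpp::NumericMatrix V;      // mesh vertices (n x 3)
  Rcpp::IntegerMatrix F;      // mesh faces, 0-based (m x 3)
  std::vector<Domain> subs;   // union members
  double lo[3], hi[3];        // sampling bounding box

  bool inside(const Vec3& p) const;
  bool mesh_parity_inside(const Vec3& p) const;
  double mesh_distance(const Vec3& p) const;
};

Domain parse_domain(const Rcpp::List& d);

// ---------------------------------------------------------------- density

// type codes: 0 uniform, 1 gaussian, 2 gaussian mixture, 3 R function
struct Density {
  int type;
  std::vector<double> w;                  // mixture weights (cumulative)
  std::vector<Vec3> mu;
  std::vector<Vec3> sigma;
  double pmax;                            // bound for R-function rejection
  Rcpp::RObject fn;

  Density() : type(0), pmax(1.0) {}
  // draw one point inside dom; max_attempts guards degenerate pairs
  Vec3 sample(const Domain& dom, int max_attempts) const;
};

Density parse_density(const Rcpp::List& d);

// ---------------------------------------------------------------- hemodynamics

// Fahraeus-Lindqvist apparent viscosity in cP; r in mm, pole at 5.5e-4 mm
inline double fl_viscosity(double r) {
  if (!(r > 5.5e-4))
    Rcpp::stop("viscosity law undefined for radius <= 5.5e-4 mm (got %g)", r);
  double k = r / (r - 5.5e-4);
  k *= k;
  return 1.125 * (k + k * k * (6.0 * std::exp(-170.0 * r)
                               - 2.44 * std::exp(-8.09 * std::pow(r, 0.64)) + 2.2));
}

// Poiseuille resistance numerator: R * r^4, with eta in cP converted to Pa s
inline double res_const(double eta_cp, double l) {
  return 8.0 * (eta_cp * 1e-3) * l / M_PI;
}

// fast powers for the Murray exponent
struct GammaOps {
  double g;
  bool is3, is2;
  explicit GammaOps(double gamma) : g(gamma), is3(gamma == 3.0), is2(gamma == 2.0) {}
  double pg(double x) const {        // x^gamma
    if (is3) return x * x * x;
    if (is2) return x * x;
    return std::pow(x, g);
  }
  double p1g(double x) const {       // x^(1/gamma)
    if (is3) return std::cbrt(x);
    if (is2) return std::sqrt(x);
    return std::pow(x, 1.0 / g);
  }
  double p2g(double x) const {       // x^(2/gamma)
    if (is3) { double c = std::cbrt(x); return c * c; }
    if (is2) return x;
    return std::pow(x, 2.0 / g);
  }
  double p4g(double x) const {       // x^(4/gamma)
    if (is3) return x * std::cbrt(x);
    if (is2) return x * x;
    return std::pow(x, 4.0 / g);
  }
  // all three powers from a single root extraction (hot path)
  void powers(double x, double& p1, double& p2, double& p4) const {
    p1 = is3 ? std::cbrt(x) : (is2 ? std::sqrt(x) : std::pow(x, 1.0 / g));
    p2 = p1 * p1;
    p4 = p2 * p2;
  }
};

inline double fourth_root(double x) { return std::sqrt(std::sqrt(x)); }

// ---------------------------------------------------------------- forest

// roles: 0 distribution, 1 transport, 2 perforator
// behaviours: 0 non-branching, 1 distal, 2 fixed, 3 versatile
struct VForest {
  // per vessel
  std::vector<Vec3> xp, xd;
  std::vector<double> r, q, eta;
  std::vector<double> len;       // cached |xd - xp|
  std::vector<double> rc;        // cached resistance constant 8 eta l / pi
  std::vector<double> Rstar;     // reduced subtree resistance (units R * r^4)
  std::vector<double> Vstar;     // subtree volume factor: sum l (r_k / r_i)^2
  std::vector<double> tq;        // (q * Rstar)^(1/4)
  std::vector<double> tgam;      // tq^gamma
  std::vector<double> sumTgam;   // over children: sum tgam
  std::vector<double> sumW;      // over children: sum tq^2 * Vstar
  std::vector<double> sumQ;      // over children: sum q
  std::vector<int> parent, role, behaviour, stage, tree;
  std::vector<std::vector<int> > children;
  std::vector<char> is_outlet;
  std::vector<double> out_frac;  // fraction of total inflow for outlets
  std::vector<double> r_chk;     // radius at the last intersection re-check
  std::vector<double> rmax;      // largest radius attained (junction-region size)

  // per tree
  std::vector<int> root_idx;
  std::vector<double> root_r, root_q;

  double gamma;
  double qf;                     // current free-terminal outflow
  bool flows_valid;

  VForest() : gamma(3.0), qf(0.0), flows_valid(false) {}

  int n() const { return (int)xp.size(); }
  bool is_leaf(int i) const { return children[i].empty(); }

  int add_vessel(Vec3 p, Vec3 d, int par, int role_, int beh,
                 int stage_, double outfrac);
  int add_root(Vec3 p, Vec3 d, double r1, double Q,
               int role_, int beh, int stage_);

  void postorder(std::vector<int>& order) const;
  int n_terminals() const;
  int n_free_terminals() const;
  double total_inflow() const;
  int bif_level(int i) const;

  // hemodynamics
  double assign_flows();                           // returns qf
  Rcpp::List update_radii(double tol, int max_iter, double eta_const);
  void refresh_reduced(double eta_const);          // one bottom-up sweep at current radii
  double total_volume() const;

  // spatial queries (brute force over segments)
  double min_point_distance(const Vec3& x, Vec3* closest = 0) const;
  void neighbourhood(const Vec3& x, double radius, std::vector<int>& out) const;

  // true if segment [a,b] with radius rad clashes with a non-exempt vessel;
  // margin > 1 enforces a clearance buffer against later radius drift
  bool intersects_any(const Vec3& a, const Vec3& b, double rad,
                      const std::vector<int>& exempt,
                      double margin = 1.0) const;

  // arc length along the tree between the point at parameter s on edge a
  // and the point at parameter t on edge b (split-invariant)
  double arc_gap(int a, double s, int b, double t) const;
  // arc length from a point sitting on edge j's axis at distance lp from
  // its proximal node to the point at parameter t on edge b
  double arc_gap_from_axis(int j, double lp, int b, double t) const;
  // clash test for a trial terminal segment [xb, xt] attached to vessel j
  // at axis position l_p from the proximal node, using the arc-length
  // junction-region exemption
  bool new_vessel_clash(int j, const Vec3& xb, const Vec3& xt, double r_new,
                        double l_p, bool distal, double margin) const;
  // clash test for a sub-segment of vessel j's axis (axis offsets lp0..lp1)
  // carrying radius rad, as the split halves v_p and v_s will
  bool axis_clash(int j, double lp0, double lp1, double rad,
                  double margin) const;
  // Cylinder overlap between a segment [a0,a1] of radius ra and vessel b.
  // The whole violating parameter interval is examined, not only the
  // closest approach: an overlap is exempt (continuous lumen) only if the
  // tree-arc between the overlapping points stays within the
  // junction-region threshold 2*(thr_a + rmax_b) everywhere. arc_fn(s, t)
  // returns the arc between the point at parameter s on the segment and
  // the point at parameter t on b.
  bool overlap_clash(const Vec3& a0, const Vec3& a1, double ra, int b,
                     double margin, double thr_a,
                     const std::function<double(double, double)>& arc_fn) const;
  // audit-grade inter-penetration test for an existing vessel pair: a
  // proper axis crossing, or a deep overlap (axes within half the combined
  // radii) whose closest points are arc-far; rare-trigger and invariant
  // under splits and radius drift below the deep threshold
  bool audit_pair_deep(int a, int b) const;
  // Post-commit re-audit: the aspect bound for every vessel whose radius
  // grew, and the clash constraint (at the exact converged radii) for the
  // first n_clash entries of `changed` (the newly created vessels; old
  // pairs are protected by the clearance margins applied at creation).
  bool audit_delta(const std::vector<int>& changed, int n_clash,
                   double margin = 1.0, int* why = 0, int* who_a = 0,
                   int* who_b = 0, double* info = 0) const;
};

// ---------------------------------------------------------------- engine types

struct AngleParams {
  bool enabled;
  double theta_min, theta_max, phi_min, phi_max;  // degrees
  AngleParams() : enabled(false), theta_min(0), theta_max(180), phi_min(0), phi_max(180) {}
};

struct StagePars {
  Domain dom;
  double gamma;
  double delta_lo, delta_hi;   // symmetry bound below / at-or-above level threshold
  int delta_level;             // threshold (INT_MAX when constant)
  double nu, f_r, f_n;
  int delta_v, n_fail;
  double max_attempts;
  AngleParams ang;
  int cost;                    // 0 volume, 1 sprouting
  double c_v, c_p, c_d, Vref, lref;
  int role, behaviour;         // vessel type generated by this stage
  int label;
  double l_c;                  // characteristic length of dom
  std::vector<int> seed_stages; // empty = any stage eligible as parent
  Density dens;
  int search_iters;            // local fixed-point iterations during search
  double nchecks_frac;         // containment check spacing as fraction of l_c
};

StagePars parse_stage(const Rcpp::List& s);

struct Candidate {
  bool ok;
  int j;                // target vessel
  bool distal;          // attach at xd_j (no split)
  Vec3 xb, xt;
  double cost, dvol;
  double r_p, r_s, r_new;
  double Rstar_root, Vstar_root;  // patched root reductions (diagnostics)
  Candidate() : ok(false), j(-1), distal(false), cost(0), dvol(0),
                r_p(0), r_s(0), r_new(0), Rstar_root(0), Vstar_root(0) {}
};

// evaluate a trial connection without mutating the forest
Candidate eval_candidate(const VForest& fo, int j, const Vec3& xb, const Vec3& xt,
                         bool distal, double gamma, int iters, bool freeze_eta);

// full admissibility + cost; returns reason code (0 = admissible)
int gate_candidate(const VForest& fo, const StagePars& st, Candidate& c);

// fills `kept` (when given) with up to `topk` feasible candidates in
// ascending cost order and returns the best one
Candidate best_connection(const VForest& fo, const StagePars& st, const Vec3& xt,
                          const std::vector<Candidate>* excluded = 0,
                          std::vector<Candidate>* kept = 0, int topk = 1);

// commit a candidate; returns ids (vp, vs, vnew) with vs = -1 for distal attach
void commit_candidate(VForest& fo, const StagePars& st, const Candidate& c,
                      int* id_s, int* id_new);

void lattice_points(const Vec3& xt, const Vec3& xpj, const Vec3& xdj, int dv,
                    int behaviour, std::vector<Vec3>& out);

#endif
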