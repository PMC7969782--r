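#include "vasc.h"

double point_segment_distance(const Vec3& p, const Vec3& a, const Vec3& b, double* t_out) {
  Vec3 ab = b - a;
  double L2 = dot(ab, ab);
  double t = 0.0;
  if (L2 > 0.0) {
    t = dot(p - a, ab) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  if (t_out) *t_out = t;
  return dist(p, a + t * ab);
}

// Lumelsky-style clamped closest approach between two segments; s_out and
// t_out receive the parameters of the closest points
double segment_segment_distance(const Vec3& a0, const Vec3& a1,
                                const Vec3& b0, const Vec3& b1,
                                double* s_out, double* t_out) {
  Vec3 u = a1 - a0, v = b1 - b0, w = a0 - b0;
  double A = dot(u, u), B = dot(u, v), C = dot(v, v);
  double D = dot(u, w), E = dot(v, w);
  double den = A * C - B * B;
  double s, t;
  if (den <= 1e-14 * A * C || A == 0.0 || C == 0.0) {
    // near-parallel or degenerate: endpoint projections
    double t0, t1, s0, s1;
    double d0 = point_segment_distance(a0, b0, b1, &t0);
    double d1 = point_segment_distance(a1, b0, b1, &t1);
    double d2 = point_segment_distance(b0, a0, a1, &s0);
    double d3 = point_segment_distance(b1, a0, a1, &s1);
    double best = d0; s = 0.0; t = t0;
    if (d1 < best) { best = d1; s = 1.0; t = t1; }
    if (d2 < best) { best = d2; s = s0; t = 0.0; }
    if (d3 < best) { best = d3; s = s1; t = 1.0; }
    if (s_out) *s_out = s;
    if (t_out) *t_out = t;
    return best;
  }
  s = (B * E - C * D) / den;
  if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
  t = (B * s + E) / C;
  if (t < 0.0) {
    t = 0.0;
    s = -D / A; if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
  } else if (t > 1.0) {
    t = 1.0;
    s = (B - D) / A; if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
  }
  if (s_out) *s_out = s;
  if (t_out) *t_out = t;
  return dist(a0 + s * u, b0 + t * v);
}

double point_triangle_distance(const Vec3& p, const Vec3& v0, const Vec3& v1, const Vec3& v2) {
  // project onto the triangle plane, then clamp to edges if outside
  Vec3 e0 = v1 - v0, e1 = v2 - v0, n = cross(e0, e1);
  double nn = dot(n, n);
  if (nn < 1e-30) { // degenerate face: treat as segments
    double d = point_segment_distance(p, v0, v1);
    double d2 = point_segment_distance(p, v0, v2); if (d2 < d) d = d2;
    d2 = point_segment_distance(p, v1, v2); if (d2 < d) d = d2;
    return d;
  }
  Vec3 w = p - v0;
  double h = dot(w, n) / nn;
  Vec3 proj = p - h * n;
  // barycentric test
  Vec3 wp = proj - v0;
  double d00 = dot(e0, e0), d01 = dot(e0, e1), d11 = dot(e1, e1);
  double d20 = dot(wp, e0), d21 = dot(wp, e1);
  double den = d00 * d11 - d01 * d01;
  double b1 = (d11 * d20 - d01 * d21) / den;
  double b2 = (d00 * d21 - d01 * d20) / den;
  if (b1 >= 0.0 && b2 >= 0.0 && b1 + b2 <= 1.0) return std::fabs(h) * std::sqrt(nn);
  double d = point_segment_distance(p, v0, v1);
  double d2 = point_segment_distance(p, v0, v2); if (d2 < d) d = d2;
  d2 = point_segment_distance(p, v1, v2); if (d2 < d) d = d2;
  return d;
}
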