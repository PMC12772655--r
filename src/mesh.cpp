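// Iso-surface area and enclosed volume by marching tetrahedra.
// Each grid cell (8 voxel-centre corners) is split into six tetrahedra
// around the main diagonal; triangle orientation is fixed locally so the
// divergence-theorem volume is signed consistently outward.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
  return r;
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 lerp(const Vec3 &a, const Vec3 &b, double va, double vb,
                        double iso) {
  double t = (iso - va) / (vb - va);
  Vec3 r = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
            a.z + t * (b.z - a.z)};
  return r;
}

static void add_tri(const Vec3 &p0, const Vec3 &p1, const Vec3 &p2,
                    const Vec3 &ref_in, const Vec3 &ref_out, double &area,
                    double &vol6) {
  Vec3 e1 = sub(p1, p0), e2 = sub(p2, p0);
  Vec3 nrm = cross(e1, e2);
  double a2 = std::sqrt(dot(nrm, nrm));
  area += 0.5 * a2;
  // orient outward: normal should point from inside centroid to outside
  Vec3 dir = sub(ref_out, ref_in);
  Vec3 a = p0, b = p1, c = p2;
  if (dot(nrm, dir) < 0) {
    Vec3 tmp = b; b = c; c = tmp;
  }
  // signed volume contribution of triangle w.r.t. origin
  vol6 += dot(a, cross(b, c));
}

static void march_tet(const Vec3 p[4], const double v[4], double iso,
                      double &area, double &vol6) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = v[i] > iso;
    if (in[i]) ++nin;
  }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4];
  int a = 0, b = 0;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) ins[a++] = i; else outs[b++] = i;
  }
  Vec3 cin = {0, 0, 0}, cout = {0, 0, 0};
  for (int i = 0; i < a; ++i) {
    cin.x += p[ins[i]].x / a; cin.y += p[ins[i]].y / a; cin.z += p[ins[i]].z / a;
  }
  for (int i = 0; i < b; ++i) {
    cout.x += p[outs[i]].x / b; cout.y += p[outs[i]].y / b; cout.z += p[outs[i]].z / b;
  }
  if (nin == 1) {
    int A = ins[0];
    Vec3 q0 = lerp(p[A], p[outs[0]], v[A], v[outs[0]], iso);
    Vec3 q1 = lerp(p[A], p[outs[1]], v[A], v[outs[1]], iso);
    Vec3 q2 = lerp(p[A], p[outs[2]], v[A], v[outs[2]], iso);
    add_tri(q0, q1, q2, cin, cout, area, vol6);
  } else if (nin == 3) {
    int D = outs[0];
    Vec3 q0 = lerp(p[ins[0]], p[D], v[ins[0]], v[D], iso);
    Vec3 q1 = lerp(p[ins[1]], p[D], v[ins[1]], v[D], iso);
    Vec3 q2 = lerp(p[ins[2]], p[D], v[ins[2]], v[D], iso);
    add_tri(q0, q1, q2, cin, cout, area, vol6);
  } else { // nin == 2: quad split into two triangles
    int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
    Vec3 qAC = lerp(p[A], p[C], v[A], v[C], iso);
    Vec3 qAD = lerp(p[A], p[D], v[A], v[D], iso);
    Vec3 qBC = lerp(p[B], p[C], v[B], v[C], iso);
    Vec3 qBD = lerp(p[B], p[D], v[B], v[D], iso);
    add_tri(qAC, qAD, qBD, cin, cout, area, vol6);
    add_tri(qAC, qBD, qBC, cin, cout, area, vol6);
  }
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector f, IntegerVector dim,
                                   NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double area = 0.0, vol6 = 0.0;
  // six tetrahedra fanned around the main diagonal c0 - c7
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double v[8];
        Vec3 p[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          v[c] = f[cx + (R_xlen_t)nx * (cy + (R_xlen_t)ny * cz)];
          p[c].x = cx * dx; p[c].y = cy * dy; p[c].z = cz * dz;
          if (v[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          Vec3 tp[4];
          double tv[4];
          for (int i = 0; i < 4; ++i) {
            tp[i] = p[tets[t][i]];
            tv[i] = v[tets[t][i]];
          }
          march_tet(tp, tv, iso, area, vol6);
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}
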