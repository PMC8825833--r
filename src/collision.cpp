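// Rigid-body collision queries and RRT search over triangle meshes.
//
// Everything is in millimetres. The "environment" is a static triangle soup
// (all component meshes concatenated); the "robot" is a single mesh moved by
// a rigid pose (translation + unit quaternion). Collision is defined as any
// pair of triangles closer than a touch tolerance (default 1e-6 mm), plus a
// ray-parity containment check for the robot centroid, so that grazing
// contact between congruent surfaces counts as a collision.

#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- vectors

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { return {x, y, z}; }
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm2(V3 a) { return dot(a, a); }

struct Quat {
  double w, x, y, z;
};

static inline Quat qnormalize(Quat q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  return {q.w / n, q.x / n, q.y / n, q.z / n};
}

static inline Quat qmul(Quat a, Quat b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

// rotation matrix rows for a unit quaternion
struct Rot {
  double m[3][3];
};
static Rot qmatrix(Quat q) {
  Rot R;
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R.m[0][0] = 1 - 2 * (y * y + z * z);
  R.m[0][1] = 2 * (x * y - w * z);
  R.m[0][2] = 2 * (x * z + w * y);
  R.m[1][0] = 2 * (x * y + w * z);
  R.m[1][1] = 1 - 2 * (x * x + z * z);
  R.m[1][2] = 2 * (y * z - w * x);
  R.m[2][0] = 2 * (x * z - w * y);
  R.m[2][1] = 2 * (y * z + w * x);
  R.m[2][2] = 1 - 2 * (x * x + y * y);
  return R;
}
static inline V3 rapply(const Rot& R, V3 v) {
  return {R.m[0][0] * v.x + R.m[0][1] * v.y + R.m[0][2] * v.z,
          R.m[1][0] * v.x + R.m[1][1] * v.y + R.m[1][2] * v.z,
          R.m[2][0] * v.x + R.m[2][1] * v.y + R.m[2][2] * v.z};
}

static inline double qangle(Quat a, Quat b) {
  double d = std::fabs(a.w * b.w + a.x * b.x + a.y * b.y + a.z * b.z);
  if (d > 1.0) d = 1.0;
  return 2.0 * std::acos(d);
}

static Quat qslerp(Quat a, Quat b, double t) {
  double d = a.w * b.w + a.x * b.x + a.y * b.y + a.z * b.z;
  if (d < 0) {  // shortest arc
    b = {-b.w, -b.x, -b.y, -b.z};
    d = -d;
  }
  if (d > 0.9995) {  // nearly parallel: lerp
    Quat q = {a.w + t * (b.w - a.w), a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
              a.z + t * (b.z - a.z)};
    return qnormalize(q);
  }
  double th = std::acos(d);
  double s = std::sin(th);
  double wa = std::sin((1 - t) * th) / s, wb = std::sin(t * th) / s;
  return {wa * a.w + wb * b.w, wa * a.x + wb * b.x, wa * a.y + wb * b.y,
          wa * a.z + wb * b.z};
}

// ------------------------------------------------- primitive distance tests

// squared distance point -> triangle (Eberly's region decomposition)
static double pointTriDist2(V3 p, V3 a, V3 b, V3 c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return norm2(ap);
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return norm2(bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return norm2(ap - v * ab);
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return norm2(cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return norm2(ap - w * ac);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = b + w * (c - b);
    return norm2(p - q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = a + v * ab + w * ac;
  return norm2(p - q);
}

// squared distance segment -> segment
static double segSegDist2(V3 p1, V3 q1, V3 p2, V3 q2) {
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double A = norm2(d1), E = norm2(d2), F = dot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (A <= EPS && E <= EPS) return norm2(r);
  if (A <= EPS) {
    s = 0;
    t = std::min(1.0, std::max(0.0, F / E));
  } else {
    double C = dot(d1, r);
    if (E <= EPS) {
      t = 0;
      s = std::min(1.0, std::max(0.0, -C / A));
    } else {
      double B = dot(d1, d2);
      double den = A * E - B * B;
      s = (den > EPS) ? std::min(1.0, std::max(0.0, (B * F - C * E) / den)) : 0.0;
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
  V3 c1 = p1 + s * d1, c2 = p2 + t * d2;
  return norm2(c1 - c2);
}

// does segment p0-p1 pass through triangle interior? (Moller-Trumbore)
static bool segHitsTri(V3 p0, V3 p1, V3 a, V3 b, V3 c) {
  V3 dir = p1 - p0;
  V3 e1 = b - a, e2 = c - a;
  V3 pv = cross(dir, e2);
  double det = dot(e1, pv);
  if (std::fabs(det) < 1e-14) return false;  // parallel: edge tests cover it
  double inv = 1.0 / det;
  V3 tv = p0 - a;
  double u = dot(tv, pv) * inv;
  if (u < 0 || u > 1) return false;
  V3 qv = cross(tv, e1);
  double v = dot(dir, qv) * inv;
  if (v < 0 || u + v > 1) return false;
  double t = dot(e2, qv) * inv;
  return (t >= 0 && t <= 1);
}

static double segTriDist2(V3 p0, V3 p1, V3 a, V3 b, V3 c) {
  if (segHitsTri(p0, p1, a, b, c)) return 0.0;
  double d = std::min(pointTriDist2(p0, a, b, c), pointTriDist2(p1, a, b, c));
  d = std::min(d, segSegDist2(p0, p1, a, b));
  d = std::min(d, segSegDist2(p0, p1, b, c));
  d = std::min(d, segSegDist2(p0, p1, c, a));
  return d;
}

// cheap eps-separation certificate: if all vertices of B lie strictly on one
// side of A's supporting plane, further than eps, the triangles are separated
// by more than eps (distance to the triangle is at least distance to its
// plane, and the plane distance is linear over B)
static inline bool planeSeparated(const V3* A, const V3* B, double eps) {
  V3 n = cross(A[1] - A[0], A[2] - A[0]);
  double n2 = norm2(n);
  if (n2 < 1e-20) return false;
  double inv = 1.0 / std::sqrt(n2);
  double d0 = dot(n, B[0] - A[0]) * inv;
  double d1 = dot(n, B[1] - A[0]) * inv;
  double d2 = dot(n, B[2] - A[0]) * inv;
  if (d0 > eps && d1 > eps && d2 > eps) return true;
  if (d0 < -eps && d1 < -eps && d2 < -eps) return true;
  return false;
}

// separating-axis test with margin: projections are 1-Lipschitz, so an axis
// separating the projected intervals by more than eps certifies distance >
// eps. Face normals plus the nine edge-edge cross products cover all
// closest-feature directions for a pair of triangles.
static bool satSeparated(const V3* A, const V3* B, double eps) {
  V3 axes[11];
  int na = 0;
  axes[na++] = cross(A[1] - A[0], A[2] - A[0]);
  axes[na++] = cross(B[1] - B[0], B[2] - B[0]);
  V3 ea[3] = {A[1] - A[0], A[2] - A[1], A[0] - A[2]};
  V3 eb[3] = {B[1] - B[0], B[2] - B[1], B[0] - B[2]};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) axes[na++] = cross(ea[i], eb[j]);
  for (int a = 0; a < na; ++a) {
    double n2 = norm2(axes[a]);
    if (n2 < 1e-20) continue;
    double inv = 1.0 / std::sqrt(n2);
    double amin = 1e300, amax = -1e300, bmin = 1e300, bmax = -1e300;
    for (int k = 0; k < 3; ++k) {
      double pa = dot(axes[a], A[k]) * inv, pb = dot(axes[a], B[k]) * inv;
      amin = std::min(amin, pa); amax = std::max(amax, pa);
      bmin = std::min(bmin, pb); bmax = std::max(bmax, pb);
    }
    if (bmin - amax > eps || amin - bmax > eps) return true;
  }
  return false;
}

// squared distance triangle -> triangle; 0 iff intersecting or touching
static double triTriDist2(const V3* A, const V3* B) {
  double d = std::numeric_limits<double>::infinity();
  for (int i = 0; i < 3; ++i) {
    d = std::min(d, segTriDist2(A[i], A[(i + 1) % 3], B[0], B[1], B[2]));
    if (d == 0) return 0;
    d = std::min(d, segTriDist2(B[i], B[(i + 1) % 3], A[0], A[1], A[2]));
    if (d == 0) return 0;
  }
  return d;
}

// ---------------------------------------------------------------- AABB/BVH

struct AABB {
  V3 lo, hi;
  void init() {
    double inf = std::numeric_limits<double>::infinity();
    lo = v3(inf, inf, inf);
    hi = v3(-inf, -inf, -inf);
  }
  void grow(V3 p) {
    lo.x = std::min(lo.x, p.x);
    lo.y = std::min(lo.y, p.y);
    lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x);
    hi.y = std::max(hi.y, p.y);
    hi.z = std::max(hi.z, p.z);
  }
  void grow(const AABB& o) {
    grow(o.lo);
    grow(o.hi);
  }
};

static inline double aabbDist2(const AABB& a, const AABB& b) {
  double d = 0, t;
  t = std::max({a.lo.x - b.hi.x, b.lo.x - a.hi.x, 0.0});
  d += t * t;
  t = std::max({a.lo.y - b.hi.y, b.lo.y - a.hi.y, 0.0});
  d += t * t;
  t = std::max({a.lo.z - b.hi.z, b.lo.z - a.hi.z, 0.0});
  d += t * t;
  return d;
}

static inline double aabbPointDist2(const AABB& a, V3 p) {
  double d = 0, t;
  t = std::max({a.lo.x - p.x, p.x - a.hi.x, 0.0});
  d += t * t;
  t = std::max({a.lo.y - p.y, p.y - a.hi.y, 0.0});
  d += t * t;
  t = std::max({a.lo.z - p.z, p.z - a.hi.z, 0.0});
  d += t * t;
  return d;
}

struct Mesh {
  std::vector<V3> V;
  std::vector<int> F;  // 3 * ntri, 0-based
  int ntri() const { return (int)F.size() / 3; }
  void tri(int i, V3* out) const {
    out[0] = V[F[3 * i]];
    out[1] = V[F[3 * i + 1]];
    out[2] = V[F[3 * i + 2]];
  }
};

struct BVH {
  struct Node {
    AABB box;
    int left = -1, right = -1;  // children, or -1 for leaf
    int start = 0, count = 0;   // leaf triangle range in idx
  };
  std::vector<Node> nodes;
  std::vector<int> idx;

  void build(const Mesh& m) {
    int n = m.ntri();
    idx.resize(n);
    std::vector<AABB> boxes(n);
    std::vector<V3> cent(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = i;
      V3 t[3];
      m.tri(i, t);
      boxes[i].init();
      boxes[i].grow(t[0]);
      boxes[i].grow(t[1]);
      boxes[i].grow(t[2]);
      cent[i] = (1.0 / 3.0) * (t[0] + t[1] + t[2]);
    }
    nodes.clear();
    if (n > 0) buildRange(0, n, boxes, cent);
  }

 private:
  int buildRange(int start, int count, const std::vector<AABB>& boxes,
                 const std::vector<V3>& cent) {
    Node nd;
    nd.box.init();
    for (int i = start; i < start + count; ++i) nd.box.grow(boxes[idx[i]]);
    int me = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[me].start = start;
      nodes[me].count = count;
      return me;
    }
    AABB cb;
    cb.init();
    for (int i = start; i < start + count; ++i) cb.grow(cent[idx[i]]);
    V3 ext = cb.hi - cb.lo;
    int axis = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
    int mid = start + count / 2;
    auto key = [&](int t) {
      V3 c = cent[t];
      return axis == 0 ? c.x : (axis == 1 ? c.y : c.z);
    };
    std::nth_element(idx.begin() + start, idx.begin() + mid,
                     idx.begin() + start + count,
                     [&](int a, int b) { return key(a) < key(b); });
    int l = buildRange(start, mid - start, boxes, cent);
    int r = buildRange(mid, start + count - mid, boxes, cent);
    nodes[me].left = l;
    nodes[me].right = r;
    nodes[me].start = 0;
    nodes[me].count = 0;
    return me;
  }
};

// transform a local-frame AABB into a conservative world-frame AABB
static AABB transformAABB(const AABB& b, const Rot& R, V3 t) {
  V3 c = 0.5 * (b.lo + b.hi);
  V3 e = 0.5 * (b.hi - b.lo);
  V3 cw = rapply(R, c) + t;
  V3 ew = v3(std::fabs(R.m[0][0]) * e.x + std::fabs(R.m[0][1]) * e.y +
                 std::fabs(R.m[0][2]) * e.z,
             std::fabs(R.m[1][0]) * e.x + std::fabs(R.m[1][1]) * e.y +
                 std::fabs(R.m[1][2]) * e.z,
             std::fabs(R.m[2][0]) * e.x + std::fabs(R.m[2][1]) * e.y +
                 std::fabs(R.m[2][2]) * e.z);
  AABB o;
  o.lo = cw - ew;
  o.hi = cw + ew;
  return o;
}

// ------------------------------------------------------------------ world

struct World {
  Mesh env;
  BVH envB;
  Mesh rob;
  BVH robB;
  V3 robCentroid;  // volume centroid, robot local frame
  double eps;      // touch tolerance (mm)
  // per-query scratch: robot vertices/triangle boxes in world frame
  mutable std::vector<V3> robW;
  mutable std::vector<AABB> robTriBox;
  std::vector<AABB> envTriBox;  // env triangle boxes, built once

  void poseRobot(const Rot& R, V3 t) const {
    size_t nv = rob.V.size();
    robW.resize(nv);
    for (size_t i = 0; i < nv; ++i) robW[i] = rapply(R, rob.V[i]) + t;
    int nt = rob.ntri();
    robTriBox.resize(nt);
    for (int i = 0; i < nt; ++i) {
      AABB b;
      b.init();
      b.grow(robW[rob.F[3 * i]]);
      b.grow(robW[rob.F[3 * i + 1]]);
      b.grow(robW[rob.F[3 * i + 2]]);
      robTriBox[i] = b;
    }
  }
};

// volume centroid by signed tetrahedra about the origin
static void volumeCentroid(const Mesh& m, double* volOut, V3* cOut) {
  double vol = 0;
  V3 c = v3(0, 0, 0);
  for (int i = 0; i < m.ntri(); ++i) {
    V3 t[3];
    m.tri(i, t);
    double v = dot(t[0], cross(t[1], t[2])) / 6.0;
    vol += v;
    c = c + (v / 4.0) * (t[0] + t[1] + t[2]);
  }
  if (std::fabs(vol) > 1e-12) c = (1.0 / vol) * c;
  *volOut = vol;
  *cOut = c;
}

// surface proximity query: any env/robot triangle pair within eps?
// Robot vertices and per-triangle boxes are posed once per query (poseRobot);
// node boxes of the robot BVH are transformed conservatively on the fly.
static bool surfacesTouch(const World& w, const Rot& R, V3 t) {
  if (w.env.ntri() == 0 || w.rob.ntri() == 0) return false;
  double eps2 = w.eps * w.eps;
  w.poseRobot(R, t);
  std::vector<std::pair<int, int>> stack;
  stack.reserve(128);
  stack.push_back({0, 0});
  while (!stack.empty()) {
    auto pr = stack.back();
    stack.pop_back();
    const BVH::Node& ne = w.envB.nodes[pr.first];
    const BVH::Node& nr = w.robB.nodes[pr.second];
    AABB rw = transformAABB(nr.box, R, t);
    if (aabbDist2(ne.box, rw) > eps2) continue;
    bool eLeaf = ne.left < 0, rLeaf = nr.left < 0;
    if (eLeaf && rLeaf) {
      for (int j = nr.start; j < nr.start + nr.count; ++j) {
        int rj = w.robB.idx[j];
        V3 tr[3] = {w.robW[w.rob.F[3 * rj]], w.robW[w.rob.F[3 * rj + 1]],
                    w.robW[w.rob.F[3 * rj + 2]]};
        const AABB& trb = w.robTriBox[rj];
        for (int i = ne.start; i < ne.start + ne.count; ++i) {
          int ei = w.envB.idx[i];
          if (aabbDist2(w.envTriBox[ei], trb) > eps2) continue;
          V3 te[3];
          w.env.tri(ei, te);
          if (planeSeparated(te, tr, w.eps) || planeSeparated(tr, te, w.eps))
            continue;
          if (satSeparated(te, tr, w.eps)) continue;
          if (triTriDist2(te, tr) <= eps2) return true;
        }
      }
    } else if (!eLeaf && (rLeaf || ne.count == 0)) {
      stack.push_back({ne.left, pr.second});
      stack.push_back({ne.right, pr.second});
    } else {
      stack.push_back({pr.first, nr.left});
      stack.push_back({pr.first, nr.right});
    }
  }
  return false;
}

// ray-parity point containment (watertight mesh assumed)
static bool pointInMesh(const Mesh& m, const BVH& b, V3 p) {
  if (m.ntri() == 0) return false;
  // fixed slightly-skew direction to avoid grazing axis-aligned edges
  V3 d = v3(0.5685354, 0.5860920, 0.5772283);
  int hits = 0;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVH::Node& nd = b.nodes[ni];
    // slab test
    double t0 = 0, t1 = std::numeric_limits<double>::infinity();
    bool miss = false;
    const double* plo = &nd.box.lo.x;
    const double* phi = &nd.box.hi.x;
    const double* pp = &p.x;
    const double* pd = &d.x;
    for (int ax = 0; ax < 3; ++ax) {
      double inv = 1.0 / pd[ax];
      double ta = (plo[ax] - pp[ax]) * inv, tb = (phi[ax] - pp[ax]) * inv;
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1) {
        miss = true;
        break;
      }
    }
    if (miss) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        V3 t[3];
        m.tri(b.idx[i], t);
        V3 e1 = t[1] - t[0], e2 = t[2] - t[0];
        V3 pv = cross(d, e2);
        double det = dot(e1, pv);
        if (std::fabs(det) < 1e-14) continue;
        double inv = 1.0 / det;
        V3 tv = p - t[0];
        double u = dot(tv, pv) * inv;
        if (u < 0 || u > 1) continue;
        V3 qv = cross(tv, e1);
        double v = dot(d, qv) * inv;
        if (v < 0 || u + v > 1) continue;
        double tt = dot(e2, qv) * inv;
        if (tt > 1e-12) ++hits;
      }
    } else {
      stack.push_back(nd.left);
      stack.push_back(nd.right);
    }
  }
  return (hits % 2) == 1;
}

static bool collideAt(const World& w, V3 t, Quat q, bool containment = true) {
  Rot R = qmatrix(q);
  if (surfacesTouch(w, R, t)) return true;
  if (containment) {
    // robot fully buried inside the environment solid
    V3 cw = rapply(R, w.robCentroid) + t;
    if (pointInMesh(w.env, w.envB, cw)) return true;
  }
  return false;
}

// global minimum separation between env and robot surfaces
static double minSeparation(const World& w, const Rot& R, V3 t) {
  if (w.env.ntri() == 0 || w.rob.ntri() == 0)
    return std::numeric_limits<double>::infinity();
  typedef std::pair<double, std::pair<int, int>> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  double best = std::numeric_limits<double>::infinity();
  auto push = [&](int e, int r) {
    AABB rw = transformAABB(w.robB.nodes[r].box, R, t);
    double lb = aabbDist2(w.envB.nodes[e].box, rw);
    if (lb < best) pq.push({lb, {e, r}});
  };
  push(0, 0);
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    if (top.first >= best) break;
    const BVH::Node& ne = w.envB.nodes[top.second.first];
    const BVH::Node& nr = w.robB.nodes[top.second.second];
    bool eLeaf = ne.left < 0, rLeaf = nr.left < 0;
    if (eLeaf && rLeaf) {
      for (int i = ne.start; i < ne.start + ne.count; ++i) {
        V3 te[3];
        w.env.tri(w.envB.idx[i], te);
        for (int j = nr.start; j < nr.start + nr.count; ++j) {
          V3 tr[3];
          w.rob.tri(w.robB.idx[j], tr);
          for (int k = 0; k < 3; ++k) tr[k] = rapply(R, tr[k]) + t;
          best = std::min(best, triTriDist2(te, tr));
          if (best == 0) return 0;
        }
      }
    } else if (eLeaf) {
      push(top.second.first, nr.left);
      push(top.second.first, nr.right);
    } else if (rLeaf) {
      push(ne.left, top.second.second);
      push(ne.right, top.second.second);
    } else {
      push(ne.left, nr.left);
      push(ne.left, nr.right);
      push(ne.right, nr.left);
      push(ne.right, nr.right);
    }
  }
  return std::sqrt(best);
}

static double pointMeshDist(const Mesh& m, const BVH& b, V3 p) {
  if (m.ntri() == 0) return std::numeric_limits<double>::infinity();
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  double best = std::numeric_limits<double>::infinity();
  pq.push({aabbPointDist2(b.nodes[0].box, p), 0});
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    if (top.first >= best) break;
    const BVH::Node& nd = b.nodes[top.second];
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        V3 t[3];
        m.tri(b.idx[i], t);
        best = std::min(best, pointTriDist2(p, t[0], t[1], t[2]));
      }
    } else {
      double dl = aabbPointDist2(b.nodes[nd.left].box, p);
      double dr = aabbPointDist2(b.nodes[nd.right].box, p);
      if (dl < best) pq.push({dl, nd.left});
      if (dr < best) pq.push({dr, nd.right});
    }
  }
  return std::sqrt(best);
}

// penetration-depth estimate: deepest buried vertex's distance to the other
// surface, taken over both robot-in-env and env-in-robot vertices
static double penetrationDepth(const World& w, V3 t, Quat q) {
  Rot R = qmatrix(q);
  Rot Rt;  // transpose = inverse rotation
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rt.m[i][j] = R.m[j][i];
  double depth = 0;
  for (const V3& v : w.rob.V) {
    V3 pw = rapply(R, v) + t;
    if (pointInMesh(w.env, w.envB, pw))
      depth = std::max(depth, pointMeshDist(w.env, w.envB, pw));
  }
  // robot AABB in world, to cheaply skip faraway env vertices
  AABB rb;
  rb.init();
  for (const V3& v : w.rob.V) rb.grow(rapply(R, v) + t);
  for (const V3& v : w.env.V) {
    if (v.x < rb.lo.x || v.x > rb.hi.x || v.y < rb.lo.y || v.y > rb.hi.y ||
        v.z < rb.lo.z || v.z > rb.hi.z)
      continue;
    V3 pl = rapply(Rt, v - t);  // into robot local frame
    if (pointInMesh(w.rob, w.robB, pl))
      depth = std::max(depth, pointMeshDist(w.rob, w.robB, pl));
  }
  return depth;
}

static bool motionValid(const World& w, V3 ta, Quat qa, V3 tb, Quat qb,
                        double res, double rotW) {
  double arc = std::sqrt(norm2(tb - ta)) + rotW * qangle(qa, qb);
  int n = std::max(1, (int)std::ceil(arc / res));
  for (int i = 0; i <= n; ++i) {
    double s = (double)i / n;
    V3 t = ta + s * (tb - ta);
    Quat q = qslerp(qa, qb, s);
    // full containment check at the endpoints; interior samples rely on
    // surface crossing (a solid thicker than the resolution cannot be
    // entered between samples without a detected surface intersection)
    if (collideAt(w, t, q, i == 0 || i == n)) return false;
  }
  return true;
}

// ------------------------------------------------------------------- RNG

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z ^= z >> 30;
    z *= 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 27;
    z *= 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return z;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static Quat randomQuat(Rng& rng, double maxTilt) {
  if (maxTilt >= M_PI - 1e-9) {  // Shoemake: uniform over SO(3)
    double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
    Quat q = {std::sqrt(u1) * std::cos(2 * M_PI * u3),
              std::sqrt(1 - u1) * std::sin(2 * M_PI * u2),
              std::sqrt(1 - u1) * std::cos(2 * M_PI * u2),
              std::sqrt(u1) * std::sin(2 * M_PI * u3)};
    return qnormalize(q);
  }
  // tilt-capped: free yaw about z, bounded tilt of the z axis
  double yaw = 2 * M_PI * rng.unif();
  double phi = 2 * M_PI * rng.unif();
  double ct = 1.0 - rng.unif() * (1.0 - std::cos(maxTilt));
  double th = std::acos(ct);
  Quat qyaw = {std::cos(yaw / 2), 0, 0, std::sin(yaw / 2)};
  Quat qtilt = {std::cos(th / 2), std::sin(th / 2) * std::cos(phi),
                std::sin(th / 2) * std::sin(phi), 0};
  return qnormalize(qmul(qyaw, qtilt));
}

// ------------------------------------------------------------- R bindings

static Mesh meshFromR(const NumericMatrix& V, const IntegerMatrix& F) {
  Mesh m;
  m.V.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.V[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  m.F.resize(3 * F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    m.F[3 * i] = F(i, 0) - 1;  // R is 1-based
    m.F[3 * i + 1] = F(i, 1) - 1;
    m.F[3 * i + 2] = F(i, 2) - 1;
  }
  return m;
}

static inline V3 vecFromR(const NumericVector& t) { return v3(t[0], t[1], t[2]); }
static inline Quat quatFromR(const NumericVector& q) {
  return qnormalize({q[0], q[1], q[2], q[3]});
}

// [[Rcpp::export]]
SEXP cpp_world_build(List env_meshes, NumericMatrix rob_v, IntegerMatrix rob_f,
                     double touch_eps) {
  World* w = new World();
  for (int k = 0; k < env_meshes.size(); ++k) {
    List m = env_meshes[k];
    NumericMatrix V = m["vertices"];
    IntegerMatrix F = m["faces"];
    int off = (int)w->env.V.size();
    for (int i = 0; i < V.nrow(); ++i)
      w->env.V.push_back(v3(V(i, 0), V(i, 1), V(i, 2)));
    for (int i = 0; i < F.nrow(); ++i) {
      w->env.F.push_back(F(i, 0) - 1 + off);
      w->env.F.push_back(F(i, 1) - 1 + off);
      w->env.F.push_back(F(i, 2) - 1 + off);
    }
  }
  w->rob = meshFromR(rob_v, rob_f);
  w->eps = touch_eps;
  w->envB.build(w->env);
  w->robB.build(w->rob);
  w->envTriBox.resize(w->env.ntri());
  for (int i = 0; i < w->env.ntri(); ++i) {
    V3 tv[3];
    w->env.tri(i, tv);
    AABB b;
    b.init();
    b.grow(tv[0]);
    b.grow(tv[1]);
    b.grow(tv[2]);
    w->envTriBox[i] = b;
  }
  double vol;
  volumeCentroid(w->rob, &vol, &w->robCentroid);
  XPtr<World> p(w, true);
  return p;
}

// [[Rcpp::export]]
bool cpp_world_ok(SEXP ptr) {
  return R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export]]
NumericVector cpp_world_centroid(SEXP ptr) {
  XPtr<World> w(ptr);
  return NumericVector::create(w->robCentroid.x, w->robCentroid.y,
                               w->robCentroid.z);
}

// [[Rcpp::export]]
bool cpp_collide(SEXP ptr, NumericVector t, NumericVector q) {
  XPtr<World> w(ptr);
  return collideAt(*w, vecFromR(t), quatFromR(q));
}

// [[Rcpp::export]]
bool cpp_motion_valid(SEXP ptr, NumericVector ta, NumericVector qa,
                      NumericVector tb, NumericVector qb, double res,
                      double rot_weight) {
  XPtr<World> w(ptr);
  return motionValid(*w, vecFromR(ta), quatFromR(qa), vecFromR(tb),
                     quatFromR(qb), res, rot_weight);
}

// [[Rcpp::export]]
double cpp_clearance(SEXP ptr, NumericVector t, NumericVector q) {
  XPtr<World> w(ptr);
  V3 tv = vecFromR(t);
  Quat qv = quatFromR(q);
  if (collideAt(*w, tv, qv)) {
    double pen = penetrationDepth(*w, tv, qv);
    return -pen;
  }
  Rot R = qmatrix(qv);
  return minSeparation(*w, R, tv);
}

// [[Rcpp::export]]
bool cpp_point_in_mesh(NumericMatrix V, IntegerMatrix F, NumericVector p) {
  Mesh m = meshFromR(V, F);
  BVH b;
  b.build(m);
  return pointInMesh(m, b, vecFromR(p));
}

// [[Rcpp::export]]
double cpp_mix_seed(double master, IntegerVector idx) {
  uint64_t h = (uint64_t)master;
  h = h * 0x9E3779B97f4A7C15ULL + 0x2545F4914F6CDD1DULL;
  for (int i = 0; i < idx.size(); ++i) {
    uint64_t v = (uint64_t)(int64_t)idx[i];
    h ^= v + 0x9E3779B97f4A7C15ULL + (h << 6) + (h >> 2);
    Rng r(h);
    h = r.next();
  }
  return (double)(h >> 11);  // 53 bits, exactly representable
}

static inline bool inBox(V3 p, V3 lo, V3 hi) {
  return p.x >= lo.x && p.x <= hi.x && p.y >= lo.y && p.y <= hi.y &&
         p.z >= lo.z && p.z <= hi.z;
}

// [[Rcpp::export]]
List cpp_rrt(SEXP ptr, NumericVector t0, NumericVector q0, NumericVector bb_lo,
             NumericVector bb_hi, NumericVector gl_lo, NumericVector gl_hi,
             List settings, double seed) {
  XPtr<World> w(ptr);
  double step = as<double>(settings["step_length"]);
  double res = as<double>(settings["collision_resolution"]);
  double rotW = as<double>(settings["rotation_weight"]);
  double goalBias = as<double>(settings["goal_bias"]);
  int maxIter = as<int>(settings["max_iterations"]);     // 0 = unbounded
  double maxSec = as<double>(settings["max_seconds"]);   // 0 = unbounded
  double maxTilt = as<double>(settings["max_tilt_rad"]);

  V3 blo = vecFromR(bb_lo), bhi = vecFromR(bb_hi);
  V3 glo = vecFromR(gl_lo), ghi = vecFromR(gl_hi);
  V3 start_t = vecFromR(t0);
  Quat start_q = quatFromR(q0);
  V3 c = w->robCentroid;

  auto t_begin = std::chrono::steady_clock::now();
  auto elapsed = [&]() {
    return std::chrono::duration<double>(std::chrono::steady_clock::now() -
                                         t_begin)
        .count();
  };

  auto result = [&](int status, const std::vector<int>& pathIdx,
                    const std::vector<V3>& T, const std::vector<Quat>& Q,
                    const std::vector<int>& parent, int samples) {
    NumericMatrix path(pathIdx.size(), 7);
    for (size_t i = 0; i < pathIdx.size(); ++i) {
      int k = pathIdx[i];
      path(i, 0) = T[k].x;
      path(i, 1) = T[k].y;
      path(i, 2) = T[k].z;
      path(i, 3) = Q[k].w;
      path(i, 4) = Q[k].x;
      path(i, 5) = Q[k].y;
      path(i, 6) = Q[k].z;
    }
    NumericMatrix nodes(T.size(), 7);
    for (size_t i = 0; i < T.size(); ++i) {
      nodes(i, 0) = T[i].x;
      nodes(i, 1) = T[i].y;
      nodes(i, 2) = T[i].z;
      nodes(i, 3) = Q[i].w;
      nodes(i, 4) = Q[i].x;
      nodes(i, 5) = Q[i].y;
      nodes(i, 6) = Q[i].z;
    }
    IntegerVector par(parent.size());
    for (size_t i = 0; i < parent.size(); ++i) par[i] = parent[i] + 1;  // 1-based, 0 = root
    return List::create(_["status"] = status, _["path"] = path,
                        _["nodes"] = nodes, _["parents"] = par,
                        _["samples_drawn"] = samples,
                        _["elapsed"] = elapsed());
  };

  std::vector<V3> T;
  std::vector<Quat> Q;
  std::vector<int> parent;

  if (collideAt(*w, start_t, start_q)) {
    return result(2, {}, T, Q, parent, 0);  // invalid start
  }
  T.push_back(start_t);
  Q.push_back(start_q);
  parent.push_back(-1);

  Rot R0 = qmatrix(start_q);
  V3 cw0 = rapply(R0, c) + start_t;
  if (inBox(cw0, glo, ghi)) {
    return result(0, {0}, T, Q, parent, 0);  // start already dislocated
  }

  Rng rng((uint64_t)seed);
  int iter = 0;
  while (true) {
    if (maxIter > 0 && iter >= maxIter) break;
    if (maxSec > 0 && (iter & 31) == 0 && elapsed() > maxSec) break;
    ++iter;

    // sample a pose: centroid position + orientation
    Quat qs = randomQuat(rng, maxTilt);
    bool goalSample = rng.unif() < goalBias;
    V3 lo = goalSample ? glo : blo;
    V3 hi = goalSample ? ghi : bhi;
    V3 cs = v3(lo.x + rng.unif() * (hi.x - lo.x),
               lo.y + rng.unif() * (hi.y - lo.y),
               lo.z + rng.unif() * (hi.z - lo.z));
    Rot Rs = qmatrix(qs);
    V3 ts = cs - rapply(Rs, c);

    // nearest tree node under the weighted pose metric
    int ni = 0;
    double nd = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < T.size(); ++k) {
      double d = std::sqrt(norm2(ts - T[k])) + rotW * qangle(qs, Q[k]);
      if (d < nd) {
        nd = d;
        ni = (int)k;
      }
    }
    if (nd < 1e-12) continue;

    double alpha = std::min(1.0, step / nd);
    V3 tc = T[ni] + alpha * (ts - T[ni]);
    Quat qc = qslerp(Q[ni], qs, alpha);
    Rot Rc = qmatrix(qc);
    V3 cc = rapply(Rc, c) + tc;
    if (!inBox(cc, blo, bhi)) continue;
    if (!motionValid(*w, T[ni], Q[ni], tc, qc, res, rotW)) continue;

    T.push_back(tc);
    Q.push_back(qc);
    parent.push_back(ni);

    if (inBox(cc, glo, ghi)) {
      std::vector<int> path;
      int k = (int)T.size() - 1;
      while (k >= 0) {
        path.push_back(k);
        k = parent[k];
      }
      std::reverse(path.begin(), path.end());
      return result(0, path, T, Q, parent, iter);
    }
  }
  return result(1, {}, T, Q, parent, iter);  // budget exhausted
}
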