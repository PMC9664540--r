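// Isosurface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// decomposition of each grid cube. The decomposition is translation-
// compatible, so the mesh is watertight across cube faces. Triangles are
// oriented with normals pointing out of the region {value > level}, so the
// divergence-theorem volume is positive for a filled object.
#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// paths 0 -> a -> b -> 7 through the cube corner graph (bits: 1=x, 2=y, 4=z)
static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                               {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

static inline Vec3 interp(const Vec3 &pa, const Vec3 &pb, double va, double vb,
                          double level) {
  double t = (level - va) / (vb - va);
  return {pa.x + t * (pb.x - pa.x), pa.y + t * (pb.y - pa.y),
          pa.z + t * (pb.z - pa.z)};
}

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, int ny, int nx, int nz, double level,
                       double dy, double dx, double dz, double oy, double ox,
                       double oz) {
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;
  double area = 0.0, svol = 0.0;
  Vec3 cp[8];
  double cv[8];
  auto val = [&](int y, int x, int z) {
    return vol[y + (size_t)ny * (x + (size_t)nx * z)];
  };
  auto emit = [&](Vec3 q0, Vec3 q1, Vec3 q2, const Vec3 &inward) {
    // orient normal away from the inside point
    Vec3 nvec = cross(sub(q1, q0), sub(q2, q0));
    Vec3 cen = {(q0.x + q1.x + q2.x) / 3 - inward.x,
                (q0.y + q1.y + q2.y) / 3 - inward.y,
                (q0.z + q1.z + q2.z) / 3 - inward.z};
    if (dot(nvec, cen) < 0) {
      std::swap(q1, q2);
      nvec = cross(sub(q1, q0), sub(q2, q0));
    }
    double a2 = std::sqrt(dot(nvec, nvec));
    area += 0.5 * a2;
    svol += dot(q0, cross(q1, q2)) / 6.0;
    int base = (int)VX.size();
    VX.push_back(q0.x); VY.push_back(q0.y); VZ.push_back(q0.z);
    VX.push_back(q1.x); VY.push_back(q1.y); VZ.push_back(q1.z);
    VX.push_back(q2.x); VY.push_back(q2.y); VZ.push_back(q2.z);
    F.push_back(base + 1); F.push_back(base + 2); F.push_back(base + 3);
  };
  for (int z = 0; z + 1 < nz; ++z)
    for (int x = 0; x + 1 < nx; ++x)
      for (int y = 0; y + 1 < ny; ++y) {
        for (int b = 0; b < 8; ++b) {
          int xx = x + (b & 1), yy = y + ((b >> 1) & 1), zz = z + ((b >> 2) & 1);
          cv[b] = val(yy, xx, zz);
          cp[b] = {ox + xx * dx, oy + yy * dy, oz + zz * dz};
        }
        // quick reject
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; ++b) (cv[b] > level ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[T[k]] > level) in_idx[ni++] = T[k];
            else out_idx[no++] = T[k];
          }
          if (ni == 0 || ni == 4) continue;
          Vec3 inward = {0, 0, 0};
          for (int k = 0; k < ni; ++k) {
            inward.x += cp[in_idx[k]].x;
            inward.y += cp[in_idx[k]].y;
            inward.z += cp[in_idx[k]].z;
          }
          inward.x /= ni; inward.y /= ni; inward.z /= ni;
          if (ni == 1) {
            Vec3 q0 = interp(cp[in_idx[0]], cp[out_idx[0]], cv[in_idx[0]],
                             cv[out_idx[0]], level);
            Vec3 q1 = interp(cp[in_idx[0]], cp[out_idx[1]], cv[in_idx[0]],
                             cv[out_idx[1]], level);
            Vec3 q2 = interp(cp[in_idx[0]], cp[out_idx[2]], cv[in_idx[0]],
                             cv[out_idx[2]], level);
            emit(q0, q1, q2, inward);
          } else if (ni == 3) {
            Vec3 q0 = interp(cp[in_idx[0]], cp[out_idx[0]], cv[in_idx[0]],
                             cv[out_idx[0]], level);
            Vec3 q1 = interp(cp[in_idx[1]], cp[out_idx[0]], cv[in_idx[1]],
                             cv[out_idx[0]], level);
            Vec3 q2 = interp(cp[in_idx[2]], cp[out_idx[0]], cv[in_idx[2]],
                             cv[out_idx[0]], level);
            emit(q0, q1, q2, inward);
          } else {  // ni == 2: quad split into two triangles
            Vec3 q00 = interp(cp[in_idx[0]], cp[out_idx[0]], cv[in_idx[0]],
                              cv[out_idx[0]], level);
            Vec3 q01 = interp(cp[in_idx[0]], cp[out_idx[1]], cv[in_idx[0]],
                              cv[out_idx[1]], level);
            Vec3 q10 = interp(cp[in_idx[1]], cp[out_idx[0]], cv[in_idx[1]],
                              cv[out_idx[0]], level);
            Vec3 q11 = interp(cp[in_idx[1]], cp[out_idx[1]], cv[in_idx[1]],
                              cv[out_idx[1]], level);
            emit(q00, q01, q11, inward);
            emit(q00, q11, q10, inward);
          }
        }
      }
  int nv = (int)VX.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = VX[i];
    V(i, 1) = VY[i];
    V(i, 2) = VZ[i];
  }
  IntegerMatrix FM((int)F.size() / 3, 3);
  for (int i = 0; i < (int)F.size() / 3; ++i) {
    FM(i, 0) = F[3 * i];
    FM(i, 1) = F[3 * i + 1];
    FM(i, 2) = F[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = FM, _["area"] = area,
                      _["volume"] = svol);
}
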