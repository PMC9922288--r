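// Isosurface extraction (marching tetrahedra on the Kuhn cube subdivision)
// and 26-connected component labeling for binary voxel masks.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// value of the zero-padded mask at (possibly out-of-range) voxel index
static inline int mval(const int *m, int nx, int ny, int nz,
                       int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
  return m[i + (long)nx * (j + (long)ny * k)];
}

// [[Rcpp::export]]
List marching_tets_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *m = INTEGER(mask);
  // grid points run over the padded lattice [-1 .. n], id base dims n+2
  const int64_t bx = nx + 2, by = ny + 2;
  auto pid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)(i + 1) + bx * ((int64_t)(j + 1) + by * (int64_t)(k + 1));
  };
  const int64_t npts = bx * by * (int64_t)(nz + 2);

  // Kuhn subdivision: 6 tets per cube, each a corner-to-corner path
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

  std::map<int64_t, int> edge_vertex;   // key: a * npts + b (a < b)
  std::vector<double> vx, vy, vz;       // vertex coords in voxel-index space
  std::vector<int> f1, f2, f3;

  double P[4][3];  // tet corner coords
  int V[4];        // tet corner values
  int64_t ID[4];   // tet corner ids

  auto midpoint = [&](int a, int b) -> int {
    int64_t lo = ID[a] < ID[b] ? ID[a] : ID[b];
    int64_t hi = ID[a] < ID[b] ? ID[b] : ID[a];
    int64_t key = lo * npts + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    int idx = (int)vx.size();
    vx.push_back((P[a][0] + P[b][0]) / 2.0);
    vy.push_back((P[a][1] + P[b][1]) / 2.0);
    vz.push_back((P[a][2] + P[b][2]) / 2.0);
    edge_vertex[key] = idx;
    return idx;
  };

  // emit a triangle of edge midpoints, oriented so the normal points from
  // the inside corners toward the outside corners
  auto emit = [&](int e1a, int e1b, int e2a, int e2b, int e3a, int e3b,
                  double ox, double oy, double oz,   // out-centroid - in-centroid
                  bool flip_ok) {
    int a = midpoint(e1a, e1b), b = midpoint(e2a, e2b), c = midpoint(e3a, e3b);
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxn = uy * wz - uz * wy;
    double nyn = uz * wx - ux * wz;
    double nzn = ux * wy - uy * wx;
    if (nxn * ox + nyn * oy + nzn * oz < 0) { int t = b; b = c; c = t; }
    f1.push_back(a + 1); f2.push_back(b + 1); f3.push_back(c + 1);
    (void)flip_ok;
  };

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        // cube corner values; skip uniform cubes quickly
        int cv[8];
        int s = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = mval(m, nx, ny, nz, i + (c & 1), j + ((c >> 1) & 1),
                       k + ((c >> 2) & 1));
          s += cv[c];
        }
        if (s == 0 || s == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int ci = i, cj = j, ck = k;
          int corner[4][3] = {{ci, cj, ck}, {0,0,0}, {0,0,0}, {0,0,0}};
          for (int step = 0; step < 3; ++step) {
            corner[step + 1][0] = corner[step][0] + (perms[t][step] == 0);
            corner[step + 1][1] = corner[step][1] + (perms[t][step] == 1);
            corner[step + 1][2] = corner[step][2] + (perms[t][step] == 2);
          }
          int inside[4], n_in = 0;
          for (int c = 0; c < 4; ++c) {
            P[c][0] = corner[c][0]; P[c][1] = corner[c][1]; P[c][2] = corner[c][2];
            V[c] = mval(m, nx, ny, nz, corner[c][0], corner[c][1], corner[c][2]);
            ID[c] = pid(corner[c][0], corner[c][1], corner[c][2]);
            inside[c] = V[c];
            n_in += V[c];
          }
          if (n_in == 0 || n_in == 4) continue;
          // centroids of inside / outside corner subsets
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int d = 0; d < 3; ++d) {
              if (inside[c]) cin[d] += P[c][d] / n_in;
              else cout[d] += P[c][d] / (4 - n_in);
            }
          double ox = cout[0] - cin[0], oy = cout[1] - cin[1], oz = cout[2] - cin[2];
          if (n_in == 1 || n_in == 3) {
            int a = -1;
            for (int c = 0; c < 4; ++c)
              if ((n_in == 1 && inside[c]) || (n_in == 3 && !inside[c])) a = c;
            int o[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[no++] = c;
            emit(a, o[0], a, o[1], a, o[2], ox, oy, oz, true);
          } else {
            int in2[2], out2[2], ni = 0, nn = 0;
            for (int c = 0; c < 4; ++c) {
              if (inside[c]) in2[ni++] = c; else out2[nn++] = c;
            }
            // quad cycle: (a,c) (a,d) (b,d) (b,c) with a,b inside, c,d outside
            int a = in2[0], b = in2[1], c = out2[0], d = out2[1];
            emit(a, c, a, d, b, d, ox, oy, oz, true);
            emit(a, c, b, d, b, c, ox, oy, oz, true);
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int q = 0; q < nv; ++q) {
    verts(q, 0) = vx[q]; verts(q, 1) = vy[q]; verts(q, 2) = vz[q];
  }
  int nf = (int)f1.size();
  IntegerMatrix faces(nf, 3);
  for (int q = 0; q < nf; ++q) {
    faces(q, 0) = f1[q]; faces(q, 1) = f2[q]; faces(q, 2) = f3[q];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// [[Rcpp::export]]
IntegerVector largest_component_26_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const int *m = INTEGER(mask);
  std::vector<int> comp(n, 0);
  int best = 0;
  long best_size = 0;
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!m[s] || comp[s]) continue;
    ++cur;
    long size = 0;
    stack.push_back(s);
    comp[s] = cur;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      ++size;
      int i = p % nx, j = (p / nx) % ny, k = p / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long q = ii + (long)nx * (jj + (long)ny * kk);
            if (m[q] && !comp[q]) { comp[q] = cur; stack.push_back(q); }
          }
    }
    if (size > best_size) { best_size = size; best = cur; }
  }
  IntegerVector out(n);
  for (long s = 0; s < n; ++s) out[s] = (comp[s] == best) ? 1 : 0;
  return out;
}
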