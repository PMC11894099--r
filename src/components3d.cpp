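#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3D logical mask.
// mask: logical array with dim (z, y, x). Returns integer array of the same
// shape with provisional labels 1..K (renumbering/sorting is done in R).
// Two-pass union-find; memory O(n).

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;

  std::vector<int> parent;
  parent.push_back(0); // parent[0] unused

  // scan order follows R column-major layout: z fastest, then y, then x.
  // For each foreground voxel, look only at already-visited neighbours
  // (those with smaller linear index) among the 26-neighbourhood.
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[idx]) continue;
        int best = 0;
        for (int dx = -1; dx <= 0; ++dx) {
          int xx = x + dx;
          if (xx < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (nidx >= idx) continue;
              int lab = labels[nidx];
              if (lab == 0) continue;
              if (best == 0) {
                best = find_root(parent, lab);
              } else {
                unite(parent, best, lab);
                best = find_root(parent, best);
              }
            }
          }
        }
        if (best == 0) {
          int lab = (int)parent.size();
          parent.push_back(lab);
          labels[idx] = lab;
        } else {
          labels[idx] = best;
        }
      }
    }
  }

  // second pass: flatten to consecutive root labels
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int r = find_root(parent, (int)i);
    if (remap[r] == 0) remap[r] = ++k;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] > 0) labels[i] = remap[find_root(parent, labels[i])];
  }
  return labels;
}
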