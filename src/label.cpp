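// Spatiotemporal wave labelling and per-cell inter-wave intervals.
//
// Active lattice points are joined within a snapshot by 4- (or 8-)
// neighbourhood adjacency and across consecutive snapshots by same-cell
// overlap or spatial adjacency; every connected set is one wave.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

struct UF {
  std::vector<int> parent;
  int add() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int x, int y) {
    x = find(x); y = find(y);
    if (x != y) parent[y] = x;
  }
};

// mask: raw array nx*ny*nt (column-major, frame-contiguous).
// Returns a data.frame of active voxels: cell (1-based), frame (1-based),
// wave id (1-based, compacted), onset flag (no active predecessor in the
// previous frame among the same cell and its spatial neighbours).
// [[Rcpp::export]]
List cpp_label_waves(RawVector mask, int nx, int ny, int nt, bool eight) {
  const int ncell = nx * ny;
  UF uf;
  std::vector<int> prevComp(ncell, -1), curComp(ncell, -1);
  std::vector<int> voxCell, voxFrame, voxComp;
  std::vector<int> voxOnset;
  std::queue<int> bfs;

  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nnb = eight ? 8 : 4;
  const int* ddx = eight ? dx8 : dx4;
  const int* ddy = eight ? dy8 : dy4;

  for (int t = 0; t < nt; ++t) {
    R_xlen_t off = (R_xlen_t)t * ncell;
    std::fill(curComp.begin(), curComp.end(), -1);
    // spatial components within the frame
    for (int i = 0; i < ncell; ++i) {
      if (!mask[off + i] || curComp[i] >= 0) continue;
      int id = uf.add();
      curComp[i] = id;
      bfs.push(i);
      while (!bfs.empty()) {
        int c = bfs.front(); bfs.pop();
        int cx = c % nx, cy = c / nx;
        for (int q = 0; q < nnb; ++q) {
          int xx = cx + ddx[q], yy = cy + ddy[q];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
          int j = yy * nx + xx;
          if (mask[off + j] && curComp[j] < 0) {
            curComp[j] = id;
            bfs.push(j);
          }
        }
      }
    }
    // temporal links to previous frame + onset flags
    for (int i = 0; i < ncell; ++i) {
      if (!mask[off + i]) continue;
      bool pred = false;
      if (t > 0) {
        if (prevComp[i] >= 0) { uf.unite(curComp[i], prevComp[i]); pred = true; }
        int cx = i % nx, cy = i / nx;
        for (int q = 0; q < nnb; ++q) {
          int xx = cx + ddx[q], yy = cy + ddy[q];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
          int j = yy * nx + xx;
          if (prevComp[j] >= 0) { uf.unite(curComp[i], prevComp[j]); pred = true; }
        }
      }
      voxCell.push_back(i + 1);
      voxFrame.push_back(t + 1);
      voxComp.push_back(curComp[i]);
      voxOnset.push_back(pred ? 0 : 1);
    }
    std::swap(prevComp, curComp);
  }

  // compact wave ids
  std::vector<int> remap(uf.parent.size(), -1);
  int nwave = 0;
  IntegerVector wid(voxComp.size());
  for (size_t q = 0; q < voxComp.size(); ++q) {
    int root = uf.find(voxComp[q]);
    if (remap[root] < 0) remap[root] = nwave++;
    wid[q] = remap[root] + 1;
  }
  return List::create(
    _["cell"] = IntegerVector(voxCell.begin(), voxCell.end()),
    _["frame"] = IntegerVector(voxFrame.begin(), voxFrame.end()),
    _["wave"] = wid,
    _["onset"] = IntegerVector(voxOnset.begin(), voxOnset.end()),
    _["nWaves"] = nwave);
}

// Per-cell upward threshold crossings of the activity mask with a minimum
// interval: a crossing is accepted only if >= minIwi after the previously
// accepted crossing for that cell. Returns pooled intervals between accepted
// crossings plus the owning cell.
// [[Rcpp::export]]
List cpp_interwave_intervals(RawVector mask, int ncell, int nt,
                             NumericVector times, double minIwi) {
  std::vector<double> iwi;
  std::vector<int> cellv;
  for (int i = 0; i < ncell; ++i) {
    double last = R_NegInf;
    bool haveLast = false;
    Rbyte prev = 0;
    for (int t = 0; t < nt; ++t) {
      Rbyte cur = mask[(R_xlen_t)t * ncell + i];
      if (cur && !prev) {
        double tt = times[t];
        if (!haveLast || tt - last >= minIwi) {
          if (haveLast) {
            iwi.push_back(tt - last);
            cellv.push_back(i + 1);
          }
          last = tt;
          haveLast = true;
        }
      }
      prev = cur;
    }
  }
  return List::create(_["interval"] = NumericVector(iwi.begin(), iwi.end()),
                      _["cell"] = IntegerVector(cellv.begin(), cellv.end()));
}
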