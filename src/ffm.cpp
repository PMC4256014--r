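// Drossel-Schwabl forest-fire lattice model.
//
// Each site is empty (0), tree (1) or burning (2). Per discrete step:
//   1) occupied sites ignite spontaneously with probability f,
//   2) burning trees ignite occupied 4-neighbours,
//   3) burning trees become empty,
//   4) empty sites regrow with probability p.
// Two spread modes: per-step spread (one neighbour ring per step, finite
// front speed, matching the retinal analogy) and instantaneous cluster burn
// (classical DS-FFM event statistics). Fires that merge while spreading are
// pooled into one avalanche via union-find.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

struct UFf {
  std::vector<int> parent;
  int add() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int x, int y) { x = find(x); y = find(y); if (x != y) parent[y] = x; }
};

// Draw k distinct members of `set` (size m) by partial Fisher-Yates; chosen
// entries are swapped to the back so membership arrays stay consistent.
// [[Rcpp::export]]
List cpp_ffm_run(int side, double p, double f, int steps, bool instantaneous,
                 int burnin, bool trackDensity) {
  const int n = side * side;
  std::vector<int> state(n, 0);            // 0 empty, 1 tree, 2 burning
  std::vector<int> emptyList, treeList;    // dynamic site sets
  std::vector<int> pos(n);                 // position of site in its set
  emptyList.reserve(n); treeList.reserve(n);
  for (int i = 0; i < n; ++i) { emptyList.push_back(i); pos[i] = i; }

  auto removeFrom = [&pos](std::vector<int>& lst, int site) {
    int pp = pos[site];
    int last = lst.back();
    lst[pp] = last; pos[last] = pp;
    lst.pop_back();
  };
  auto addTo = [&pos](std::vector<int>& lst, int site) {
    pos[site] = (int)lst.size();
    lst.push_back(site);
  };

  const int dx[] = {1, -1, 0, 0}, dy[] = {0, 0, 1, -1};

  UFf uf;
  std::vector<int> fireId(n, -1);          // avalanche id of burning site
  std::vector<int> fireSizeAcc, fireStart, fireEnd;
  std::vector<int> outSize, outLife;
  std::vector<double> density;
  std::vector<int> burning, ignited;

  for (int step = 0; step < steps; ++step) {
    // 4) regrowth on empty sites
    int ne = (int)emptyList.size();
    if (ne > 0 && p > 0) {
      int k = (int)R::rbinom((double)ne, p);
      for (int q = 0; q < k; ++q) {
        int m = (int)emptyList.size();
        int j = (int)std::floor(unif_rand() * m);
        if (j >= m) j = m - 1;
        int site = emptyList[j];
        removeFrom(emptyList, site);
        addTo(treeList, site);
        state[site] = 1;
      }
    }
    // 1) lightning on trees
    int ntr = (int)treeList.size();
    if (ntr > 0 && f > 0) {
      int k = (int)R::rbinom((double)ntr, f);
      for (int q = 0; q < k; ++q) {
        int m = (int)treeList.size();
        if (m == 0) break;
        int j = (int)std::floor(unif_rand() * m);
        if (j >= m) j = m - 1;
        int site = treeList[j];
        removeFrom(treeList, site);
        if (instantaneous) {
          // burn whole connected cluster at once
          int sz = 0;
          std::queue<int> bfs;
          state[site] = 0; addTo(emptyList, site); ++sz;
          bfs.push(site);
          while (!bfs.empty()) {
            int c = bfs.front(); bfs.pop();
            int cx = c % side, cy = c / side;
            for (int d = 0; d < 4; ++d) {
              int xx = cx + dx[d], yy = cy + dy[d];
              if (xx < 0 || xx >= side || yy < 0 || yy >= side) continue;
              int nb = yy * side + xx;
              if (state[nb] == 1) {
                state[nb] = 0;
                removeFrom(treeList, nb);
                addTo(emptyList, nb);
                ++sz;
                bfs.push(nb);
              }
            }
          }
          if (step >= burnin) { outSize.push_back(sz); outLife.push_back(1); }
        } else {
          state[site] = 2;
          int id = uf.add();
          fireId[site] = id;
          fireSizeAcc.push_back(1);
          fireStart.push_back(step);
          fireEnd.push_back(step);
          burning.push_back(site);
        }
      }
    }
    if (!instantaneous && !burning.empty()) {
      // 2) spread one ring; merging fronts unite
      ignited.clear();
      for (int c : burning) {
        int cx = c % side, cy = c / side;
        for (int d = 0; d < 4; ++d) {
          int xx = cx + dx[d], yy = cy + dy[d];
          if (xx < 0 || xx >= side || yy < 0 || yy >= side) continue;
          int nb = yy * side + xx;
          if (state[nb] == 1) {
            state[nb] = 2;
            removeFrom(treeList, nb);
            fireId[nb] = fireId[c];
            int root = uf.find(fireId[c]);
            fireSizeAcc[root] += 1;
            fireEnd[root] = step + 1;
            ignited.push_back(nb);
          } else if (state[nb] == 2 && fireId[nb] >= 0 && fireId[c] >= 0) {
            int ra = uf.find(fireId[nb]), rb = uf.find(fireId[c]);
            if (ra != rb) {
              uf.unite(ra, rb);
              int root = uf.find(ra);
              int other = (root == ra) ? rb : ra;
              fireSizeAcc[root] += fireSizeAcc[other];
              if (fireStart[other] < fireStart[root]) fireStart[root] = fireStart[other];
              if (fireEnd[other] > fireEnd[root]) fireEnd[root] = fireEnd[other];
            }
          }
        }
      }
      // 3) burning -> empty
      for (int c : burning) {
        state[c] = 0;
        addTo(emptyList, c);
      }
      std::vector<int> still;
      still.reserve(ignited.size());
      for (int c : ignited) still.push_back(c);
      // a fire with no freshly ignited members is finished
      // (resolved after swap: finished roots flushed below)
      std::swap(burning, still);
      // flush finished fires: roots not represented among burning sites
      if (true) {
        std::vector<char> alive(uf.parent.size(), 0);
        for (int c : burning) alive[uf.find(fireId[c])] = 1;
        for (size_t id = 0; id < uf.parent.size(); ++id) {
          if ((int)uf.parent[id] == (int)id && !alive[id] && fireSizeAcc[id] > 0) {
            if (fireStart[id] >= burnin) {
              outSize.push_back(fireSizeAcc[id]);
              outLife.push_back(fireEnd[id] - fireStart[id] + 1);
            }
            fireSizeAcc[id] = 0;
          }
        }
      }
      for (int c : ignited) (void)c;
    }
    if (trackDensity && step >= burnin)
      density.push_back((double)treeList.size() / n);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["size"] = IntegerVector(outSize.begin(), outSize.end()),
    _["lifetime"] = IntegerVector(outLife.begin(), outLife.end()),
    _["treeDensity"] = NumericVector(density.begin(), density.end()),
    _["finalState"] = IntegerVector(state.begin(), state.end()));
}
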