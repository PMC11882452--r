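// Maximum edge count over connected n-vertex subgraphs of the infinite
// honeycomb lattice: the normalizer of the network-density metric.
//
// Sites are indexed by axial cell coordinates (u, v) and a sublattice bit.
// A(u,v) is adjacent to B(u,v), B(u-1,v), B(u,v-1);
// B(u,v) is adjacent to A(u,v), A(u+1,v), A(u,v+1).
// With unit bond length, A(u,v) sits at u*t1 + v*t2 and B at that + (1,0),
// t1 = (3/2, sqrt(3)/2), t2 = (3/2, -sqrt(3)/2).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Lattice {
  int R;            // u, v in [-R, R]
  int side;         // 2R + 1
  std::vector<int> adj; // 3 neighbours per site, -1 outside
  std::vector<double> px, py;

  int id(int u, int v, int s) const {
    return ((v + R) * side + (u + R)) * 2 + s;
  }
  bool inside(int u, int v) const {
    return u >= -R && u <= R && v >= -R && v <= R;
  }

  explicit Lattice(int R_) : R(R_), side(2 * R_ + 1) {
    int nsite = side * side * 2;
    adj.assign(3 * nsite, -1);
    px.assign(nsite, 0.0);
    py.assign(nsite, 0.0);
    const double t1x = 1.5, t1y = std::sqrt(3.0) / 2.0;
    const double t2x = 1.5, t2y = -std::sqrt(3.0) / 2.0;
    for (int u = -R; u <= R; ++u) {
      for (int v = -R; v <= R; ++v) {
        int a = id(u, v, 0), b = id(u, v, 1);
        px[a] = u * t1x + v * t2x;       py[a] = u * t1y + v * t2y;
        px[b] = px[a] + 1.0;             py[b] = py[a];
        // A neighbours
        adj[3 * a + 0] = b;
        adj[3 * a + 1] = inside(u - 1, v) ? id(u - 1, v, 1) : -1;
        adj[3 * a + 2] = inside(u, v - 1) ? id(u, v - 1, 1) : -1;
        // B neighbours
        adj[3 * b + 0] = a;
        adj[3 * b + 1] = inside(u + 1, v) ? id(u + 1, v, 0) : -1;
        adj[3 * b + 2] = inside(u, v + 1) ? id(u, v + 1, 0) : -1;
      }
    }
  }
};

struct Enumerator {
  const Lattice& L;
  int nmax;
  std::vector<int> best;      // best[k-1] = max edges at size k
  std::vector<char> in_sub, seen;
  std::vector<int> sub;

  Enumerator(const Lattice& L_, int nmax_)
      : L(L_), nmax(nmax_), best(nmax_, 0),
        in_sub(L_.px.size(), 0), seen(L_.px.size(), 0) {}

  // Enumerate every connected subgraph containing the root exactly once:
  // at each level walk the extension list left to right; element i is added
  // with the extension being the tail plus its unseen neighbours, then
  // retired for all deeper branches of this level.
  void rec(std::vector<int>& ext, size_t from, int edges) {
    int k = (int)sub.size();
    if (edges > best[k - 1]) best[k - 1] = edges;
    if (k == nmax) return;
    for (size_t i = from; i < ext.size(); ++i) {
      int v = ext[i];
      int de = 0;
      for (int q = 0; q < 3; ++q) {
        int w = L.adj[3 * v + q];
        if (w >= 0 && in_sub[w]) ++de;
      }
      in_sub[v] = 1;
      sub.push_back(v);
      size_t old_size = ext.size();
      std::vector<int> added;
      for (int q = 0; q < 3; ++q) {
        int w = L.adj[3 * v + q];
        if (w >= 0 && !seen[w]) {
          seen[w] = 1;
          ext.push_back(w);
          added.push_back(w);
        }
      }
      rec(ext, i + 1, edges + de);
      for (size_t a = 0; a < added.size(); ++a) seen[added[a]] = 0;
      ext.resize(old_size);
      sub.pop_back();
      in_sub[v] = 0;
    }
  }

  void run(int root) {
    std::vector<int> ext;
    seen[root] = 1;
    in_sub[root] = 1;
    sub.push_back(root);
    for (int q = 0; q < 3; ++q) {
      int w = L.adj[3 * root + q];
      if (w >= 0) { seen[w] = 1; ext.push_back(w); }
    }
    rec(ext, 0, 0);
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector honeycomb_max_edges_exhaustive_cpp(int nmax) {
  if (nmax < 1) stop("nmax must be >= 1");
  if (nmax > 14) stop("exhaustive search supported only up to n = 14");
  // a connected subgraph of n vertices stays within graph distance n of the
  // root; R = nmax cells is generous
  Lattice L(nmax);
  Enumerator en(L, nmax);
  en.run(L.id(0, 0, 0)); // lattice is vertex-transitive: one root suffices
  return IntegerVector(en.best.begin(), en.best.end());
}

// Spiral construction: hexagon cells are laid down in spiral order around
// a seed cell (sorted by centre distance, then angle); within a cell the
// missing vertices are added one at a time, always the one closing the
// most bonds with the current cluster. Partial cells give the values for
// every intermediate vertex count. This reproduces the extremal compact
// polyhex fragments (validated against the exhaustive search on n <= 12).
// [[Rcpp::export]]
IntegerVector honeycomb_max_edges_spiral_cpp(int nmax) {
  if (nmax < 1) stop("nmax must be >= 1");
  int R = (int)std::ceil(std::sqrt((double)nmax)) + 4;
  Lattice L(R);
  int nsite = (int)L.px.size();
  const double t1x = 1.5, t1y = std::sqrt(3.0) / 2.0;
  const double t2x = 1.5, t2y = -std::sqrt(3.0) / 2.0;
  const double cx0 = 0.5, cy0 = std::sqrt(3.0) / 2.0; // seed-cell centre

  // cells (p, q) with all six vertices inside the lattice window
  struct Cell { int p, q; double d2, ang; };
  std::vector<Cell> cells;
  for (int p = -R + 1; p <= R - 1; ++p) {
    for (int q = -R + 2; q <= R - 1; ++q) {
      double ccx = cx0 + p * t1x + q * t2x;
      double ccy = cy0 + p * t1y + q * t2y;
      double dx = ccx - cx0, dy = ccy - cy0;
      cells.push_back({p, q, dx * dx + dy * dy, std::atan2(dy, dx)});
    }
  }
  std::sort(cells.begin(), cells.end(), [](const Cell& a, const Cell& b) {
    if (a.d2 != b.d2) return a.d2 < b.d2;
    return a.ang < b.ang;
  });

  std::vector<char> in_sub(nsite, 0);
  std::vector<int> deg_in(nsite, 0);
  IntegerVector best(nmax);
  int edges = 0, count = 0;

  for (const Cell& c : cells) {
    if (count >= nmax) break;
    int p = c.p, q = c.q;
    int verts[6] = {
      L.id(p, q, 0), L.id(p, q, 1), L.id(p + 1, q, 0),
      L.id(p + 1, q - 1, 1), L.id(p + 1, q - 1, 0), L.id(p, q - 1, 1)
    };
    bool more = true;
    while (more && count < nmax) {
      more = false;
      int pick = -1, pick_de = -1;
      for (int k = 0; k < 6; ++k) {
        int v = verts[k];
        if (in_sub[v]) continue;
        more = true;
        if (deg_in[v] > pick_de) { pick = v; pick_de = deg_in[v]; }
      }
      if (pick < 0) break;
      in_sub[pick] = 1;
      edges += pick_de;
      for (int t = 0; t < 3; ++t) {
        int w = L.adj[3 * pick + t];
        if (w >= 0) ++deg_in[w];
      }
      best[count] = edges;
      ++count;
    }
  }
  if (count < nmax) stop("spiral construction ran out of lattice sites");
  return best;
}
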