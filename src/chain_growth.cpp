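// Chain-growth beam search for fitting protein coordinates onto a lattice.
//
// Both strategies grow a self-avoiding lattice chain one residue at a time
// from the amino terminus, keeping the n_keep best partial models:
//  - dRMSD mode scores a partial model by the sum of squared deviations of
//    all pairwise distances from the target's, updated incrementally (a new
//    monomer adds only its distances to the already-placed monomers), and
//    collapses symmetry-equivalent partial models onto one canonical
//    representative per point-group orbit (dRMSD cannot distinguish them).
//  - cRMSD mode scores by the sum of squared coordinate deviations against
//    a rotated, anchored target; orientation matters, so no symmetry
//    filtering is applied.
//
// Point storage is interleaved: residue i occupies point 2i (backbone) and
// 2i+1 (side chain) in side-chain mode, point i in backbone mode.
// Scores are raw squared-deviation sums; normalisation to an RMSD happens
// at the R level.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <limits>
#include <map>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Entry {
  std::vector<int> nodes;  // 3 ints per point, interleaved order
  std::vector<int> key;    // canonical flattened form (tie-break order)
  double score = 0.0;
};

typedef std::vector<std::array<int, 9> > SymList;

inline bool occupied(const std::vector<int>& nodes, int x, int y, int z) {
  for (size_t j = 0; j < nodes.size(); j += 3) {
    if (nodes[j] == x && nodes[j + 1] == y && nodes[j + 2] == z) return true;
  }
  return false;
}

// canonical form: lexicographically smallest image over all point-group
// transforms, translated so the first backbone node sits at the origin;
// flattened backbone-then-side-chains.
void canonicalize(const std::vector<int>& nd, int nres, bool side,
                  const SymList& G, std::vector<int>& key,
                  std::vector<int>& out) {
  const int npts = side ? 2 * nres : nres;
  std::vector<int> tmp(3 * npts);
  key.clear();
  for (size_t gi = 0; gi < G.size(); ++gi) {
    const std::array<int, 9>& g = G[gi];
    const int bx = g[0] * nd[0] + g[1] * nd[1] + g[2] * nd[2];
    const int by = g[3] * nd[0] + g[4] * nd[1] + g[5] * nd[2];
    const int bz = g[6] * nd[0] + g[7] * nd[1] + g[8] * nd[2];
    int pos = 0;
    const int passes = side ? 2 : 1;
    for (int pass = 0; pass < passes; ++pass) {
      for (int r = 0; r < nres; ++r) {
        const int pi = side ? 2 * r + pass : r;
        const int* p = &nd[3 * pi];
        tmp[pos++] = g[0] * p[0] + g[1] * p[1] + g[2] * p[2] - bx;
        tmp[pos++] = g[3] * p[0] + g[4] * p[1] + g[5] * p[2] - by;
        tmp[pos++] = g[6] * p[0] + g[7] * p[1] + g[8] * p[2] - bz;
      }
    }
    if (key.empty() || tmp < key) key = tmp;
  }
  out.resize(3 * npts);
  if (!side) {
    out = key;
  } else {
    for (int r = 0; r < nres; ++r) {
      for (int c = 0; c < 3; ++c) {
        out[3 * (2 * r) + c] = key[3 * r + c];
        out[3 * (2 * r + 1) + c] = key[3 * (nres + r) + c];
      }
    }
  }
}

// incremental dRMSD score term: squared deviations of the new point's
// distances (to every placed point) from the target's distances.
inline double drmsd_terms(const std::vector<int>& nodes, int nplaced,
                          int nx, int ny, int nz, double unit,
                          const NumericMatrix& targetD, int pidx) {
  double s = 0.0;
  for (int j = 0; j < nplaced; ++j) {
    const int dx = nodes[3 * j] - nx;
    const int dy = nodes[3 * j + 1] - ny;
    const int dz = nodes[3 * j + 2] - nz;
    const double d = unit * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
    const double dd = d - targetD(pidx, j);
    s += dd * dd;
  }
  return s;
}

inline double crmsd_term(int nx, int ny, int nz, double unit,
                         const NumericMatrix& target, int pidx) {
  const double dx = unit * nx - target(pidx, 0);
  const double dy = unit * ny - target(pidx, 1);
  const double dz = unit * nz - target(pidx, 2);
  return dx * dx + dy * dy + dz * dz;
}

struct ChildPool {
  // dedup map: canonical key -> best entry; plus a bound on the n_keep-th
  // best inserted score so hopeless children are dropped early.
  std::map<std::vector<int>, Entry> pool;
  std::priority_queue<double> topk;
  size_t n_keep;
  explicit ChildPool(size_t k) : n_keep(k) {}

  double bound() const {
    if (topk.size() < n_keep) return std::numeric_limits<double>::infinity();
    return topk.top() + 1e-9 * (1.0 + std::fabs(topk.top()));
  }

  void add(Entry&& e) {
    std::map<std::vector<int>, Entry>::iterator it = pool.find(e.key);
    if (it == pool.end()) {
      topk.push(e.score);
      if (topk.size() > n_keep) topk.pop();
      pool.insert(std::make_pair(e.key, std::move(e)));
    } else if (e.score < it->second.score) {
      it->second = std::move(e);
    }
  }

  std::vector<Entry> best() {
    std::vector<Entry> out;
    out.reserve(pool.size());
    for (std::map<std::vector<int>, Entry>::iterator it = pool.begin();
         it != pool.end(); ++it)
      out.push_back(std::move(it->second));
    std::sort(out.begin(), out.end(), [](const Entry& a, const Entry& b) {
      if (a.score != b.score) return a.score < b.score;
      return a.key < b.key;
    });
    if (out.size() > n_keep) out.resize(n_keep);
    return out;
  }
};

SymList as_symlist(const List& symmats) {
  SymList G;
  for (int i = 0; i < symmats.size(); ++i) {
    IntegerMatrix g = symmats[i];
    std::array<int, 9> a;
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) a[3 * r + c] = g(r, c);
    G.push_back(a);
  }
  return G;
}

List make_result(const Entry& e, int l, bool side, bool ok, int failed_at) {
  const int npts = side ? 2 * l : l;
  IntegerMatrix nodes(npts, 3);
  if (ok) {
    for (int p = 0; p < npts; ++p)
      for (int c = 0; c < 3; ++c) nodes(p, c) = e.nodes[3 * p + c];
  }
  return List::create(Named("ok") = ok, Named("failed_at") = failed_at,
                      Named("nodes") = nodes, Named("score") = e.score);
}

}  // namespace

// [[Rcpp::export(name = ".cg_fit_drmsd")]]
List cg_fit_drmsd(NumericMatrix targetD, int l, bool side,
                  IntegerMatrix neighbors, double unit, List symmats,
                  int n_keep) {
  if (n_keep < 1) stop("n_keep must be >= 1");
  const SymList G = as_symlist(symmats);
  const int k = neighbors.nrow();
  const double bond =
      unit * std::sqrt((double)(neighbors(0, 0) * neighbors(0, 0) +
                                neighbors(0, 1) * neighbors(0, 1) +
                                neighbors(0, 2) * neighbors(0, 2)));

  // seed: first backbone monomer at the origin; in side-chain mode the first
  // side-chain monomer on one canonical adjacent node (the point group acts
  // transitively on the neighbourhood, so the choice is a single orbit).
  Entry seed;
  if (side) {
    seed.nodes.assign(6, 0);
    seed.nodes[3] = neighbors(0, 0);
    seed.nodes[4] = neighbors(0, 1);
    seed.nodes[5] = neighbors(0, 2);
    const double dd = bond - targetD(0, 1);
    seed.score = dd * dd;
  } else {
    seed.nodes.assign(3, 0);
    seed.score = 0.0;
  }
  {
    std::vector<int> cnodes;
    canonicalize(seed.nodes, 1, side, G, seed.key, cnodes);
    seed.nodes = cnodes;
  }

  std::vector<Entry> beam;
  beam.push_back(seed);

  for (int i = 1; i < l; ++i) {
    ChildPool pool((size_t)n_keep);
    const int bb_pt = side ? 2 * i : i;  // point index of the new backbone node
    for (size_t e = 0; e < beam.size(); ++e) {
      const Entry& ent = beam[e];
      const int last = side ? 2 * (i - 1) : (i - 1);
      const int lx = ent.nodes[3 * last], ly = ent.nodes[3 * last + 1],
                lz = ent.nodes[3 * last + 2];
      for (int v = 0; v < k; ++v) {
        const int nx = lx + neighbors(v, 0), ny = ly + neighbors(v, 1),
                  nz = lz + neighbors(v, 2);
        if (occupied(ent.nodes, nx, ny, nz)) continue;
        const double s1 =
            drmsd_terms(ent.nodes, bb_pt, nx, ny, nz, unit, targetD, bb_pt);
        if (!side) {
          const double sc = ent.score + s1;
          if (sc > pool.bound()) continue;
          Entry child;
          child.nodes = ent.nodes;
          child.nodes.push_back(nx);
          child.nodes.push_back(ny);
          child.nodes.push_back(nz);
          child.score = sc;
          std::vector<int> cnodes;
          canonicalize(child.nodes, i + 1, side, G, child.key, cnodes);
          child.nodes = cnodes;
          pool.add(std::move(child));
        } else {
          // place the side-chain monomer on every free adjacent node
          std::vector<int> base = ent.nodes;
          base.push_back(nx);
          base.push_back(ny);
          base.push_back(nz);
          for (int w = 0; w < k; ++w) {
            const int sx = nx + neighbors(w, 0), sy = ny + neighbors(w, 1),
                      sz = nz + neighbors(w, 2);
            if (occupied(base, sx, sy, sz)) continue;
            const double s2 = drmsd_terms(base, bb_pt + 1, sx, sy, sz, unit,
                                          targetD, bb_pt + 1);
            const double sc = ent.score + s1 + s2;
            if (sc > pool.bound()) continue;
            Entry child;
            child.nodes = base;
            child.nodes.push_back(sx);
            child.nodes.push_back(sy);
            child.nodes.push_back(sz);
            child.score = sc;
            std::vector<int> cnodes;
            canonicalize(child.nodes, i + 1, side, G, child.key, cnodes);
            child.nodes = cnodes;
            pool.add(std::move(child));
          }
        }
      }
    }
    beam = pool.best();
    if (beam.empty()) return make_result(Entry(), l, side, false, i + 1);
    Rcpp::checkUserInterrupt();
  }
  return make_result(beam.front(), l, side, true, -1);
}

// [[Rcpp::export(name = ".cg_fit_crmsd")]]
List cg_fit_crmsd(NumericMatrix target, int l, bool side,
                  IntegerMatrix neighbors, double unit, int n_keep) {
  if (n_keep < 1) stop("n_keep must be >= 1");
  const int k = neighbors.nrow();

  // seed: the target is pre-anchored with P_1^b at the origin, where the
  // first backbone monomer is placed; the first side-chain monomer goes to
  // the adjacent node closest to P_1^s.
  Entry seed;
  seed.nodes.assign(3, 0);
  seed.score = crmsd_term(0, 0, 0, unit, target, 0);
  if (side) {
    int bestv = 0;
    double bestd = std::numeric_limits<double>::infinity();
    for (int v = 0; v < k; ++v) {
      const double d =
          crmsd_term(neighbors(v, 0), neighbors(v, 1), neighbors(v, 2), unit,
                     target, 1);
      if (d < bestd) {
        bestd = d;
        bestv = v;
      }
    }
    seed.nodes.push_back(neighbors(bestv, 0));
    seed.nodes.push_back(neighbors(bestv, 1));
    seed.nodes.push_back(neighbors(bestv, 2));
    seed.score += bestd;
  }
  seed.key = seed.nodes;

  std::vector<Entry> beam;
  beam.push_back(seed);

  for (int i = 1; i < l; ++i) {
    ChildPool pool((size_t)n_keep);
    const int bb_pt = side ? 2 * i : i;
    for (size_t e = 0; e < beam.size(); ++e) {
      const Entry& ent = beam[e];
      const int last = side ? 2 * (i - 1) : (i - 1);
      const int lx = ent.nodes[3 * last], ly = ent.nodes[3 * last + 1],
                lz = ent.nodes[3 * last + 2];
      for (int v = 0; v < k; ++v) {
        const int nx = lx + neighbors(v, 0), ny = ly + neighbors(v, 1),
                  nz = lz + neighbors(v, 2);
        if (occupied(ent.nodes, nx, ny, nz)) continue;
        const double s1 = crmsd_term(nx, ny, nz, unit, target, bb_pt);
        if (!side) {
          const double sc = ent.score + s1;
          if (sc > pool.bound()) continue;
          Entry child;
          child.nodes = ent.nodes;
          child.nodes.push_back(nx);
          child.nodes.push_back(ny);
          child.nodes.push_back(nz);
          child.score = sc;
          child.key = child.nodes;
          pool.add(std::move(child));
        } else {
          std::vector<int> base = ent.nodes;
          base.push_back(nx);
          base.push_back(ny);
          base.push_back(nz);
          for (int w = 0; w < k; ++w) {
            const int sx = nx + neighbors(w, 0), sy = ny + neighbors(w, 1),
                      sz = nz + neighbors(w, 2);
            if (occupied(base, sx, sy, sz)) continue;
            const double s2 = crmsd_term(sx, sy, sz, unit, target, bb_pt + 1);
            const double sc = ent.score + s1 + s2;
            if (sc > pool.bound()) continue;
            Entry child;
            child.nodes = base;
            child.nodes.push_back(sx);
            child.nodes.push_back(sy);
            child.nodes.push_back(sz);
            child.score = sc;
            child.key = child.nodes;
            pool.add(std::move(child));
          }
        }
      }
    }
    beam = pool.best();
    if (beam.empty()) return make_result(Entry(), l, side, false, i + 1);
    Rcpp::checkUserInterrupt();
  }
  return make_result(beam.front(), l, side, true, -1);
}
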