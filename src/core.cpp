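#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Combinatorial kernels for benzenoid analysis. Everything here works on
// plain integer encodings handed over from R:
//   * dualist graphs as n x 6 matrices (ring x lattice direction -> ring id,
//     1-based, 0 = no neighbour),
//   * carbon graphs as bond lists (m x 2, 1-based atom ids) plus a 0/1
//     bipartition vector (benzenoid carbon graphs are bipartite).

// ---------------------------------------------------------------------------
// Canonical code of a direction-annotated dualist graph.
//
// Identity of a benzenoid is its connected dualist graph with each edge
// labelled by one of the 6 lattice directions, up to the 12 lattice
// symmetries (6 rotations x optional reflection) and translation.  The code
// is the lexicographic minimum, over all symmetries and all BFS start rings,
// of a BFS relabelling in which neighbours are discovered in direction order.

// [[Rcpp::export]]
String cpp_canonical_code(IntegerMatrix adj) {
  const int n = adj.nrow();
  std::string best;
  std::vector<int> tadj(n * 6), id(n), order(n);

  for (int ref = 0; ref < 2; ++ref) {
    for (int rot = 0; rot < 6; ++rot) {
      // transform edge directions: reflection d -> (6 - d) %% 6, then + rot
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 6; ++d) {
          int nd = ref ? (6 - d) % 6 : d;
          nd = (nd + rot) % 6;
          tadj[i * 6 + nd] = adj(i, d) - 1;  // -1 when absent
        }
      for (int start = 0; start < n; ++start) {
        std::fill(id.begin(), id.end(), -1);
        id[start] = 0; order[0] = start;
        int cnt = 1;
        for (int k = 0; k < cnt; ++k) {
          const int i = order[k];
          for (int d = 0; d < 6; ++d) {
            const int j = tadj[i * 6 + d];
            if (j >= 0 && id[j] < 0) { id[j] = cnt; order[cnt++] = j; }
          }
        }
        if (cnt < n) stop("dualist graph is disconnected");
        std::string code(6 * n, '.');
        for (int k = 0; k < n; ++k) {
          const int i = order[k];
          for (int d = 0; d < 6; ++d) {
            const int j = tadj[i * 6 + d];
            if (j >= 0) code[k * 6 + d] = (char)('A' + id[j]);
          }
        }
        if (best.empty() || code < best) best = code;
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Bipartite maximum matching (Kuhn's augmenting paths) on the carbon graph,
// restricted to atoms not flagged as removed.  Used both as a matchability
// test (perfect matching of the residual graph) and inside the Clar search.

static bool try_kuhn(int u, const std::vector<std::vector<int> > &nbr,
                     std::vector<int> &match, std::vector<char> &seen) {
  for (size_t t = 0; t < nbr[u].size(); ++t) {
    const int v = nbr[u][t];
    if (seen[v]) continue;
    seen[v] = 1;
    if (match[v] < 0 || try_kuhn(match[v], nbr, match, seen)) {
      match[v] = u; match[u] = v;
      return true;
    }
  }
  return false;
}

static bool matchable_impl(int n_atoms, const IntegerMatrix &bonds,
                           const IntegerVector &side,
                           const std::vector<char> &removed) {
  int nleft = 0, nright = 0;
  for (int i = 0; i < n_atoms; ++i) {
    if (removed[i]) continue;
    if (side[i] == 0) ++nleft; else ++nright;
  }
  if (nleft != nright) return false;
  std::vector<std::vector<int> > nbr(n_atoms);
  for (int e = 0; e < bonds.nrow(); ++e) {
    const int a = bonds(e, 0) - 1, b = bonds(e, 1) - 1;
    if (removed[a] || removed[b]) continue;
    if (side[a] == 0) nbr[a].push_back(b); else nbr[b].push_back(a);
  }
  std::vector<int> match(n_atoms, -1);
  std::vector<char> seen(n_atoms);
  int covered = 0;
  for (int u = 0; u < n_atoms; ++u) {
    if (removed[u] || side[u] != 0) continue;
    std::fill(seen.begin(), seen.end(), 0);
    if (try_kuhn(u, nbr, match, seen)) ++covered;
  }
  return covered == nleft;
}

// [[Rcpp::export]]
bool cpp_matchable(int n_atoms, IntegerMatrix bonds, IntegerVector side,
                   LogicalVector removed) {
  std::vector<char> rem(n_atoms, 0);
  for (int i = 0; i < n_atoms; ++i) if (removed[i]) rem[i] = 1;
  return matchable_impl(n_atoms, bonds, side, rem);
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration of perfect matchings (Kekule structures).
// Backtracking on the lowest-indexed uncovered atom; output is a list of
// 1-based bond-index vectors.  `limit` guards pathological inputs.

static void kekule_rec(int n_atoms,
                       const std::vector<std::vector<std::pair<int,int> > > &inc,
                       std::vector<char> &cov, std::vector<int> &cur,
                       std::vector<std::vector<int> > &out, int limit) {
  int u = -1;
  for (int i = 0; i < n_atoms; ++i) if (!cov[i]) { u = i; break; }
  if (u < 0) {
    if ((int)out.size() >= limit) stop("matching enumeration limit exceeded");
    out.push_back(cur);
    return;
  }
  for (size_t t = 0; t < inc[u].size(); ++t) {
    const int v = inc[u][t].first, e = inc[u][t].second;
    if (cov[v]) continue;
    cov[u] = cov[v] = 1; cur.push_back(e + 1);
    kekule_rec(n_atoms, inc, cov, cur, out, limit);
    cur.pop_back(); cov[u] = cov[v] = 0;
  }
}

// [[Rcpp::export]]
List cpp_enumerate_matchings(int n_atoms, IntegerMatrix bonds,
                             int limit = 1000000) {
  std::vector<std::vector<std::pair<int,int> > > inc(n_atoms);
  for (int e = 0; e < bonds.nrow(); ++e) {
    const int a = bonds(e, 0) - 1, b = bonds(e, 1) - 1;
    inc[a].push_back(std::make_pair(b, e));
    inc[b].push_back(std::make_pair(a, e));
  }
  std::vector<std::vector<int> > out;
  std::vector<char> cov(n_atoms, 0);
  std::vector<int> cur;
  if (n_atoms % 2 == 0)
    kekule_rec(n_atoms, inc, cov, cur, out, limit);
  List res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = wrap(out[i]);
  return res;
}

// ---------------------------------------------------------------------------
// Clar search: enumerate all feasible sextet-ring sets.
//
// A ring set S is feasible iff the rings are pairwise non-adjacent in the
// dualist (hence atom-disjoint) and the carbon graph minus their atoms has a
// perfect matching.  Feasibility is downward closed (a returned sextet ring
// can always be re-matched internally), so an infeasible partial set prunes
// its whole branch.  All feasible sets are collected; the maximum-cardinality
// ones are the Clar structures and their size is the Clar number.

struct ClarCtx {
  int n_rings, n_atoms;
  const IntegerMatrix *ring_atoms;   // n_rings x 6, 1-based atom ids
  const LogicalMatrix *ring_adj;     // dualist adjacency
  const IntegerMatrix *bonds;
  const IntegerVector *side;
  std::vector<char> removed;
  std::vector<int> chosen;
  std::vector<std::vector<int> > feasible;
};

static void clar_rec(ClarCtx &C, int start) {
  C.feasible.push_back(C.chosen);
  for (int r = start; r < C.n_rings; ++r) {
    bool indep = true;
    for (size_t k = 0; k < C.chosen.size() && indep; ++k)
      if ((*C.ring_adj)(C.chosen[k], r)) indep = false;
    if (!indep) continue;
    for (int t = 0; t < 6; ++t) C.removed[(*C.ring_atoms)(r, t) - 1] = 1;
    if (matchable_impl(C.n_atoms, *C.bonds, *C.side, C.removed)) {
      C.chosen.push_back(r);
      clar_rec(C, r + 1);
      C.chosen.pop_back();
    }
    for (int t = 0; t < 6; ++t) C.removed[(*C.ring_atoms)(r, t) - 1] = 0;
  }
}

// [[Rcpp::export]]
List cpp_clar_sets(IntegerMatrix ring_atoms, LogicalMatrix ring_adj,
                   int n_atoms, IntegerMatrix bonds, IntegerVector side) {
  ClarCtx C;
  C.n_rings = ring_atoms.nrow();
  C.n_atoms = n_atoms;
  C.ring_atoms = &ring_atoms;
  C.ring_adj = &ring_adj;
  C.bonds = &bonds;
  C.side = &side;
  C.removed.assign(n_atoms, 0);

  const bool kekulean =
      matchable_impl(n_atoms, bonds, side, C.removed);
  if (kekulean) clar_rec(C, 0);

  size_t maxsz = 0;
  for (size_t i = 0; i < C.feasible.size(); ++i)
    if (C.feasible[i].size() > maxsz) maxsz = C.feasible[i].size();
  std::vector<std::vector<int> > best;
  for (size_t i = 0; i < C.feasible.size(); ++i)
    if (C.feasible[i].size() == maxsz) best.push_back(C.feasible[i]);

  List sets(best.size());
  for (size_t i = 0; i < best.size(); ++i) {
    IntegerVector s(best[i].size());
    for (size_t k = 0; k < best[i].size(); ++k) s[k] = best[i][k] + 1;
    sets[i] = s;
  }
  return List::create(_["kekulean"] = kekulean,
                      _["clar_number"] = kekulean ? (int)maxsz : NA_INTEGER,
                      _["sets"] = sets);
}
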