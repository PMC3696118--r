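#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected double-edge swap: randomize topology while preserving the exact
// degree sequence, simplicity (no loops / multi-edges) and connectedness.
// A candidate swap (a-b, c-d) -> (a-d, c-b) is applied, then connectivity is
// verified; if the untouched edges a-c or b-d exist the four endpoints stay
// mutually connected and no global check is needed (only their incident
// edges changed). Otherwise it suffices to check that b is reachable from a
// in the swapped graph: the input was connected and only the edges a-b and
// c-d were removed, and a~b restores every broken a-b path while
// c-b + b~a + a-d restores every broken c-d path. The swap is reverted on
// failure.

static bool bfs_reaches(const IntegerMatrix &adj, int n, int from, int to) {
    std::vector<char> seen(n, 0);
    std::vector<int> queue;
    queue.reserve(n);
    queue.push_back(from);
    seen[from] = 1;
    for (size_t qi = 0; qi < queue.size(); ++qi) {
        int u = queue[qi];
        for (int v = 0; v < n; ++v) {
            if (adj(u, v) && !seen[v]) {
                if (v == to) return true;
                seen[v] = 1;
                queue.push_back(v);
            }
        }
    }
    return false;
}

// [[Rcpp::export]]
List rewire_connected_cpp(IntegerMatrix adjacency, int swaps_target,
                          int max_attempts) {
    IntegerMatrix adj = clone(adjacency);
    int n = adj.nrow();

    std::vector<int> eu, ev;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (adj(i, j)) { eu.push_back(i); ev.push_back(j); }
    int E = (int)eu.size();

    int accepted = 0, attempts = 0;
    if (E >= 2) {
        while (accepted < swaps_target && attempts < max_attempts) {
            ++attempts;
            int e1 = (int)(unif_rand() * E);
            int e2 = (int)(unif_rand() * E);
            if (e1 >= E) e1 = E - 1;
            if (e2 >= E) e2 = E - 1;
            if (e1 == e2) continue;
            int a = eu[e1], b = ev[e1], c = eu[e2], d = ev[e2];
            if (unif_rand() < 0.5) std::swap(a, b);
            if (unif_rand() < 0.5) std::swap(c, d);
            if (a == c || a == d || b == c || b == d) continue;
            if (adj(a, d) || adj(c, b)) continue;
            // apply swap
            adj(a, b) = adj(b, a) = 0;
            adj(c, d) = adj(d, c) = 0;
            adj(a, d) = adj(d, a) = 1;
            adj(c, b) = adj(b, c) = 1;
            bool ok = adj(a, c) || adj(b, d);
            if (!ok) ok = bfs_reaches(adj, n, a, b);
            if (!ok) {
                // revert
                adj(a, d) = adj(d, a) = 0;
                adj(c, b) = adj(b, c) = 0;
                adj(a, b) = adj(b, a) = 1;
                adj(c, d) = adj(d, c) = 1;
                continue;
            }
            eu[e1] = std::min(a, d); ev[e1] = std::max(a, d);
            eu[e2] = std::min(c, b); ev[e2] = std::max(c, b);
            ++accepted;
        }
    }
    return List::create(_["adjacency"] = adj,
                        _["accepted"] = accepted,
                        _["attempts"] = attempts);
}
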