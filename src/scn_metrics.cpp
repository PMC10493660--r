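#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Graph-metric kernels for binary undirected networks.
// Conventions used throughout the package:
//   - distances are unweighted hop counts; 1/infinity = 0 for efficiencies
//   - characteristic path length (lp) averages over *connected* node pairs
//   - local clustering c_i = 2 t_i / (k_i (k_i - 1)), 0 when k_i < 2;
//     Cp is the mean over all nodes
//   - local efficiency averages, over nodes, the global efficiency of the
//     subgraph induced by each node's neighbours (0 when k_i < 2)
//   - betweenness is unnormalized: sum over unordered pairs s<t (s,t != i)
//     of sigma_st(i)/sigma_st, disconnected pairs contributing 0
//
// Distance sweeps use level-synchronous BFS over bitset adjacency rows,
// which keeps permutation-loop recomputation cheap; betweenness uses
// Brandes accumulation over adjacency lists.

struct MetricsOut {
    double eglob, eloc, cp, lp;
    std::vector<double> nodal_eff, bc;
    std::vector<int> degree;
};

static inline int popcnt(uint64_t x) { return __builtin_popcountll(x); }

// BFS over the node subset `mask` (bitset of W words) from source s;
// accumulates sum of 1/dist and (optionally) dist sums over reached nodes.
static void bitset_bfs(const std::vector<uint64_t> &rows, int W, int s,
                       const uint64_t *mask,
                       std::vector<uint64_t> &visited,
                       std::vector<uint64_t> &frontier,
                       std::vector<uint64_t> &nxt,
                       double *inv_sum, double *dist_sum, long long *n_reached)
{
    for (int w = 0; w < W; ++w) visited[w] = frontier[w] = 0;
    visited[s >> 6] = frontier[s >> 6] = 1ULL << (s & 63);
    int level = 0;
    for (;;) {
        ++level;
        for (int w = 0; w < W; ++w) nxt[w] = 0;
        for (int w = 0; w < W; ++w) {
            uint64_t f = frontier[w];
            while (f) {
                int v = (w << 6) + __builtin_ctzll(f);
                f &= f - 1;
                const uint64_t *rv = &rows[(size_t) v * W];
                for (int w2 = 0; w2 < W; ++w2) nxt[w2] |= rv[w2];
            }
        }
        int cnt = 0;
        for (int w = 0; w < W; ++w) {
            nxt[w] &= ~visited[w];
            if (mask) nxt[w] &= mask[w];
            cnt += popcnt(nxt[w]);
        }
        if (cnt == 0) break;
        if (inv_sum) *inv_sum += (double) cnt / level;
        if (dist_sum) *dist_sum += (double) cnt * level;
        if (n_reached) *n_reached += cnt;
        for (int w = 0; w < W; ++w) {
            visited[w] |= nxt[w];
            std::swap(frontier[w], nxt[w]);
        }
    }
}

// single-word BFS (N <= 64): returns sum of 1/dist over reached nodes in
// mask, optionally accumulating dist sums/counts
static inline double word_bfs(const uint64_t *rows, int s, uint64_t mask,
                              double *dist_sum, long long *n_reached)
{
    uint64_t visited = 1ULL << s, frontier = visited;
    double inv = 0.0;
    int level = 0;
    for (;;) {
        ++level;
        uint64_t nxt = 0, f = frontier;
        while (f) {
            nxt |= rows[__builtin_ctzll(f)];
            f &= f - 1;
        }
        nxt &= mask & ~visited;
        if (!nxt) break;
        int cnt = popcnt(nxt);
        inv += (double) cnt / level;
        if (dist_sum) *dist_sum += (double) cnt * level;
        if (n_reached) *n_reached += cnt;
        visited |= nxt;
        frontier = nxt;
    }
    return inv;
}

static void compute_all(int N,
                        const std::vector< std::vector<int> > &adj,
                        const std::vector<uint64_t> &rows, int W,
                        bool need_spl, bool need_bc, bool need_cp,
                        bool need_eloc, MetricsOut &out)
{
    out.eglob = NA_REAL; out.eloc = NA_REAL;
    out.cp = NA_REAL; out.lp = NA_REAL;

    out.degree.assign(N, 0);
    for (int i = 0; i < N; ++i) out.degree[i] = (int) adj[i].size();

    if (need_bc) {
        // Brandes: shortest-path counts + dependency accumulation; the BFS
        // also yields the distances used for the efficiency metrics.
        out.nodal_eff.assign(N, 0.0);
        out.bc.assign(N, 0.0);
        double inv_sum = 0.0, lp_sum = 0.0;
        long long lp_cnt = 0;
        std::vector<int> dist(N), q(N), order;
        std::vector<double> sigma(N), delta(N);
        std::vector< std::vector<int> > preds(N);
        order.reserve(N);

        for (int s = 0; s < N; ++s) {
            std::fill(dist.begin(), dist.end(), -1);
            std::fill(sigma.begin(), sigma.end(), 0.0);
            for (int i = 0; i < N; ++i) preds[i].clear();
            order.clear();
            dist[s] = 0; sigma[s] = 1.0;
            int qh = 0, qt = 0;
            q[qt++] = s;
            while (qh < qt) {
                int v = q[qh++];
                order.push_back(v);
                for (size_t a = 0; a < adj[v].size(); ++a) {
                    int w = adj[v][a];
                    if (dist[w] < 0) { dist[w] = dist[v] + 1; q[qt++] = w; }
                    if (dist[w] == dist[v] + 1) {
                        sigma[w] += sigma[v];
                        preds[w].push_back(v);
                    }
                }
            }
            double ne = 0.0;
            for (int t = 0; t < N; ++t) {
                if (t == s || dist[t] <= 0) continue;
                ne += 1.0 / dist[t];
                lp_sum += dist[t];
                ++lp_cnt;
            }
            out.nodal_eff[s] = (N > 1) ? ne / (N - 1) : 0.0;
            inv_sum += ne;
            std::fill(delta.begin(), delta.end(), 0.0);
            for (int i = (int) order.size() - 1; i >= 0; --i) {
                int w = order[i];
                for (size_t a = 0; a < preds[w].size(); ++a) {
                    int v = preds[w][a];
                    delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
                }
                if (w != s) out.bc[w] += delta[w];
            }
        }
        out.eglob = (N > 1) ? inv_sum / ((double) N * (N - 1)) : 0.0;
        out.lp = (lp_cnt > 0) ? lp_sum / (double) lp_cnt : NA_REAL;
        for (int i = 0; i < N; ++i) out.bc[i] *= 0.5;  // unordered pairs
    } else if (need_spl) {
        out.nodal_eff.assign(N, 0.0);
        double inv_sum = 0.0, lp_sum = 0.0;
        long long lp_cnt = 0;
        if (W == 1) {
            uint64_t full = (N == 64) ? ~0ULL : ((1ULL << N) - 1);
            for (int s = 0; s < N; ++s) {
                double ne = word_bfs(&rows[0], s, full, &lp_sum, &lp_cnt);
                out.nodal_eff[s] = (N > 1) ? ne / (N - 1) : 0.0;
                inv_sum += ne;
            }
        } else {
            std::vector<uint64_t> visited(W), frontier(W), nxt(W);
            for (int s = 0; s < N; ++s) {
                double ne = 0.0;
                bitset_bfs(rows, W, s, NULL, visited, frontier, nxt,
                           &ne, &lp_sum, &lp_cnt);
                out.nodal_eff[s] = (N > 1) ? ne / (N - 1) : 0.0;
                inv_sum += ne;
            }
        }
        out.eglob = (N > 1) ? inv_sum / ((double) N * (N - 1)) : 0.0;
        out.lp = (lp_cnt > 0) ? lp_sum / (double) lp_cnt : NA_REAL;
    }

    if (need_cp) {
        double cpsum = 0.0;
        for (int i = 0; i < N; ++i) {
            int k = (int) adj[i].size();
            if (k < 2) continue;
            long long tri2 = 0;  // twice the triangle count around i
            const uint64_t *ri = &rows[(size_t) i * W];
            for (size_t a = 0; a < adj[i].size(); ++a) {
                const uint64_t *rv = &rows[(size_t) adj[i][a] * W];
                for (int w = 0; w < W; ++w) tri2 += popcnt(ri[w] & rv[w]);
            }
            cpsum += (double) tri2 / ((double) k * (k - 1));
        }
        out.cp = cpsum / N;
    }

    if (need_eloc) {
        double elsum = 0.0;
        if (W == 1) {
            for (int i = 0; i < N; ++i) {
                int k = (int) adj[i].size();
                if (k < 2) continue;
                uint64_t mask = rows[i];
                double invsum = 0.0;
                for (size_t a = 0; a < adj[i].size(); ++a)
                    invsum += word_bfs(&rows[0], adj[i][a], mask, NULL, NULL);
                elsum += invsum / ((double) k * (k - 1));
            }
        } else {
            std::vector<uint64_t> visited(W), frontier(W), nxt(W);
            for (int i = 0; i < N; ++i) {
                int k = (int) adj[i].size();
                if (k < 2) continue;
                const uint64_t *mask = &rows[(size_t) i * W];
                double invsum = 0.0;
                for (size_t a = 0; a < adj[i].size(); ++a)
                    bitset_bfs(rows, W, adj[i][a], mask, visited, frontier,
                               nxt, &invsum, NULL, NULL);
                elsum += invsum / ((double) k * (k - 1));
            }
        }
        out.eloc = elsum / N;
    }
}

struct PairRec { double w; int m, n; };

static bool pair_cmp(const PairRec &a, const PairRec &b)
{
    if (a.w != b.w) return a.w > b.w;       // larger |r| first
    if (a.m != b.m) return a.m < b.m;       // deterministic tie-break
    return a.n < b.n;
}

static std::vector<PairRec> order_pairs(const NumericMatrix &absR)
{
    int N = absR.nrow();
    std::vector<PairRec> pairs;
    pairs.reserve((size_t) N * (N - 1) / 2);
    for (int m = 0; m < N - 1; ++m)
        for (int n = m + 1; n < N; ++n) {
            PairRec p; p.w = absR(m, n); p.m = m; p.n = n;
            pairs.push_back(p);
        }
    std::sort(pairs.begin(), pairs.end(), pair_cmp);
    return pairs;
}

static inline void add_edge(std::vector< std::vector<int> > &adj,
                            std::vector<uint64_t> &rows, int W, int m, int n)
{
    adj[m].push_back(n);
    adj[n].push_back(m);
    rows[(size_t) m * W + (n >> 6)] |= 1ULL << (n & 63);
    rows[(size_t) n * W + (m >> 6)] |= 1ULL << (m & 63);
}

// [[Rcpp::export]]
IntegerMatrix cpp_edge_order(NumericMatrix absR)
{
    std::vector<PairRec> pairs = order_pairs(absR);
    IntegerMatrix out((int) pairs.size(), 2);
    for (size_t i = 0; i < pairs.size(); ++i) {
        out(i, 0) = pairs[i].m + 1;   // 1-based for R
        out(i, 1) = pairs[i].n + 1;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_graph_metrics(IntegerMatrix A, bool spl, bool bc, bool cp, bool eloc)
{
    int N = A.nrow();
    int W = (N + 63) / 64;
    std::vector< std::vector<int> > adj(N);
    std::vector<uint64_t> rows((size_t) N * W, 0);
    for (int m = 0; m < N - 1; ++m)
        for (int n = m + 1; n < N; ++n)
            if (A(m, n) != 0) add_edge(adj, rows, W, m, n);
    MetricsOut out;
    compute_all(N, adj, rows, W, spl, bc, cp, eloc, out);

    List res = List::create(
        _["degree"] = wrap(out.degree),
        _["eglob"] = out.eglob, _["eloc"] = out.eloc,
        _["cp"] = out.cp, _["lp"] = out.lp);
    if (spl || bc) res["nodal_efficiency"] = wrap(out.nodal_eff);
    if (bc) res["betweenness"] = wrap(out.bc);
    return res;
}

// Metrics for one |r| matrix binarized at every edge count in kvec
// (ascending).  Edges are added incrementally, so the density grid is a
// nested family of graphs and each level reuses the previous adjacency.
// [[Rcpp::export]]
List cpp_grid_metrics(NumericMatrix absR, IntegerVector kvec,
                      bool spl, bool bc, bool cp, bool eloc, bool degree)
{
    int N = absR.nrow();
    int W = (N + 63) / 64;
    int nd = kvec.size();
    std::vector<PairRec> pairs = order_pairs(absR);
    long long npairs = (long long) N * (N - 1) / 2;
    for (int d = 0; d < nd; ++d) {
        if (kvec[d] < 1 || kvec[d] > npairs)
            stop("edge count out of range at density index %d", d + 1);
        if (d > 0 && kvec[d] < kvec[d - 1])
            stop("kvec must be non-decreasing");
    }

    std::vector< std::vector<int> > adj(N);
    std::vector<uint64_t> rows((size_t) N * W, 0);

    NumericMatrix glob(nd, 4);
    colnames(glob) = CharacterVector::create("eglob", "eloc", "cp", "lp");
    IntegerMatrix deg_m(degree ? N : 0, degree ? nd : 0);
    NumericMatrix bc_m(bc ? N : 0, bc ? nd : 0);
    NumericMatrix ne_m((spl || bc) ? N : 0, (spl || bc) ? nd : 0);

    int added = 0;
    MetricsOut out;
    for (int d = 0; d < nd; ++d) {
        while (added < kvec[d]) {
            add_edge(adj, rows, W, pairs[added].m, pairs[added].n);
            ++added;
        }
        compute_all(N, adj, rows, W, spl, bc, cp, eloc, out);
        glob(d, 0) = out.eglob; glob(d, 1) = out.eloc;
        glob(d, 2) = out.cp;    glob(d, 3) = out.lp;
        if (degree) for (int i = 0; i < N; ++i) deg_m(i, d) = out.degree[i];
        if (bc)     for (int i = 0; i < N; ++i) bc_m(i, d) = out.bc[i];
        if (spl || bc) for (int i = 0; i < N; ++i) ne_m(i, d) = out.nodal_eff[i];
    }

    List res = List::create(_["global"] = glob);
    if (degree) res["degree"] = deg_m;
    if (bc) res["betweenness"] = bc_m;
    if (spl || bc) res["nodal_efficiency"] = ne_m;
    return res;
}
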