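#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Copy of X (n x d, column-major) with each point's coordinates contiguous.
static std::vector<double> row_major(NumericMatrix X) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<double> out((std::size_t)n * d);
    for (int j = 0; j < d; ++j)
        for (int i = 0; i < n; ++i)
            out[(std::size_t)i * d + j] = X(i, j);
    return out;
}

static inline double sqdist_pts(const double* a, const double* b, int d) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
        double diff = a[j] - b[j];
        s += diff * diff;
    }
    return s;
}

// OR-symmetrized k-nearest-neighbor edge list. Ties in distance are broken by
// the lower row index so the graph is reproducible. Returns unique undirected
// edges (1-based, first column < second column).
// [[Rcpp::export]]
IntegerMatrix cpp_knn_edges(NumericMatrix X, int k) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<double> P = row_major(X);
    if (k >= n) k = n - 1;
    std::vector<std::uint64_t> edges;
    edges.reserve((std::size_t)n * k);
    std::vector<std::pair<double, int>> cand(n);
    for (int i = 0; i < n; ++i) {
        const double* pi = &P[(std::size_t)i * d];
        int m = 0;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            cand[m++] = std::make_pair(sqdist_pts(pi, &P[(std::size_t)j * d], d), j);
        }
        std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + m);
        for (int t = 0; t < k; ++t) {
            int j = cand[t].second;
            int a = std::min(i, j), b = std::max(i, j);
            edges.push_back(((std::uint64_t)a << 32) | (std::uint64_t)b);
        }
    }
    std::sort(edges.begin(), edges.end());
    edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
    IntegerMatrix out(edges.size(), 2);
    for (std::size_t e = 0; e < edges.size(); ++e) {
        out(e, 0) = (int)(edges[e] >> 32) + 1;
        out(e, 1) = (int)(edges[e] & 0xffffffffu) + 1;
    }
    return out;
}

struct UnionFind {
    std::vector<int> parent, rank_;
    UnionFind(int n) : parent(n), rank_(n, 0) {
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (rank_[a] < rank_[b]) std::swap(a, b);
        parent[b] = a;
        if (rank_[a] == rank_[b]) ++rank_[a];
    }
};

// Connected-component labels (1-based, ordered by first appearance) of a
// graph on n nodes given an edge list (1-based).
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerMatrix edges) {
    UnionFind uf(n);
    for (int e = 0; e < edges.nrow(); ++e)
        uf.unite(edges(e, 0) - 1, edges(e, 1) - 1);
    IntegerVector lab(n);
    std::vector<int> remap(n, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
        int r = uf.find(i);
        if (remap[r] == 0) remap[r] = ++next;
        lab[i] = remap[r];
    }
    return lab;
}

// Index (1-based) of the nearest row of `ref` for each row of `query`.
// Ties broken by the lower reference index.
// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix query, NumericMatrix ref) {
    const int m = query.nrow(), n = ref.nrow(), d = query.ncol();
    std::vector<double> Q = row_major(query), R = row_major(ref);
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) {
        const double* qi = &Q[(std::size_t)i * d];
        double best = R_PosInf;
        int arg = 0;
        for (int j = 0; j < n; ++j) {
            double s = sqdist_pts(qi, &R[(std::size_t)j * d], d);
            if (s < best) { best = s; arg = j; }
        }
        out[i] = arg + 1;
    }
    return out;
}

// Mean number of neighbors (excluding the point itself) within each radius of
// an increasing radius grid; used for the intrinsic-dimension estimate.
// [[Rcpp::export]]
NumericVector cpp_radius_counts(NumericMatrix X, NumericVector radii) {
    const int n = X.nrow(), d = X.ncol(), R = radii.size();
    std::vector<double> P = row_major(X);
    std::vector<double> r2(R);
    for (int r = 0; r < R; ++r) r2[r] = radii[r] * radii[r];
    std::vector<double> hist(R + 1, 0.0);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double s = sqdist_pts(&P[(std::size_t)i * d],
                                  &P[(std::size_t)j * d], d);
            int idx = (int)(std::lower_bound(r2.begin(), r2.end(), s) - r2.begin());
            hist[idx] += 2.0; // pair counts for both endpoints
        }
    }
    NumericVector out(R);
    double cum = 0.0;
    for (int r = 0; r < R; ++r) {
        cum += hist[r];
        out[r] = cum / n;
    }
    return out;
}

// Euclidean minimum spanning tree (Prim, O(n^2)); returns edges (1-based) and
// their lengths. Cutting all edges longer than r reproduces single-linkage
// components at radius r.
// [[Rcpp::export]]
List cpp_mst(NumericMatrix X) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<double> P = row_major(X);
    std::vector<double> mind(n, R_PosInf);
    std::vector<int> from(n, -1);
    std::vector<char> used(n, 0);
    IntegerMatrix edges(n > 1 ? n - 1 : 0, 2);
    NumericVector w(n > 1 ? n - 1 : 0);
    int cur = 0;
    used[0] = 1;
    for (int it = 0; it < n - 1; ++it) {
        for (int j = 0; j < n; ++j) {
            if (used[j]) continue;
            double s = sqdist_pts(&P[(std::size_t)cur * d],
                                  &P[(std::size_t)j * d], d);
            if (s < mind[j]) { mind[j] = s; from[j] = cur; }
        }
        double best = R_PosInf;
        int arg = -1;
        for (int j = 0; j < n; ++j)
            if (!used[j] && mind[j] < best) { best = mind[j]; arg = j; }
        edges(it, 0) = from[arg] + 1;
        edges(it, 1) = arg + 1;
        w[it] = std::sqrt(best);
        used[arg] = 1;
        cur = arg;
    }
    return List::create(_["edges"] = edges, _["lengths"] = w);
}
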