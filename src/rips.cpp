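#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Vietoris-Rips persistent homology up to dimension `maxdim` (simplices up to
// dimension maxdim+1), truncated at filtration radius rmax. Pairs are computed
// dimension by dimension from the anti-transposed (coboundary) matrix with
// clearing, which is equivalent to the standard boundary-matrix reduction but
// far cheaper because the top-dimensional simplices never get columns of
// their own. Classes still alive at rmax are reported with death = Inf.

namespace {

struct Simp {
    double filt;
    std::uint8_t dim;
    std::uint8_t v[4]; // sorted vertex ids (0-based), unused slots = 0xff
};

inline std::uint32_t simp_key(const std::uint8_t* v, int nv) {
    std::uint32_t key = 0;
    for (int t = 0; t < nv; ++t) key |= (std::uint32_t)(v[t] + 1) << (8 * t);
    return key;
}

inline bool simp_less(const Simp& a, const Simp& b) {
    if (a.filt != b.filt) return a.filt < b.filt;
    if (a.dim != b.dim) return a.dim < b.dim;
    for (int t = 0; t <= a.dim; ++t)
        if (a.v[t] != b.v[t]) return a.v[t] < b.v[t];
    return false;
}

// symmetric difference of two ascending index vectors
inline void symdiff(std::vector<int>& a, const std::vector<int>& b) {
    std::vector<int> out;
    out.reserve(a.size() + b.size());
    std::size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
        if (a[i] < b[j]) out.push_back(a[i++]);
        else if (b[j] < a[i]) out.push_back(b[j++]);
        else { ++i; ++j; }
    }
    while (i < a.size()) out.push_back(a[i++]);
    while (j < b.size()) out.push_back(b[j++]);
    a.swap(out);
}

} // namespace

// [[Rcpp::export]]
List cpp_rips_pairs(NumericMatrix D, double rmax, int maxdim) {
    const int n = D.nrow();
    if (n > 250) stop("too many landmark points for persistence (max 250)");
    if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1, or 2");
    const int topdim = maxdim + 1;

    // neighbor lists under rmax
    std::vector<std::vector<int>> nbr(n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (j != i && D(i, j) <= rmax) nbr[i].push_back(j);

    // enumerate simplices of dimension 0 .. topdim
    std::vector<Simp> simp;
    simp.reserve((std::size_t)n * 32);
    for (int i = 0; i < n; ++i) {
        Simp s; s.filt = 0.0; s.dim = 0;
        s.v[0] = (std::uint8_t)i; s.v[1] = s.v[2] = s.v[3] = 0xff;
        simp.push_back(s);
    }
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            if (D(i, j) > rmax) continue;
            Simp s; s.filt = D(i, j); s.dim = 1;
            s.v[0] = (std::uint8_t)i; s.v[1] = (std::uint8_t)j;
            s.v[2] = s.v[3] = 0xff;
            simp.push_back(s);
            if (topdim < 2) continue;
            for (int k = j + 1; k < n; ++k) {
                if (D(i, k) > rmax || D(j, k) > rmax) continue;
                Simp t; t.dim = 2;
                t.filt = std::max(D(i, j), std::max(D(i, k), D(j, k)));
                t.v[0] = (std::uint8_t)i; t.v[1] = (std::uint8_t)j;
                t.v[2] = (std::uint8_t)k; t.v[3] = 0xff;
                simp.push_back(t);
                if (topdim < 3) continue;
                for (int l = k + 1; l < n; ++l) {
                    if (D(i, l) > rmax || D(j, l) > rmax || D(k, l) > rmax)
                        continue;
                    Simp u; u.dim = 3;
                    u.filt = std::max(t.filt,
                        std::max(D(i, l), std::max(D(j, l), D(k, l))));
                    u.v[0] = (std::uint8_t)i; u.v[1] = (std::uint8_t)j;
                    u.v[2] = (std::uint8_t)k; u.v[3] = (std::uint8_t)l;
                    simp.push_back(u);
                }
            }
        }

    std::sort(simp.begin(), simp.end(), simp_less);
    const int total = (int)simp.size();

    std::unordered_map<std::uint32_t, int> index_of;
    index_of.reserve(total * 2);
    for (int s = 0; s < total; ++s)
        index_of[simp_key(simp[s].v, simp[s].dim + 1)] = s;

    // per-dimension column lists (ascending sorted order)
    std::vector<std::vector<int>> bydim(topdim + 1);
    for (int s = 0; s < total; ++s) bydim[simp[s].dim].push_back(s);

    std::vector<char> cleared(total, 0);   // paired as a death in dim below
    std::vector<char> paired(total, 0);    // paired as a birth
    std::vector<double> death_of(total, 0.0);
    std::vector<char> essential(total, 0);

    std::uint8_t cof[5];
    for (int q = 0; q <= maxdim; ++q) {
        std::unordered_map<int, std::vector<int>> lowcol; // pivot -> column
        const std::vector<int>& cols = bydim[q];
        // decreasing filtration order
        for (int ci = (int)cols.size() - 1; ci >= 0; --ci) {
            int sidx = cols[ci];
            if (cleared[sidx]) continue;
            const Simp& s = simp[sidx];
            // build coboundary column: cofacet global indices, ascending
            std::vector<int> col;
            for (int u : nbr[s.v[0]]) {
                bool ok = true;
                double f = D(s.v[0], u);
                for (int t = 1; t <= q; ++t) {
                    if (u == s.v[t]) { ok = false; break; }
                    double duv = D(s.v[t], u);
                    if (duv > rmax) { ok = false; break; }
                    if (duv > f) f = duv;
                }
                if (!ok) continue;
                int nv = 0;
                for (int t = 0; t <= q; ++t) cof[nv++] = s.v[t];
                cof[nv++] = (std::uint8_t)u;
                std::sort(cof, cof + nv);
                col.push_back(index_of[simp_key(cof, nv)]);
            }
            std::sort(col.begin(), col.end());
            // reduce: pivot = smallest global index (latest in anti order)
            while (!col.empty()) {
                int piv = col.front();
                auto it = lowcol.find(piv);
                if (it == lowcol.end()) {
                    lowcol.emplace(piv, std::move(col));
                    paired[sidx] = 1;
                    death_of[sidx] = simp[piv].filt;
                    cleared[piv] = 1;
                    break;
                }
                symdiff(col, it->second);
            }
            if (!paired[sidx]) essential[sidx] = 1;
        }
    }

    // collect intervals per dimension, dropping zero-persistence pairs
    List out(maxdim + 1);
    for (int q = 0; q <= maxdim; ++q) {
        std::vector<double> births, deaths;
        for (int sidx : bydim[q]) {
            if (paired[sidx]) {
                if (death_of[sidx] > simp[sidx].filt) {
                    births.push_back(simp[sidx].filt);
                    deaths.push_back(death_of[sidx]);
                }
            } else if (essential[sidx]) {
                births.push_back(simp[sidx].filt);
                deaths.push_back(R_PosInf);
            }
        }
        NumericMatrix iv(births.size(), 2);
        for (std::size_t r = 0; r < births.size(); ++r) {
            iv(r, 0) = births[r];
            iv(r, 1) = deaths[r];
        }
        colnames(iv) = CharacterVector::create("birth", "death");
        out[q] = iv;
    }
    return out;
}
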