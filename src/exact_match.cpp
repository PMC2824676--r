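#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
#include <tuple>

using namespace Rcpp;

// Maximal repeated pair detection over a single nucleotide sequence.
//
// A direct pair (a, b, L), a < b, satisfies s[a..a+L) == s[b..b+L) with all
// characters in {A,C,G,T}; it is maximal when no single-position extension on
// either side preserves the match (sequence boundaries and N characters also
// terminate extension; N never matches anything, including itself).
//
// An inverted pair matches s[a..a+L) against the reverse complement of
// s[b..b+L). Pairs are canonicalized with a <= b; the degenerate case where
// an interval is its own reverse complement partner is excluded.
//
// Strategy: k-mer seed index (k = min_len) plus seed-and-extend, with a
// per-diagonal list of already-covered intervals so each maximal pair is
// extended exactly once regardless of how many of its seeds are visited.

static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

typedef std::unordered_map<long long, std::vector<std::pair<int, int> > > DiagCover;

static inline bool diag_covered(const DiagCover &cov, long long diag, int pos) {
    DiagCover::const_iterator it = cov.find(diag);
    if (it == cov.end()) return false;
    const std::vector<std::pair<int, int> > &v = it->second;
    for (size_t m = 0; m < v.size(); ++m)
        if (pos >= v[m].first && pos < v[m].second) return true;
    return false;
}

static void index_kmers(const std::string &s, int k,
                        std::unordered_map<std::string, std::vector<int> > &idx) {
    const int n = (int)s.size();
    if (n < k) return;
    int bad = 0;  // non-ACGT count in current window
    for (int i = 0; i < k; ++i) if (!is_acgt(s[i])) ++bad;
    for (int i = 0; i + k <= n; ++i) {
        if (i > 0) {
            if (!is_acgt(s[i - 1])) --bad;
            if (!is_acgt(s[i + k - 1])) ++bad;
        }
        if (bad == 0) idx[s.substr(i, k)].push_back(i);
    }
}

// [[Rcpp::export(name = ".mem_pairs_cpp")]]
DataFrame mem_pairs_cpp(std::string s, int min_len) {
    const int n = (int)s.size();
    const int k = min_len;
    std::vector<int> a_out, b_out, len_out;
    std::vector<int> inv_out;

    if (k < 1) stop("min_len must be >= 1");

    // ---- direct pairs -----------------------------------------------------
    {
        std::unordered_map<std::string, std::vector<int> > idx;
        index_kmers(s, k, idx);
        DiagCover cov;
        for (std::unordered_map<std::string, std::vector<int> >::const_iterator
                 it = idx.begin(); it != idx.end(); ++it) {
            const std::vector<int> &pos = it->second;
            const size_t m = pos.size();
            if (m < 2) continue;
            for (size_t x = 0; x < m; ++x) {
                for (size_t y = x + 1; y < m; ++y) {
                    int i = pos[x], j = pos[y];
                    long long diag = (long long)j - i;
                    if (diag_covered(cov, diag, i)) continue;
                    int a = i, b = j;
                    while (a > 0 && b > 0 && is_acgt(s[a - 1]) && s[a - 1] == s[b - 1]) {
                        --a; --b;
                    }
                    int e1 = i + k, e2 = j + k;
                    while (e1 < n && e2 < n && is_acgt(s[e1]) && s[e1] == s[e2]) {
                        ++e1; ++e2;
                    }
                    cov[diag].push_back(std::make_pair(a, e1));
                    a_out.push_back(a);
                    b_out.push_back(b);
                    len_out.push_back(e1 - a);
                    inv_out.push_back(0);
                }
                if ((x & 63) == 0) Rcpp::checkUserInterrupt();
            }
        }
    }

    // ---- inverted pairs ---------------------------------------------------
    {
        std::string t(n, 'N');  // reverse complement of s
        for (int i = 0; i < n; ++i) t[i] = comp_base(s[n - 1 - i]);
        std::unordered_map<std::string, std::vector<int> > idxT;
        index_kmers(t, k, idxT);
        DiagCover cov;
        std::set<std::tuple<int, int, int> > seen;

        int bad = 0;
        for (int i = 0; i < k && i < n; ++i) if (!is_acgt(s[i])) ++bad;
        for (int i = 0; i + k <= n; ++i) {
            if (i > 0) {
                if (!is_acgt(s[i - 1])) --bad;
                if (!is_acgt(s[i + k - 1])) ++bad;
            }
            if (bad != 0) continue;
            std::unordered_map<std::string, std::vector<int> >::const_iterator
                hit = idxT.find(s.substr(i, k));
            if (hit == idxT.end()) continue;
            const std::vector<int> &pos = hit->second;
            for (size_t y = 0; y < pos.size(); ++y) {
                int j = pos[y];
                long long diag = (long long)i - j;
                if (diag_covered(cov, diag, i)) continue;
                int a = i, b = j;
                while (a > 0 && b > 0 && is_acgt(s[a - 1]) && s[a - 1] == t[b - 1]) {
                    --a; --b;
                }
                int e1 = i + k, e2 = j + k;
                while (e1 < n && e2 < n && is_acgt(s[e1]) && s[e1] == t[e2]) {
                    ++e1; ++e2;
                }
                cov[diag].push_back(std::make_pair(a, e1));
                int L = e1 - a;
                int p2 = n - e2;  // start of the partner interval in s coords
                int lo = a < p2 ? a : p2;
                int hi = a < p2 ? p2 : a;
                if (lo == hi) continue;  // interval is its own RC partner
                std::tuple<int, int, int> key(lo, hi, L);
                if (seen.insert(key).second) {
                    a_out.push_back(lo);
                    b_out.push_back(hi);
                    len_out.push_back(L);
                    inv_out.push_back(1);
                }
            }
            if ((i & 255) == 0) Rcpp::checkUserInterrupt();
        }
    }

    return DataFrame::create(
        Named("a_start") = a_out,
        Named("b_start") = b_out,
        Named("length") = len_out,
        Named("inverted") = inv_out);
}
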