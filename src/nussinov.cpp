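#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// base codes: A=0, C=1, G=2, U/T=3, anything else=4 (never pairs)
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4;
    }
}

static inline bool can_pair(int a, int b, bool gu) {
    if (a > b) std::swap(a, b);
    if (a == 0 && b == 3) return true;          // A:U
    if (a == 1 && b == 2) return true;          // C:G
    if (gu && a == 2 && b == 3) return true;    // G:U wobble
    return false;
}

static std::vector<int> encode(const std::string& s) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
    return v;
}

// Fill the maximum-pairing DP table. M[i][j] = max pairs in s[i..j].
static void fill_dp(const std::vector<int>& s, int min_loop, bool gu,
                    std::vector<std::vector<int> >& M) {
    int n = (int) s.size();
    M.assign(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = M[i + 1][j];               // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(s[i], s[k], gu)) continue;
                int v = 1;
                if (k - 1 >= i + 1) v += M[i + 1][k - 1];
                if (k + 1 <= j) v += M[k + 1][j];
                if (v > best) best = v;
            }
            M[i][j] = best;
        }
    }
}

// Deterministic traceback. At each subproblem the base i is left unpaired
// whenever that is co-optimal (no pair is invented that the count does not
// require); otherwise i is paired with the smallest co-optimal partner j.
static void traceback(const std::vector<int>& s, int min_loop, bool gu,
                      const std::vector<std::vector<int> >& M,
                      std::vector<std::pair<int,int> >& pairs) {
    int n = (int) s.size();
    if (n == 0) return;
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= min_loop) continue;
        if (M[i][j] == M[i + 1][j]) {
            stack.push_back(std::make_pair(i + 1, j));
            continue;
        }
        for (int k = i + min_loop + 1; k <= j; ++k) {
            if (!can_pair(s[i], s[k], gu)) continue;
            int v = 1;
            if (k - 1 >= i + 1) v += M[i + 1][k - 1];
            if (k + 1 <= j) v += M[k + 1][j];
            if (v == M[i][j]) {
                pairs.push_back(std::make_pair(i, k));
                stack.push_back(std::make_pair(k + 1, j));
                stack.push_back(std::make_pair(i + 1, k - 1));
                break;
            }
        }
    }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop, bool allow_GU,
                   bool want_pairs) {
    std::vector<int> s = encode(seq);
    int n = (int) s.size();
    if (n == 0) {
        return List::create(_["count"] = 0,
                            _["pairs"] = IntegerMatrix(0, 2));
    }
    std::vector<std::vector<int> > M;
    fill_dp(s, min_loop, allow_GU, M);
    int count = M[0][n - 1];
    if (!want_pairs) {
        return List::create(_["count"] = count,
                            _["pairs"] = R_NilValue);
    }
    std::vector<std::pair<int,int> > pairs;
    traceback(s, min_loop, allow_GU, M, pairs);
    IntegerMatrix pm((int) pairs.size(), 2);
    for (size_t r = 0; r < pairs.size(); ++r) {
        pm(r, 0) = pairs[r].first + 1;   // 1-based for R
        pm(r, 1) = pairs[r].second + 1;
    }
    return List::create(_["count"] = count, _["pairs"] = pm);
}

// [[Rcpp::export(name = ".nussinov_count_batch")]]
IntegerVector nussinov_count_batch(CharacterVector seqs, int min_loop,
                                   bool allow_GU) {
    int m = seqs.size();
    IntegerVector out(m);
    std::vector<std::vector<int> > M;
    for (int q = 0; q < m; ++q) {
        std::string seq = as<std::string>(seqs[q]);
        std::vector<int> s = encode(seq);
        if (s.empty()) { out[q] = 0; continue; }
        fill_dp(s, min_loop, allow_GU, M);
        out[q] = M[0][(int) s.size() - 1];
    }
    return out;
}
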