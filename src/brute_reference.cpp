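// Exhaustive-enumeration reference for maximum base pairing.
//
// Plain recursion over all nested structures (base i unpaired, or paired
// with every admissible k) with no memoisation: exponential, intended only
// as an independent correctness oracle for short sequences.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int bcode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4;
    }
}

static inline bool bpair(int a, int b, bool gu) {
    if (a > b) std::swap(a, b);
    return (a == 0 && b == 3) || (a == 1 && b == 2) ||
           (gu && a == 2 && b == 3);
}

static int brute(const std::vector<int>& s, int i, int j, int min_loop,
                 bool gu) {
    if (i >= j || j - i <= min_loop) return 0;
    int best = brute(s, i + 1, j, min_loop, gu);
    for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!bpair(s[i], s[k], gu)) continue;
        int v = 1 + brute(s, i + 1, k - 1, min_loop, gu)
                  + brute(s, k + 1, j, min_loop, gu);
        if (v > best) best = v;
    }
    return best;
}

// [[Rcpp::export(name = ".nussinov_brute_batch")]]
IntegerVector nussinov_brute_batch(CharacterVector seqs, int min_loop,
                                   bool allow_GU) {
    int m = seqs.size();
    IntegerVector out(m);
    for (int q = 0; q < m; ++q) {
        std::string seq = as<std::string>(seqs[q]);
        std::vector<int> s(seq.size());
        for (size_t i = 0; i < seq.size(); ++i) s[i] = bcode(seq[i]);
        out[q] = s.empty() ? 0
                           : brute(s, 0, (int) s.size() - 1, min_loop,
                                   allow_GU);
        if (q % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
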