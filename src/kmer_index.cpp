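#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit packed k-mer hash over {A,C,G,T}; anything else (N etc.) breaks the
// window. k <= 31 so a k-mer fits a 64-bit word; class sets are 32-bit
// bitmasks, so at most 32 feature classes per index.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

struct KmerIndex {
    int k;
    int n_classes;
    std::unordered_map<uint64_t, uint32_t> map; // k-mer -> class bitmask
};

// Collect the encoded k-mers of a sequence; positions with non-ACGT bases
// yield no k-mer. Appends (code) to out.
static void encode_kmers(const char *s, size_t n, int k,
                         std::vector<uint64_t> &out) {
    if ((int)n < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) {
            valid = 0;
            cur = 0;
            continue;
        }
        cur = ((cur << 2) | (uint64_t)c) & mask;
        if (++valid >= k) out.push_back(cur);
    }
}

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, IntegerVector class_ids,
                      int k, int n_classes) {
    if (k < 1 || k > 31) stop("k must be between 1 and 31");
    if (n_classes < 1 || n_classes > 32)
        stop("at most 32 feature classes are supported");
    if (seqs.size() != class_ids.size())
        stop("seqs and class_ids must have equal length");
    KmerIndex *idx = new KmerIndex();
    idx->k = k;
    idx->n_classes = n_classes;
    std::vector<uint64_t> words;
    bool any = false;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        int cls = class_ids[i];
        if (cls < 0 || cls >= n_classes) {
            delete idx;
            stop("class id out of range");
        }
        const char *s = CHAR(STRING_ELT(seqs, i));
        size_t n = std::strlen(s);
        words.clear();
        encode_kmers(s, n, k, words);
        if (!words.empty()) any = true;
        uint32_t bit = 1u << cls;
        for (uint64_t w : words) idx->map[w] |= bit;
    }
    if (!any) {
        delete idx;
        stop("empty index: no record contributes a k-mer of length k");
    }
    XPtr<KmerIndex> ptr(idx, true);
    return ptr;
}

// [[Rcpp::export(name = ".ptr_is_null")]]
bool ptr_is_null(SEXP xp) {
    return TYPEOF(xp) != EXTPTRSXP || R_ExternalPtrAddr(xp) == NULL;
}

// [[Rcpp::export(name = ".kmer_index_size")]]
double kmer_index_size(SEXP xp) {
    XPtr<KmerIndex> idx(xp);
    return (double)idx->map.size();
}

// Class sets (1-based class indices) for each query word; integer(0) when the
// word is absent or contains non-ACGT bases or has wrong length.
// [[Rcpp::export(name = ".kmer_index_query")]]
List kmer_index_query(SEXP xp, CharacterVector words) {
    XPtr<KmerIndex> idx(xp);
    int k = idx->k;
    List out(words.size());
    std::vector<uint64_t> enc;
    for (R_xlen_t i = 0; i < words.size(); ++i) {
        const char *s = CHAR(STRING_ELT(words, i));
        size_t n = std::strlen(s);
        enc.clear();
        if ((int)n == k) encode_kmers(s, n, k, enc);
        if (enc.size() != 1) {
            out[i] = IntegerVector(0);
            continue;
        }
        auto it = idx->map.find(enc[0]);
        if (it == idx->map.end()) {
            out[i] = IntegerVector(0);
            continue;
        }
        std::vector<int> cls;
        for (int c = 0; c < idx->n_classes; ++c)
            if (it->second & (1u << c)) cls.push_back(c + 1);
        out[i] = wrap(cls);
    }
    return out;
}

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcount(x);
#else
    int n = 0;
    while (x) { n += x & 1u; x >>= 1; }
    return n;
#endif
}

// Assign reads to feature classes by unique k-mer membership.
// Outcomes: 0 unassigned, 1 assigned (class in `cls`), 2 ambiguous.
// specific_mask: bitmask of classes regarded as isoform-specific; a read whose
// matched k-mers span one specific class plus non-specific (common) classes is
// assigned to the specific class when it has >= min_hits k-mers unique to it
// (junction rule); any other multi-class pattern is ambiguous.
// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(SEXP xp, CharacterVector reads, int min_hits,
                      uint32_t specific_mask) {
    XPtr<KmerIndex> idx(xp);
    const int k = idx->k;
    const int nc = idx->n_classes;
    R_xlen_t n = reads.size();
    IntegerVector outcome(n), cls(n), nhits(n);
    std::vector<uint64_t> words;
    std::vector<std::pair<uint64_t, uint32_t> > hits;
    std::vector<int> uniq(nc);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(reads, i));
        size_t len = std::strlen(s);
        cls[i] = NA_INTEGER;
        if ((int)len < k) { // shorter than k: unassigned by contract
            outcome[i] = 0;
            nhits[i] = 0;
            continue;
        }
        words.clear();
        encode_kmers(s, len, k, words);
        std::sort(words.begin(), words.end());
        words.erase(std::unique(words.begin(), words.end()), words.end());
        hits.clear();
        for (uint64_t w : words) {
            auto it = idx->map.find(w);
            if (it != idx->map.end()) hits.push_back({w, it->second});
        }
        nhits[i] = (int)hits.size();
        if (hits.empty()) {
            outcome[i] = 0;
            continue;
        }
        uint32_t unionmask = 0;
        std::fill(uniq.begin(), uniq.end(), 0);
        for (auto &h : hits) {
            unionmask |= h.second;
            if (popcount32(h.second) == 1) {
                int c = 0;
                uint32_t m = h.second;
                while (!(m & 1u)) { m >>= 1; ++c; }
                uniq[c]++;
            }
        }
        int nclasses = popcount32(unionmask);
        if (nclasses == 1) {
            int c = 0;
            uint32_t m = unionmask;
            while (!(m & 1u)) { m >>= 1; ++c; }
            if (uniq[c] >= min_hits) {
                outcome[i] = 1;
                cls[i] = c + 1;
            } else {
                outcome[i] = 0; // too little evidence
            }
        } else {
            uint32_t spec_in_union = unionmask & specific_mask;
            if (popcount32(spec_in_union) == 1) {
                int c = 0;
                uint32_t m = spec_in_union;
                while (!(m & 1u)) { m >>= 1; ++c; }
                if (uniq[c] >= min_hits) { // junction rule
                    outcome[i] = 1;
                    cls[i] = c + 1;
                } else {
                    outcome[i] = 2;
                }
            } else {
                outcome[i] = 2;
            }
        }
    }
    return List::create(_["outcome"] = outcome, _["class"] = cls,
                        _["n_hits"] = nhits);
}
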