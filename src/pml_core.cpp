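#include <Rcpp.h>
#include <array>
#include <cmath>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Suffix automaton over the alphabet {A,C,G,T,#}. '#' separates concatenated
// reference segments (and replaces ambiguous bases), so a read -- which never
// contains '#' -- can never match across a segment boundary.
struct SuffixAutomaton {
  std::vector<int> len, link;
  std::vector<std::array<int, 5>> nxt;
  int last;
  SuffixAutomaton() {
    new_state(0, -1);
    last = 0;
  }
  int new_state(int l, int lk) {
    len.push_back(l);
    link.push_back(lk);
    nxt.push_back({-1, -1, -1, -1, -1});
    return (int)len.size() - 1;
  }
  void extend(int c) {
    int cur = new_state(len[last] + 1, -1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q]);
        nxt[clone] = nxt[q];
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

static inline int base_code(char ch) {
  switch (ch) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;  // N, '#', anything else: universal mismatch / separator
}

// Build the automaton over the REVERSED text. Matching statistics computed on
// a reversed read against the reversed text give, after reversal, the
// longest-prefix match length at every read start position.
// [[Rcpp::export]]
SEXP sa_build(std::string text) {
  SuffixAutomaton* sam = new SuffixAutomaton();
  for (auto it = text.rbegin(); it != text.rend(); ++it) {
    int c = base_code(*it);
    sam->extend(c < 0 ? 4 : c);
  }
  XPtr<SuffixAutomaton> p(sam, true);
  return p;
}

// [[Rcpp::export]]
bool sa_valid(SEXP ptr) {
  return ptr != R_NilValue && TYPEOF(ptr) == EXTPTRSXP &&
         R_ExternalPtrAddr(ptr) != NULL;
}

// values[i] = length of the longest prefix of read[i:] occurring in the text
// (either strand is handled by indexing both strands). Non-ACGT read bases
// match nothing.
// [[Rcpp::export]]
List sa_matching_lengths(SEXP ptr, CharacterVector reads) {
  XPtr<SuffixAutomaton> sam(ptr);
  List out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int L = (int)s.size();
    IntegerVector ms(L);
    int v = 0, l = 0;
    for (int i = L - 1; i >= 0; --i) {
      int c = base_code(s[i]);
      if (c < 0) {
        v = 0;
        l = 0;
        ms[i] = 0;
        continue;
      }
      while (v != 0 && sam->nxt[v][c] == -1) {
        v = sam->link[v];
        l = sam->len[v];
      }
      if (sam->nxt[v][c] != -1) {
        v = sam->nxt[v][c];
        ++l;
      } else {
        l = 0;
      }
      ms[i] = l;
    }
    out[r] = ms;
  }
  return out;
}

// Deterministic seed-and-extend read aligner: exact k-mer seeds against the
// concatenated (separator-joined) reference text, ungapped extension along the
// seed diagonal; a read maps if some diagonal reaches >= min_ident identity
// over an overlap of >= min_len bases. NA reads return NA.
// [[Rcpp::export]]
LogicalVector seed_align(std::string text, CharacterVector reads, int k,
                         int min_len, double min_ident) {
  std::unordered_map<uint64_t, std::vector<int>> kmer_idx;
  const int n = (int)text.size();
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(text[i]);
    if (c < 0) {
      run = 0;
      key = 0;
      continue;
    }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) kmer_idx[key].push_back(i - k + 1);
  }
  LogicalVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (CharacterVector::is_na(reads[r])) {
      out[r] = NA_LOGICAL;
      continue;
    }
    std::string s = as<std::string>(reads[r]);
    int L = (int)s.size();
    bool mapped = false;
    std::unordered_set<long long> seen;
    uint64_t rk = 0;
    int rrun = 0;
    for (int i = 0; i < L && !mapped; ++i) {
      int c = base_code(s[i]);
      if (c < 0) {
        rrun = 0;
        rk = 0;
        continue;
      }
      rk = ((rk << 2) | (uint64_t)c) & mask;
      if (++rrun < k) continue;
      int spos = i - k + 1;
      auto it = kmer_idx.find(rk);
      if (it == kmer_idx.end()) continue;
      for (int tpos : it->second) {
        long long diag = (long long)tpos - spos;
        if (!seen.insert(diag).second) continue;
        int lo = spos, hi = spos + k - 1;
        while (lo > 0 && lo - 1 + diag >= 0 &&
               base_code(text[(size_t)(lo - 1 + diag)]) >= 0)
          --lo;
        while (hi < L - 1 && hi + 1 + diag < n &&
               base_code(text[(size_t)(hi + 1 + diag)]) >= 0)
          ++hi;
        int ov = hi - lo + 1;
        if (ov < min_len) continue;
        int m = 0;
        for (int j = lo; j <= hi; ++j)
          if (s[j] == text[(size_t)(j + diag)]) ++m;
        if ((double)m >= std::ceil(min_ident * ov)) {
          mapped = true;
          break;
        }
      }
    }
    out[r] = mapped;
  }
  return out;
}
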