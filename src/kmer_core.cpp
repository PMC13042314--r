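#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <string>
#include <cstring>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else is ambiguous.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Collect canonical k-mer codes for one sequence (rolling, skipping windows
// that contain ambiguous bases).  k must be <= 31 so codes fit in 62 bits.
static void collect_codes(const char *s, size_t n, int k,
                          std::vector<uint64_t> &out) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // length of current unambiguous run
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  int n = seqs.size();
  List res(n);
  std::vector<uint64_t> codes;
  std::vector<double> ucodes, ucounts;
  for (int i = 0; i < n; ++i) {
    codes.clear(); ucodes.clear(); ucounts.clear();
    const char *s = CHAR(STRING_ELT(seqs, i));
    collect_codes(s, std::strlen(s), k, codes);
    std::sort(codes.begin(), codes.end());
    for (size_t j = 0; j < codes.size(); ) {
      size_t j2 = j;
      while (j2 < codes.size() && codes[j2] == codes[j]) ++j2;
      ucodes.push_back((double)codes[j]);
      ucounts.push_back((double)(j2 - j));
      j = j2;
    }
    res[i] = List::create(_["codes"] = NumericVector(ucodes.begin(), ucodes.end()),
                          _["counts"] = NumericVector(ucounts.begin(), ucounts.end()));
  }
  return res;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  int n = codes.size();
  CharacterVector out(n);
  static const char bases[] = "ACGT";
  std::string buf(k, 'A');
  for (int i = 0; i < n; ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = bases[c & 3ULL]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// Competitive assignment of read pairs to the chromosome sharing the most
// canonical k-mer windows; ties or scores < min_shared are unassigned (0).
// [[Rcpp::export]]
// tie_mode 0: tied pairs unassigned; 1: deterministic pseudo-random pick
// among the tied chromosomes (hash of pair index and score), emulating a
// "top best" aligner's unbiased tie resolution.
// [[Rcpp::export]]
IntegerVector cpp_competitive_assign(CharacterVector mate1,
                                     CharacterVector mate2,
                                     CharacterVector chroms,
                                     int k, int min_shared,
                                     int tie_mode) {
  int nc = chroms.size();
  if (nc == 0) stop("empty chromosome index");
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  // Build (code -> postings of chromosome ids) as sorted parallel arrays.
  std::vector<std::pair<uint64_t, uint32_t>> pairs;
  {
    std::vector<uint64_t> codes;
    for (int c = 0; c < nc; ++c) {
      codes.clear();
      const char *s = CHAR(STRING_ELT(chroms, c));
      collect_codes(s, std::strlen(s), k, codes);
      std::sort(codes.begin(), codes.end());
      codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
      for (uint64_t cd : codes) pairs.emplace_back(cd, (uint32_t)c);
    }
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<uint64_t> keys;  std::vector<uint32_t> post, off;
  keys.reserve(pairs.size()); post.reserve(pairs.size());
  off.push_back(0);
  for (size_t i = 0; i < pairs.size(); ) {
    size_t j = i;
    keys.push_back(pairs[i].first);
    while (j < pairs.size() && pairs[j].first == pairs[i].first) {
      post.push_back(pairs[j].second); ++j;
    }
    off.push_back((uint32_t)post.size());
    i = j;
  }

  int np = mate1.size();
  if (mate2.size() != np) stop("mate vectors differ in length");
  IntegerVector out(np);
  std::vector<int> score(nc, 0);
  std::vector<int> touched;
  std::vector<uint64_t> rk;
  for (int p = 0; p < np; ++p) {
    touched.clear();
    for (int m = 0; m < 2; ++m) {
      const char *s = CHAR(STRING_ELT(m == 0 ? mate1 : mate2, p));
      rk.clear();
      collect_codes(s, std::strlen(s), k, rk);
      for (uint64_t cd : rk) {
        auto it = std::lower_bound(keys.begin(), keys.end(), cd);
        if (it == keys.end() || *it != cd) continue;
        size_t ki = (size_t)(it - keys.begin());
        for (uint32_t q = off[ki]; q < off[ki + 1]; ++q) {
          int c = (int)post[q];
          if (score[c] == 0) touched.push_back(c);
          score[c]++;
        }
      }
    }
    int bestscore = 0;
    for (int c : touched) if (score[c] > bestscore) bestscore = score[c];
    if (bestscore < min_shared || bestscore == 0) {
      out[p] = 0;
    } else {
      std::vector<int> tied;
      for (int c : touched) if (score[c] == bestscore) tied.push_back(c);
      std::sort(tied.begin(), tied.end());
      if (tied.size() == 1) {
        out[p] = tied[0] + 1;
      } else if (tie_mode == 0) {
        out[p] = 0;
      } else {
        uint64_t h = (uint64_t)(p + 1) * 2654435761ULL ^
                     (uint64_t)bestscore * 97531ULL;
        h ^= h >> 16; h *= 0x45d9f3b1ULL; h ^= h >> 13;
        out[p] = tied[h % tied.size()] + 1;
      }
    }
    for (int c : touched) score[c] = 0;
  }
  return out;
}

// Mutate sequences i.i.d. per site at the given rate (uniform choice among
// the 3 alternative bases); uses R's RNG so set.seed() governs determinism.
// Ambiguous bases are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, NumericVector rate) {
  static const char bases[] = "ACGT";
  int n = seqs.size();
  if (rate.size() != 1 && rate.size() != n)
    stop("rate must have length 1 or length(seqs)");
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (int i = 0; i < n; ++i) {
    double p = rate.size() == 1 ? rate[0] : rate[i];
    if (p < 0 || p >= 1) stop("mutation rate must be in [0, 1)");
    const char *s = CHAR(STRING_ELT(seqs, i));
    buf.assign(s);
    if (p > 0) {
      for (size_t j = 0; j < buf.size(); ++j) {
        int b = base_code(buf[j]);
        if (b < 0) continue;
        if (R::unif_rand() < p) {
          int alt = (int)(R::unif_rand() * 3.0);
          if (alt > 2) alt = 2;
          // pick among the 3 bases != b
          if (alt >= b) ++alt;
          buf[j] = bases[alt];
        }
      }
    }
    out[i] = buf;
  }
  return out;
}
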