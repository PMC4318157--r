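#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend matcher with the SOAP-style contract: report a read only if
// its best placement (fewest mismatches, capped at max_mm) is unique across
// all features and offsets; ties are "repeats". Seeds are three disjoint
// k-mers (pigeonhole: with <=2 mismatches at least one seed is exact).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N etc: never matches
  }
}

struct RefIndex {
  std::vector<std::vector<int8_t>> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> kmap; // key -> (feat<<32)|pos
  int k;
};

static void build_index(const CharacterVector &refs, int k, RefIndex &idx) {
  idx.k = k;
  int nf = refs.size();
  idx.seqs.resize(nf);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int f = 0; f < nf; ++f) {
    const char *s = CHAR(STRING_ELT(refs, f));
    int L = (int) strlen(s);
    std::vector<int8_t> &enc = idx.seqs[f];
    enc.resize(L);
    for (int i = 0; i < L; ++i) enc[i] = (int8_t) base_code(s[i]);
    if (L < k) continue;
    uint64_t key = 0;
    int valid = 0; // run length of non-N bases ending here
    for (int i = 0; i < L; ++i) {
      int c = enc[i];
      if (c > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        idx.kmap[key].push_back(((uint64_t) f << 32) | (uint64_t) pos);
      }
    }
  }
}

static inline int count_mm(const std::vector<int8_t> &ref, int start,
                           const std::vector<int8_t> &read, int max_mm) {
  int mm = 0;
  int L = (int) read.size();
  for (int i = 0; i < L; ++i) {
    if (ref[start + i] != read[i] || read[i] > 3) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export(name = ".cpp_align_reads")]]
List cpp_align_reads(CharacterVector reads, CharacterVector refs,
                     int max_mm = 2, bool report_ties = false) {
  int n = reads.size();
  // choose k from the shortest read (>= 3 disjoint seeds for <=2 mismatches)
  int min_len = 1 << 30;
  for (int i = 0; i < n; ++i) {
    int L = (int) strlen(CHAR(STRING_ELT(reads, i)));
    if (L < min_len) min_len = L;
  }
  if (n == 0) min_len = 36;
  int k = min_len / (max_mm + 1);
  if (k > 12) k = 12;
  if (k < 4) stop("reads too short for seeded matching (need length >= %d)",
                  4 * (max_mm + 1));

  RefIndex idx;
  build_index(refs, k, idx);

  IntegerVector feat(n, NA_INTEGER), pos(n, NA_INTEGER), mm_out(n, NA_INTEGER),
      nbest(n, 0);
  CharacterVector status(n), ties(n);
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<int8_t> renc;
  std::vector<uint64_t> seen;       // candidate (feat<<32)|alignpos, dedupe
  std::vector<uint64_t> best_locs;  // locations achieving best mm

  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int L = (int) strlen(s);
    renc.resize(L);
    bool has_bad = false;
    for (int i = 0; i < L; ++i) {
      renc[i] = (int8_t) base_code(s[i]);
      if (renc[i] > 3) has_bad = true;
    }
    int nseeds = max_mm + 1;
    seen.clear();
    best_locs.clear();
    int best_mm = max_mm + 1;
    for (int sd = 0; sd < nseeds; ++sd) {
      // spread seeds across the read; last seed flush with the end
      int off = (sd == nseeds - 1) ? (L - k) : sd * k;
      if (off < 0) continue;
      uint64_t key = 0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        if (renc[off + i] > 3) { ok = false; break; }
        key = ((key << 2) | (uint64_t) renc[off + i]) & mask;
      }
      if (!ok) continue;
      auto it = idx.kmap.find(key);
      if (it == idx.kmap.end()) continue;
      for (uint64_t packed : it->second) {
        int f = (int) (packed >> 32);
        int p = (int) (packed & 0xffffffffULL);
        int astart = p - off;
        if (astart < 0 || astart + L > (int) idx.seqs[f].size()) continue;
        uint64_t loc = ((uint64_t) f << 32) | (uint64_t) astart;
        bool dup = false;
        for (uint64_t q : seen) if (q == loc) { dup = true; break; }
        if (dup) continue;
        seen.push_back(loc);
        int mm = count_mm(idx.seqs[f], astart, renc, max_mm);
        if (mm > max_mm) continue;
        if (mm < best_mm) { best_mm = mm; best_locs.clear(); }
        if (mm == best_mm) best_locs.push_back(loc);
      }
    }
    (void) has_bad;
    if (best_locs.empty()) {
      status[r] = "unaligned";
    } else if (best_locs.size() == 1) {
      status[r] = "unique";
      feat[r] = (int) (best_locs[0] >> 32) + 1; // 1-based feature index
      pos[r] = (int) (best_locs[0] & 0xffffffffULL) + 1;
      mm_out[r] = best_mm;
      nbest[r] = 1;
    } else {
      status[r] = "repeat";
      mm_out[r] = best_mm;
      nbest[r] = (int) best_locs.size();
      if (report_ties) {
        std::string t;
        int cap = 0;
        for (uint64_t loc : best_locs) {
          if (cap++ >= 64) break;
          if (!t.empty()) t += ",";
          t += std::to_string((int) (loc >> 32) + 1);
        }
        ties[r] = t;
      }
    }
  }
  return List::create(_["feature"] = feat, _["pos"] = pos,
                      _["mismatches"] = mm_out, _["status"] = status,
                      _["n_best"] = nbest, _["tied_features"] = ties);
}
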