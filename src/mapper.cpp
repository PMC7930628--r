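#include <Rcpp.h>
#include <unordered_map>
#include <climits>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else = 4 (never matches).
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? 3 - b : 4;
  }
  return r;
}

// Placements with more than max_mismatch substitutions are ignored by
// contract, which licenses a pigeonhole-seeded search: split each read into
// max_mismatch+1 disjoint chunks of length k; any placement within the
// budget must match at least one chunk exactly, so exact k-mer lookup over
// the targets enumerates every qualifying placement.  Equivalent to the
// exhaustive minimum-mismatch scan (property-tested against it) but fast.
// Circular targets are indexed over a doubled copy so wrap-around
// placements get one canonical start in 1..L.
// Returns the leftmost best placement plus n_best and the mismatch count
// of the runner-up placement (NA if none within max_mismatch).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads,
                        CharacterVector target_seqs,
                        CharacterVector target_names,
                        LogicalVector circular,
                        int max_mismatch) {
  int n_t = target_seqs.size();
  std::vector<std::vector<int>> tenc(n_t);
  std::vector<int> tlen(n_t);
  for (int t = 0; t < n_t; ++t) {
    std::string s = as<std::string>(target_seqs[t]);
    tlen[t] = (int)s.size();
    if (circular[t]) s += s;          // doubled for wrap-around placements
    tenc[t] = encode(s);
  }

  int n_r = reads.size();
  IntegerVector out_target(n_r), out_start(n_r), out_mm(n_r),
      out_nbest(n_r), out_second(n_r);
  CharacterVector out_strand(n_r);

  // chunk length from the shortest read (one index serves all reads)
  int min_rlen = INT_MAX;
  for (int r = 0; r < n_r; ++r)
    min_rlen = std::min(min_rlen, (int)LENGTH(STRING_ELT(reads, r)));
  if (n_r == 0) min_rlen = 30;
  int k = std::min(31, min_rlen / (max_mismatch + 1));
  if (k < 4) k = std::min(4, min_rlen);

  // k-mer index: packed 2-bit k-mer -> (target, offset) pairs
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < n_t; ++t) {
    const std::vector<int>& T = tenc[t];
    int n = (int)T.size();
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      if (T[i] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)T[i]) & mask;
      if (++run >= k) index[key].push_back({t, i - k + 1});
    }
  }

  std::vector<int64_t> seen;  // per-read candidate dedup
  for (int r = 0; r < n_r; ++r) {
    std::vector<int> fwd = encode(as<std::string>(reads[r]));
    std::vector<int> rev = revcomp(fwd);
    int rlen = (int)fwd.size();
    int n_chunks = std::min(max_mismatch + 1, rlen / k);

    int best = max_mismatch + 1, second = max_mismatch + 1, nbest = 0;
    int b_t = -1, b_s = -1; char b_strand = '+';

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& R = strand == 0 ? fwd : rev;
      seen.clear();
      for (int c = 0; c < n_chunks; ++c) {
        int off = c * k;
        uint64_t key = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          if (R[off + i] > 3) { ok = false; break; }
          key = (key << 2) | (uint64_t)R[off + i];
        }
        if (!ok) continue;             // chunk with N can never match exactly
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (auto& hit : it->second) {
          int t = hit.first;
          int s = hit.second - off;    // implied alignment start (0-based)
          int n_starts = circular[t] ? tlen[t] : tlen[t] - rlen + 1;
          if (s < 0 || s >= n_starts) continue;
          if ((int)(tenc[t].size()) < s + rlen) continue;
          int64_t id = (int64_t)t * 100000000LL + s;
          bool dup = false;
          for (int64_t v : seen) if (v == id) { dup = true; break; }
          if (dup) continue;
          seen.push_back(id);
          int mm = 0;
          const int* tp = tenc[t].data() + s;
          for (int i = 0; i < rlen; ++i) {
            if (tp[i] != R[i] || R[i] == 4) {
              if (++mm > max_mismatch) break;
            }
          }
          if (mm > max_mismatch || mm > second) continue;
          if (mm < best) {
            second = best; best = mm; nbest = 1;
            b_t = t; b_s = s; b_strand = strand == 0 ? '+' : '-';
          } else if (mm == best) {
            ++nbest; second = mm;
          } else if (mm < second) {
            second = mm;
          }
        }
      }
    }

    if (b_t < 0) {
      out_target[r] = NA_INTEGER; out_start[r] = NA_INTEGER;
      out_mm[r] = NA_INTEGER; out_nbest[r] = 0;
      out_second[r] = NA_INTEGER; out_strand[r] = NA_STRING;
    } else {
      out_target[r] = b_t + 1;
      out_start[r] = b_s + 1;           // 1-based; circular canonical by scan
      out_mm[r] = best;
      out_nbest[r] = nbest;
      out_second[r] = (second <= max_mismatch) ? second : NA_INTEGER;
      out_strand[r] = std::string(1, b_strand);
    }
  }

  CharacterVector tname(n_r);
  for (int r = 0; r < n_r; ++r)
    tname[r] = (out_target[r] == NA_INTEGER) ? NA_STRING
                                             : target_names[out_target[r] - 1];
  return DataFrame::create(
      _["target"] = tname, _["start"] = out_start, _["strand"] = out_strand,
      _["mismatches"] = out_mm, _["n_best"] = out_nbest,
      _["second_best_mismatches"] = out_second);
}

// Expand ungapped alignments into per-base pileup records.  Returns parallel
// vectors (position on the circle, observed base code, strand, quality,
// distance from the nearer read end) for bases meeting min_bq.
// [[Rcpp::export]]
List cpp_expand_pileup(CharacterVector seqs, IntegerVector quals_offset,
                       CharacterVector qual_strings,
                       IntegerVector starts, CharacterVector strands,
                       int genome_length, int min_bq) {
  long total = 0;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) total += LENGTH(STRING_ELT(seqs, i));
  std::vector<int> pos; pos.reserve(total);
  std::vector<int> base; base.reserve(total);
  std::vector<int> fwd; fwd.reserve(total);
  std::vector<int> qv; qv.reserve(total);
  std::vector<int> dist; dist.reserve(total);

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(qual_strings[i]);
    int L = (int)s.size();
    bool plus = (as<std::string>(strands[i]) == "+");
    int st = starts[i];
    for (int j = 0; j < L; ++j) {
      int quality = (int)q[j] - quals_offset[0];
      if (quality < min_bq) continue;
      // j indexes the reference-forward orientation of the stored sequence
      int b = enc(s[j]);
      if (b == 4) continue;
      int p = ((st - 1 + j) % genome_length) + 1;
      // distance from nearer read end, in read orientation (symmetric)
      int d = std::min(j, L - 1 - j);
      pos.push_back(p); base.push_back(b); fwd.push_back(plus ? 1 : 0);
      qv.push_back(quality); dist.push_back(d);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["base"] = wrap(base),
                      _["fwd"] = wrap(fwd), _["qual"] = wrap(qv),
                      _["end_dist"] = wrap(dist));
}
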