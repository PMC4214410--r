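// Sequence kernels: k-mer counting, seed-and-extend read mapping with pileup,
// suffix-prefix overlap discovery, banded affine segment alignment, anchor
// extraction for whole-genome comparison, and the MITE structural scanner.
// All functions are deterministic; randomness stays on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char code2base(int c) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[c & 3];
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// ------------------------------------------------------------------
// k-mer spectrum
// ------------------------------------------------------------------

// Count canonical k-mers over a set of reads; k <= 31. Returns the depth
// histogram (depth -> number of distinct k-mers at that depth).
// [[Rcpp::export]]
List cpp_kmer_spectrum(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int L = LENGTH(STRING_ELT(reads, r));
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < L; ++i) {
      int c = base2code(s[i]);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rc);
        ++counts[canon];
      }
    }
  }
  // histogram
  std::unordered_map<uint32_t, double> hist;
  for (auto& kv : counts) hist[kv.second] += 1.0;
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (auto& kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector d(depths.size());
  NumericVector n(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    d[i] = (int)depths[i];
    n[i] = hist[depths[i]];
  }
  return List::create(_["depth"] = d, _["count"] = n);
}

// ------------------------------------------------------------------
// seed index over one or more reference sequences
// ------------------------------------------------------------------

struct SeedIndex {
  std::unordered_map<uint64_t, int64_t> map; // packed (ref << 40 | pos), -1 = ambiguous
  int k;
};

static void build_index(SeedIndex& idx, const std::vector<std::string>& refs, int k) {
  idx.k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  size_t total = 0;
  for (auto& r : refs) total += r.size();
  idx.map.reserve(total);
  for (size_t ri = 0; ri < refs.size(); ++ri) {
    const std::string& s = refs[ri];
    uint64_t fwd = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base2code(s[i]);
      if (c < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        int64_t packed = ((int64_t)ri << 40) | (int64_t)(i - k + 1);
        auto it = idx.map.find(fwd);
        if (it == idx.map.end()) idx.map[fwd] = packed;
        else it->second = -1;
      }
    }
  }
}

// look up the k-mer of `read` starting at offset o; returns packed pos or -2
// (absent) / -1 (ambiguous)
static int64_t seed_lookup(const SeedIndex& idx, const std::string& read, int o) {
  const int k = idx.k;
  if (o < 0 || o + k > (int)read.size()) return -2;
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(read[o + i]);
    if (c < 0) return -2;
    v = (v << 2) | (uint64_t)c;
  }
  auto it = idx.map.find(v);
  if (it == idx.map.end()) return -2;
  return it->second;
}

static inline int hamming_capped(const char* a, const char* b, int n, int cap) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) { if (++mm > cap) return mm; }
  }
  return mm;
}

// ------------------------------------------------------------------
// read placement (link evidence / BAC ends): ungapped, unique-seed
// ------------------------------------------------------------------

struct Placement {
  int ref;      // -1 unmapped
  int pos;      // 0-based start on ref
  int strand;   // +1 / -1
  int mm;
};

static Placement place_read_ungapped(const SeedIndex& idx,
                                     const std::vector<std::string>& refs,
                                     const std::string& read, int max_mm) {
  Placement best; best.ref = -1; best.pos = 0; best.strand = 0; best.mm = 1 << 30;
  const int k = idx.k;
  const int L = (int)read.size();
  for (int strand = 0; strand < 2; ++strand) {
    std::string r = strand == 0 ? read : revcomp_str(read);
    // try a few seed offsets until one yields a unique hit
    int offsets[6] = {0, L - k, k, L - 2 * k, 2 * k, (L - k) / 2};
    for (int oi = 0; oi < 6; ++oi) {
      int o = offsets[oi];
      if (o < 0 || o + k > L) continue;
      int64_t p = seed_lookup(idx, r, o);
      if (p < 0) continue; // absent or ambiguous seed: try another offset
      {
        int ri = (int)(p >> 40);
        int pos = (int)(p & ((1LL << 40) - 1)) - o;
        if (pos < 0 || pos + L > (int)refs[ri].size()) continue;
        int mm = hamming_capped(refs[ri].c_str() + pos, r.c_str(), L, max_mm);
        if (mm <= max_mm) {
          if (mm < best.mm) {
            best.ref = ri; best.pos = pos; best.strand = strand == 0 ? 1 : -1; best.mm = mm;
          } else if (mm == best.mm &&
                     !(best.ref == ri && best.pos == pos &&
                       best.strand == (strand == 0 ? 1 : -1))) {
            best.ref = -1; // ambiguous placement across strands
          }
          break;
        }
      }
    }
  }
  if (best.ref < 0) { best.ref = -1; best.strand = 0; }
  return best;
}

// [[Rcpp::export]]
List cpp_map_placements(CharacterVector ref_seqs, CharacterVector reads,
                        int k, int max_mm) {
  std::vector<std::string> refs(ref_seqs.size());
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);
  SeedIndex idx;
  build_index(idx, refs, k);
  R_xlen_t n = reads.size();
  IntegerVector ref_out(n), pos_out(n), strand_out(n), mm_out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    Placement p = place_read_ungapped(idx, refs, rd, max_mm);
    if (p.ref < 0) {
      ref_out[i] = NA_INTEGER; pos_out[i] = NA_INTEGER;
      strand_out[i] = NA_INTEGER; mm_out[i] = NA_INTEGER;
    } else {
      ref_out[i] = p.ref + 1; pos_out[i] = p.pos + 1;
      strand_out[i] = p.strand; mm_out[i] = p.mm;
    }
  }
  return List::create(_["ref"] = ref_out, _["pos"] = pos_out,
                      _["strand"] = strand_out, _["mm"] = mm_out);
}

// ------------------------------------------------------------------
// pileup over a single reference with gapped (two-seed) placement
// ------------------------------------------------------------------

struct GappedAln {
  bool ok;
  int start;        // 0-based ref start of the read's left part
  int strand;       // +1 / -1
  int mm;
  int split;        // read offset where the indel occurs (0 = none meaningful)
  int delta;        // ref advance minus read advance: >0 deletion-in-read, <0 insertion
};

// align one oriented read string against ref using seeds; allow one indel
static GappedAln align_read_oriented(const SeedIndex& idx, const std::string& ref,
                                     const std::string& r, int max_mm, int max_indel) {
  GappedAln a; a.ok = false; a.delta = 0; a.split = 0; a.mm = 0; a.strand = 1;
  const int k = idx.k;
  const int L = (int)r.size();
  const int Lr = (int)ref.size();
  // find a unique left seed and a unique right seed
  int64_t pl = -2, pr = -2; int ol = -1, orr = -1;
  for (int o = 0; o + k <= L && o <= 4 * 8; o += 8) {
    int64_t p = seed_lookup(idx, r, o);
    if (p >= 0) { pl = p; ol = o; break; }
  }
  for (int o = L - k; o >= 0 && o >= L - k - 4 * 8; o -= 8) {
    int64_t p = seed_lookup(idx, r, o);
    if (p >= 0) { pr = p; orr = o; break; }
  }
  int sL = (pl >= 0) ? (int)(pl & ((1LL << 40) - 1)) - ol : INT_MIN;
  int sR = (pr >= 0) ? (int)(pr & ((1LL << 40) - 1)) - orr : INT_MIN;

  if (sL == INT_MIN && sR == INT_MIN) return a;
  if (sL == INT_MIN) sL = sR;
  if (sR == INT_MIN) sR = sL;

  if (sL == sR) { // ungapped
    if (sL < 0 || sL + L > Lr) return a;
    int mm = hamming_capped(ref.c_str() + sL, r.c_str(), L, max_mm);
    if (mm > max_mm) return a;
    a.ok = true; a.start = sL; a.mm = mm; a.delta = 0;
    return a;
  }
  int delta = sR - sL;
  if (delta == 0 || std::abs(delta) > max_indel) return a;
  if (sL < 0 || sL + L + std::max(0, delta) > Lr) return a;
  // prefix mismatches pm[i]: r[0..i) vs ref[sL..)
  std::vector<int> pm(L + 1, 0), sm(L + 1, 0);
  for (int i = 0; i < L; ++i)
    pm[i + 1] = pm[i] + ((sL + i < Lr && r[i] == ref[sL + i]) ? 0 : 1);
  if (delta > 0) {
    // deletion in read of `delta` ref bases at split i
    for (int i = L - 1; i >= 0; --i) {
      int rp = sL + delta + i;
      sm[i] = sm[i + 1] + ((rp >= 0 && rp < Lr && r[i] == ref[rp]) ? 0 : 1);
    }
    int besti = -1, bestmm = 1 << 30;
    for (int i = k; i <= L - k; ++i) {
      int mm = pm[i] + sm[i];
      if (mm < bestmm) { bestmm = mm; besti = i; }
    }
    if (besti < 0 || bestmm > max_mm) return a;
    a.ok = true; a.start = sL; a.mm = bestmm; a.split = besti; a.delta = delta;
    return a;
  } else {
    int m = -delta; // insertion length in read
    for (int i = L - 1; i >= 0; --i) {
      int rp = sL + delta + i;
      sm[i] = sm[i + 1] + ((rp >= 0 && rp < Lr && r[i] == ref[rp]) ? 0 : 1);
    }
    int besti = -1, bestmm = 1 << 30;
    for (int i = k; i + m <= L - k; ++i) {
      int mm = pm[i] + sm[i + m];
      if (mm < bestmm) { bestmm = mm; besti = i; }
    }
    if (besti < 0 || bestmm > max_mm) return a;
    a.ok = true; a.start = sL; a.mm = bestmm; a.split = besti; a.delta = delta;
    return a;
  }
}

// Pileup of reads against one reference. Returns per-position base counts
// (4 x L matrix) and aggregated indel observations.
// [[Rcpp::export]]
List cpp_pileup(std::string ref, CharacterVector reads, int k, int max_mm,
                int max_indel) {
  std::vector<std::string> refs(1, ref);
  SeedIndex idx;
  build_index(idx, refs, k);
  const int Lr = (int)ref.size();
  IntegerMatrix counts(4, Lr);
  int* cptr = INTEGER(counts);
  std::unordered_map<int64_t, int> indels; // key pos*64 + (len+31); len signed
  int n_mapped = 0, n_unmapped = 0, n_gapped = 0;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    GappedAln best = align_read_oriented(idx, ref, rd, max_mm, max_indel);
    if (!best.ok || best.mm > 0) {
      std::string rc = revcomp_str(rd);
      GappedAln rv = align_read_oriented(idx, ref, rc, max_mm, max_indel);
      if (rv.ok && (!best.ok || rv.mm < best.mm)) { best = rv; rd = rc; }
    }
    if (!best.ok) { ++n_unmapped; continue; }
    ++n_mapped;
    const int L = (int)rd.size();
    if (best.delta == 0) {
      for (int j = 0; j < L; ++j) {
        int c = base2code(rd[j]);
        int rp = best.start + j;
        if (c >= 0 && rp >= 0 && rp < Lr) ++cptr[4 * rp + c];
      }
    } else {
      ++n_gapped;
      int split = best.split, delta = best.delta;
      for (int j = 0; j < split; ++j) {
        int c = base2code(rd[j]);
        int rp = best.start + j;
        if (c >= 0 && rp >= 0 && rp < Lr) ++cptr[4 * rp + c];
      }
      int jstart = (delta < 0) ? split - delta : split;
      for (int j = jstart; j < L; ++j) {
        int c = base2code(rd[j]);
        int rp = best.start + delta + j;
        if (c >= 0 && rp >= 0 && rp < Lr) ++cptr[4 * rp + c];
      }
      int ipos = best.start + split; // 0-based ref position of event
      int64_t key = (int64_t)ipos * 64 + (delta + 31);
      ++indels[key];
    }
  }

  std::vector<int64_t> keys;
  keys.reserve(indels.size());
  for (auto& kv : indels) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector ipos(keys.size()), ilen(keys.size()), icount(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    ipos[i] = (int)(keys[i] / 64) + 1;       // 1-based
    ilen[i] = (int)(keys[i] % 64) - 31;      // >0 deletion, <0 insertion
    icount[i] = indels[keys[i]];
  }
  return List::create(_["counts"] = counts,
                      _["indel_pos"] = ipos, _["indel_len"] = ilen,
                      _["indel_count"] = icount,
                      _["n_mapped"] = n_mapped, _["n_unmapped"] = n_unmapped,
                      _["n_gapped"] = n_gapped);
}

// ------------------------------------------------------------------
// suffix-prefix overlap discovery
// ------------------------------------------------------------------

// best suffix(A)-prefix(B) overlap with Hamming error rate <= max_err
static bool best_suffix_prefix(const std::string& A, const std::string& B,
                               int min_len, double max_err, int seed_len,
                               int& olen_out, double& ident_out) {
  const int la = (int)A.size(), lb = (int)B.size();
  const int maxo = std::min(la, lb);
  if (maxo < min_len || min_len < seed_len) return false;
  // index seed k-mers of B's prefix region
  std::unordered_map<uint64_t, std::vector<int> > bidx;
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  {
    uint64_t v = 0; int valid = 0;
    int lim = maxo;
    for (int i = 0; i < lim; ++i) {
      int c = base2code(B[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len) bidx[v].push_back(i - seed_len + 1);
    }
  }
  std::vector<char> seen(maxo + 1, 0);
  std::vector<int> candidates;
  {
    uint64_t v = 0; int valid = 0;
    for (int i = la - maxo; i < la; ++i) {
      int c = base2code(A[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len) {
        auto it = bidx.find(v);
        if (it == bidx.end()) continue;
        int pa = i - seed_len + 1; // start of seed in A
        for (int pb : it->second) {
          int olen = (la - pa) + pb;
          if (olen >= min_len && olen <= maxo && !seen[olen]) {
            seen[olen] = 1;
            candidates.push_back(olen);
          }
        }
      }
    }
  }
  std::sort(candidates.begin(), candidates.end(), std::greater<int>());
  for (int olen : candidates) {
    int cap = (int)(max_err * olen);
    int mm = hamming_capped(A.c_str() + la - olen, B.c_str(), olen, cap);
    if (mm <= cap) {
      olen_out = olen;
      ident_out = 1.0 - (double)mm / olen;
      return true;
    }
  }
  return false;
}

// All dovetail overlaps between contigs, both strands. Ends: 1 = head (5'),
// 2 = tail (3'). Records returned once per unordered pair/end combination.
// [[Rcpp::export]]
List cpp_find_overlaps(CharacterVector seqs, int min_len, double max_err,
                       int seed_len) {
  int n = (int)seqs.size();
  std::vector<std::string> s(n), rc(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp_str(s[i]);
  }
  std::vector<int> va, vb, ea, eb, len;
  std::vector<double> ident;
  auto add = [&](int a, int b, int aend, int bend, int olen, double id) {
    va.push_back(a + 1); vb.push_back(b + 1);
    ea.push_back(aend); eb.push_back(bend);
    len.push_back(olen); ident.push_back(id);
  };
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int olen; double id;
      // a.tail - b.head : suffix(a) vs prefix(b)
      if (best_suffix_prefix(s[a], s[b], min_len, max_err, seed_len, olen, id))
        add(a, b, 2, 1, olen, id);
      // a.tail - b.tail : suffix(a) vs prefix(rc(b))
      if (best_suffix_prefix(s[a], rc[b], min_len, max_err, seed_len, olen, id))
        add(a, b, 2, 2, olen, id);
      // a.head - b.head : suffix(rc(a)) vs prefix(b)
      if (best_suffix_prefix(rc[a], s[b], min_len, max_err, seed_len, olen, id))
        add(a, b, 1, 1, olen, id);
      // a.head - b.tail : suffix(b) vs prefix(a)
      if (best_suffix_prefix(s[b], s[a], min_len, max_err, seed_len, olen, id))
        add(a, b, 1, 2, olen, id);
    }
  }
  return List::create(_["a"] = wrap(va), _["b"] = wrap(vb),
                      _["a_end"] = wrap(ea), _["b_end"] = wrap(eb),
                      _["length"] = wrap(len), _["identity"] = wrap(ident));
}

// Best local containment of `query` in `target` (either strand), approximated
// by the best ungapped extension around shared seeds. Returns the fraction of
// the query covered and the identity of that aligned stretch.
// [[Rcpp::export]]
List cpp_containment(std::string query, CharacterVector targets, int seed_len,
                     double max_err) {
  int nt = (int)targets.size();
  NumericVector cover(nt), identity(nt);
  const int lq = (int)query.size();
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  // seed positions of query
  std::unordered_map<uint64_t, int> qidx;
  {
    uint64_t v = 0; int valid = 0;
    for (int i = 0; i < lq; ++i) {
      int c = base2code(query[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len)
        if (qidx.find(v) == qidx.end()) qidx[v] = i - seed_len + 1;
    }
  }
  for (int t = 0; t < nt; ++t) {
    std::string T = as<std::string>(targets[t]);
    double best_cov = 0, best_id = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string Ts = strand == 0 ? T : revcomp_str(T);
      const int lt = (int)Ts.size();
      // collect diagonal votes
      std::unordered_map<int, int> diag;
      uint64_t v = 0; int valid = 0;
      for (int i = 0; i < lt; ++i) {
        int c = base2code(Ts[i]);
        if (c < 0) { valid = 0; v = 0; continue; }
        v = ((v << 2) | (uint64_t)c) & mask;
        if (++valid >= seed_len) {
          auto it = qidx.find(v);
          if (it != qidx.end()) ++diag[(i - seed_len + 1) - it->second];
        }
      }
      for (auto& kv : diag) {
        if (kv.second < 2) continue;
        int off = kv.first; // query pos q maps to target pos q + off
        int q0 = std::max(0, -off), q1 = std::min(lq, lt - off);
        if (q1 - q0 < seed_len) continue;
        int n = q1 - q0;
        int cap = (int)(max_err * n) + 1;
        int mm = hamming_capped(query.c_str() + q0, Ts.c_str() + q0 + off, n, cap);
        double id = 1.0 - (double)mm / n;
        double cov = (double)n / lq;
        if (id >= 1.0 - max_err &&
            (cov > best_cov || (cov == best_cov && id > best_id))) {
          best_cov = cov; best_id = id;
        }
      }
    }
    cover[t] = best_cov; identity[t] = best_id;
  }
  return List::create(_["coverage"] = cover, _["identity"] = identity);
}

// ------------------------------------------------------------------
// anchors for whole-genome comparison
// ------------------------------------------------------------------

// k-mers unique in A and unique in B, matched exactly (forward strand) or by
// reverse complement. Returns 1-based positions.
// [[Rcpp::export]]
List cpp_unique_anchors(std::string A, std::string B, int k) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  std::unordered_map<uint64_t, int64_t> amap; // canonical kmer -> pos (or -1 dup); sign bit of pos unused
  amap.reserve(A.size());
  std::vector<int8_t> astrand; // not needed per key; store orientation with pos
  {
    uint64_t fwd = 0, rcv = 0; int valid = 0;
    for (size_t i = 0; i < A.size(); ++i) {
      int c = base2code(A[i]);
      if (c < 0) { valid = 0; fwd = 0; rcv = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rcv);
        int64_t enc = (((int64_t)(i - k + 1)) << 1) | (fwd <= rcv ? 0 : 1);
        auto it = amap.find(canon);
        if (it == amap.end()) amap[canon] = enc; else it->second = -1;
      }
    }
  }
  // scan B: first pass marks duplicates within B
  std::unordered_map<uint64_t, int64_t> bmap;
  bmap.reserve(B.size());
  {
    uint64_t fwd = 0, rcv = 0; int valid = 0;
    for (size_t i = 0; i < B.size(); ++i) {
      int c = base2code(B[i]);
      if (c < 0) { valid = 0; fwd = 0; rcv = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rcv);
        auto ita = amap.find(canon);
        if (ita == amap.end() || ita->second < 0) continue;
        int64_t enc = (((int64_t)(i - k + 1)) << 1) | (fwd <= rcv ? 0 : 1);
        auto it = bmap.find(canon);
        if (it == bmap.end()) bmap[canon] = enc; else it->second = -1;
      }
    }
  }
  std::vector<int> pa, pb, strand;
  pa.reserve(bmap.size());
  for (auto& kv : bmap) {
    if (kv.second < 0) continue;
    int64_t ea = amap[kv.first];
    if (ea < 0) continue;
    int posa = (int)(ea >> 1), oa = (int)(ea & 1);
    int posb = (int)(kv.second >> 1), ob = (int)(kv.second & 1);
    pa.push_back(posa + 1);
    pb.push_back(posb + 1);
    strand.push_back(oa == ob ? 1 : -1);
  }
  return List::create(_["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb),
                      _["strand"] = wrap(strand));
}

// ------------------------------------------------------------------
// banded affine global alignment of short segment pairs
// ------------------------------------------------------------------

static const double MMCOST = 3.0, GOPEN = 5.0, GEXT = 1.0;
static const double INF = 1e18;

// Align segments a[i] vs b[i]; returns per-segment SNV/indel events.
// SNV offsets are 0-based within each segment. Indel length signed:
// >0 = deletion in b (bases of a unmatched), <0 insertion in b.
// [[Rcpp::export]]
List cpp_align_segments(CharacterVector av, CharacterVector bv, int band_extra,
                        int max_indel_report) {
  std::vector<int> seg_id;
  std::vector<int> snv_seg, snv_off_a, snv_off_b;
  std::vector<char> snv_ref, snv_alt;
  std::vector<int> ind_seg, ind_off_a, ind_len;
  std::vector<double> aligned(av.size(), 0.0);

  for (R_xlen_t si = 0; si < av.size(); ++si) {
    std::string a = as<std::string>(av[si]);
    std::string b = as<std::string>(bv[si]);
    const int la = (int)a.size(), lb = (int)b.size();
    if (la == 0 && lb == 0) continue;
    if (la == 0 || lb == 0) {
      int l = la > 0 ? la : -lb;
      ind_seg.push_back((int)si + 1); ind_off_a.push_back(0); ind_len.push_back(l);
      continue;
    }
    int w = std::abs(la - lb) + band_extra;
    // skip pathological segments (large structural differences); they are
    // reported as unaligned rather than forced through the DP
    if ((double)(la + 1) * (2.0 * w + 1) > 3e7) continue;
    auto inband = [&](int i, int j) { return std::abs(j - i) <= w; };
    // matrices M (match/mismatch), X (gap in b, consuming a), Y (gap in a, consuming b)
    std::vector<std::vector<double> > M(la + 1), X(la + 1), Y(la + 1);
    for (int i = 0; i <= la; ++i) {
      M[i].assign(2 * w + 1, INF);
      X[i].assign(2 * w + 1, INF);
      Y[i].assign(2 * w + 1, INF);
    }
    auto col = [&](int i, int j) { return j - i + w; };
    M[0][col(0, 0)] = 0;
    for (int j = 1; j <= lb && inband(0, j); ++j)
      Y[0][col(0, j)] = GOPEN + GEXT * j;
    for (int i = 1; i <= la; ++i) {
      if (inband(i, 0)) X[i][col(i, 0)] = GOPEN + GEXT * i;
      int jlo = std::max(1, i - w), jhi = std::min(lb, i + w);
      for (int j = jlo; j <= jhi; ++j) {
        int c = col(i, j);
        double sub = (a[i - 1] == b[j - 1]) ? 0.0 : MMCOST;
        // M
        double best = INF;
        if (inband(i - 1, j - 1)) {
          int pc = col(i - 1, j - 1);
          best = std::min(std::min(M[i - 1][pc], X[i - 1][pc]), Y[i - 1][pc]);
        }
        if (best < INF) M[i][c] = best + sub;
        // X: gap in b, consume a[i-1]
        if (inband(i - 1, j)) {
          int pc = col(i - 1, j);
          double vo = std::min(M[i - 1][pc], Y[i - 1][pc]) + GOPEN + GEXT;
          double ve = X[i - 1][pc] + GEXT;
          X[i][c] = std::min(vo, ve);
        }
        // Y: gap in a, consume b[j-1]
        if (inband(i, j - 1)) {
          int pc = col(i, j - 1);
          double vo = std::min(M[i][pc], X[i][pc]) + GOPEN + GEXT;
          double ve = Y[i][pc] + GEXT;
          Y[i][c] = std::min(vo, ve);
        }
      }
    }
    // backtrack
    int i = la, j = lb;
    int state; // 0=M 1=X 2=Y
    {
      int c = col(i, j);
      double m = M[i][c], x = X[i][c], y = Y[i][c];
      state = (m <= x && m <= y) ? 0 : (x <= y ? 1 : 2);
    }
    int gap_run = 0, gap_sign = 0, gap_start_a = 0;
    double ncols = 0;
    auto flush_gap = [&]() {
      if (gap_run > 0) {
        if (gap_run <= max_indel_report || max_indel_report <= 0) {
          ind_seg.push_back((int)si + 1);
          ind_off_a.push_back(gap_start_a);
          ind_len.push_back(gap_sign * gap_run);
        }
        gap_run = 0; gap_sign = 0;
      }
    };
    while (i > 0 || j > 0) {
      int c = col(i, j);
      if (state == 0) {
        flush_gap();
        // came from min of M/X/Y at (i-1, j-1)
        ncols += 1;
        if (a[i - 1] != b[j - 1]) {
          snv_seg.push_back((int)si + 1);
          snv_off_a.push_back(i - 1);
          snv_off_b.push_back(j - 1);
          snv_ref.push_back(a[i - 1]);
          snv_alt.push_back(b[j - 1]);
        }
        int pc = col(i - 1, j - 1);
        double target = M[i][c] - ((a[i - 1] == b[j - 1]) ? 0.0 : MMCOST);
        --i; --j;
        if (std::abs(M[i][pc] - target) < 1e-9) state = 0;
        else if (std::abs(X[i][pc] - target) < 1e-9) state = 1;
        else state = 2;
      } else if (state == 1) {
        // gap in b: a[i-1] unmatched (deletion in b)
        if (gap_sign != 1) { flush_gap(); gap_sign = 1; }
        ++gap_run; gap_start_a = i - 1;
        int pc = col(i - 1, j);
        double cur = X[i][c];
        --i;
        if (std::abs(X[i][pc] + GEXT - cur) < 1e-9) state = 1;
        else if (std::abs(M[i][pc] + GOPEN + GEXT - cur) < 1e-9) state = 0;
        else state = 2;
      } else {
        // gap in a: b[j-1] unmatched (insertion in b)
        if (gap_sign != -1) { flush_gap(); gap_sign = -1; }
        ++gap_run; gap_start_a = i;
        int pc = col(i, j - 1);
        double cur = Y[i][c];
        --j;
        if (std::abs(Y[i][pc] + GEXT - cur) < 1e-9) state = 2;
        else if (std::abs(M[i][pc] + GOPEN + GEXT - cur) < 1e-9) state = 0;
        else state = 1;
      }
    }
    flush_gap();
    aligned[si] = ncols;
  }
  CharacterVector refv(snv_ref.size()), altv(snv_alt.size());
  for (size_t q = 0; q < snv_ref.size(); ++q) {
    refv[q] = std::string(1, snv_ref[q]);
    altv[q] = std::string(1, snv_alt[q]);
  }
  return List::create(
    _["snv_seg"] = wrap(snv_seg), _["snv_off_a"] = wrap(snv_off_a),
    _["snv_off_b"] = wrap(snv_off_b),
    _["snv_ref"] = refv, _["snv_alt"] = altv,
    _["ind_seg"] = wrap(ind_seg), _["ind_off_a"] = wrap(ind_off_a),
    _["ind_len"] = wrap(ind_len), _["aligned"] = wrap(aligned));
}

// ------------------------------------------------------------------
// MITE structural scanner
// ------------------------------------------------------------------

// Scan `s` for candidate elements [i, j) with terminal inverted repeats and a
// duplicated flanking target site. A TIR of extent t with m mismatches is
// accepted when m <= max_mm and t >= min_tir + mm_step * m. Candidates are
// returned unresolved; overlap resolution happens in R.
// [[Rcpp::export]]
List cpp_scan_mites(std::string s, int min_tir, int max_mm, int mm_step,
                    int min_len, int max_len, int min_tsd, int max_tsd) {
  const int n = (int)s.size();
  std::vector<int> start, end, tirlen, tirmm, tsdlen;
  for (int i = min_tsd; i + min_len + min_tsd <= n; ++i) {
    int jmax = std::min(n - min_tsd, i + max_len);
    for (int j = i + min_len; j <= jmax; ++j) {
      // TIR extent
      int len = j - i;
      int tmax = std::min(len / 2, 40);
      int mm = 0, best_t = 0, best_mm = 0;
      for (int t = 1; t <= tmax; ++t) {
        char lc = s[i + t - 1];
        char rc = comp_base(s[j - t]);
        if (lc != rc) {
          if (++mm > max_mm) break;
        } else if (t >= min_tir + mm_step * mm && t > best_t) {
          // a reportable TIR extent must end on a matching column
          best_t = t; best_mm = mm;
        }
      }
      if (best_t < min_tir) continue;
      // TSD: longest exact duplicated flank
      int best_tsd = 0;
      for (int L = max_tsd; L >= min_tsd; --L) {
        if (i - L < 0 || j + L > n) continue;
        bool ok = true;
        for (int q = 0; q < L; ++q)
          if (s[i - L + q] != s[j + q]) { ok = false; break; }
        if (ok) { best_tsd = L; break; }
      }
      if (best_tsd < min_tsd) continue;
      start.push_back(i + 1); // 1-based inclusive
      end.push_back(j);       // 1-based inclusive end
      tirlen.push_back(best_t);
      tirmm.push_back(best_mm);
      tsdlen.push_back(best_tsd);
    }
  }
  return List::create(_["start"] = wrap(start), _["end"] = wrap(end),
                      _["tir_len"] = wrap(tirlen), _["tir_mm"] = wrap(tirmm),
                      _["tsd_len"] = wrap(tsdlen));
}

// ------------------------------------------------------------------
// misc helpers used by the simulators
// ------------------------------------------------------------------

// Extract subsequences (1-based starts); reverse-complement where rc is TRUE.
// [[Rcpp::export]]
CharacterVector cpp_extract_subseqs(std::string genome, IntegerVector start,
                                    IntegerVector len, LogicalVector rc) {
  R_xlen_t n = start.size();
  CharacterVector out(n);
  const int L = (int)genome.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = start[i] - 1, l = len[i];
    if (s < 0 || l < 0 || s + l > L) stop("subsequence out of bounds");
    std::string sub = genome.substr(s, l);
    if (rc[i]) sub = revcomp_str(sub);
    out[i] = sub;
  }
  return out;
}

// Apply substitution errors in place: read read_idx[i] (1-based), position
// pos[i] (1-based), shift[i] in 1..3 selects one of the three other bases.
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector reads, IntegerVector read_idx,
                                 IntegerVector pos, IntegerVector shift) {
  CharacterVector out = clone(reads);
  // group edits per read
  for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1;
    std::string s = as<std::string>(out[r]);
    int p = pos[i] - 1;
    if (p < 0 || p >= (int)s.size()) continue;
    int c = base2code(s[p]);
    if (c < 0) continue;
    s[p] = code2base((c + shift[i]) % 4);
    out[r] = s;
  }
  return out;
}
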