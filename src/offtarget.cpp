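// k-mismatch genome matching engines.
//
// Two independent code paths deliberately kept apart:
//  * exact engine  : exhaustive scan of every genome window on both strands,
//                    early-exit Hamming counting (full sensitivity by
//                    construction).
//  * seeded engine : pigeonhole seed partition. Each query is split into
//                    max_mm + 1 contiguous seeds; any window within max_mm
//                    mismatches preserves at least one seed exactly, so a
//                    hash lookup of every genome substring of each seed
//                    length followed by Hamming verification is complete.
//
// Conventions: genome sequences are uppercase; any non-ACGT genome base
// (including N) matches nothing. Coordinates returned are 1-based closed.
// A minus-strand match means the reverse complement of the plus-strand
// window equals the query within the mismatch budget.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
    case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;  case 'N': return 15;
    default:  return -1;
  }
}

// genome-side mask: only unambiguous bases carry a bit, so genome N never
// satisfies any pattern letter (N "matches nothing")
static inline int base_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default:  return 0;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static std::vector<int> pam_masks(const std::string& pam) {
  std::vector<int> m(pam.size());
  for (size_t i = 0; i < pam.size(); ++i) {
    int b = iupac_mask(pam[i]);
    if (b < 0) stop("PAM pattern contains a non-IUPAC letter: %s", pam);
    m[i] = b;
  }
  return m;
}

// reverse-complement of an IUPAC mask vector: reverse order, swap A<->T and
// C<->G bits
static std::vector<int> rc_masks(const std::vector<int>& m) {
  std::vector<int> r(m.rbegin(), m.rend());
  for (auto& x : r) {
    int a = (x & 1) != 0, c = (x & 2) != 0, g = (x & 4) != 0, t = (x & 8) != 0;
    x = (t ? 1 : 0) | (g ? 2 : 0) | (c ? 4 : 0) | (a ? 8 : 0);
  }
  return r;
}

// does the PAM pattern sit at 0-based position p (fully in bounds)?
static inline bool pam_at(const std::string& seq, long p, const std::vector<int>& masks) {
  if (p < 0 || p + (long)masks.size() > (long)seq.size()) return false;
  for (size_t j = 0; j < masks.size(); ++j)
    if ((base_mask(seq[p + j]) & masks[j]) == 0) return false;
  return true;
}

struct MatchRec {
  int query;   // 1-based query index
  int chrom;   // 1-based chromosome index
  long start;  // 1-based window start
  int strand;  // 0 = plus, 1 = minus
  int mm;
};

static DataFrame to_frame(const std::vector<MatchRec>& recs) {
  int n = recs.size();
  IntegerVector query(n), chrom(n), start(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    query[i]  = recs[i].query;
    chrom[i]  = recs[i].chrom;
    start[i]  = (int)recs[i].start;
    strand[i] = recs[i].strand == 0 ? "+" : "-";
    mm[i]     = recs[i].mm;
  }
  return DataFrame::create(_["query"] = query, _["chrom"] = chrom,
                           _["start"] = start, _["strand"] = strand,
                           _["mm"] = mm, _["stringsAsFactors"] = false);
}

// PAM check for a match: on the plus strand the PAM follows the window; a
// minus-strand match needs the reverse-complemented PAM immediately 5' of
// the window on the plus strand.
static inline bool match_pam_ok(const std::string& seq, long i, int W, int strand,
                                const std::vector<int>& fwd, const std::vector<int>& rc) {
  if (strand == 0) return pam_at(seq, i + W, fwd);
  return pam_at(seq, i - (long)rc.size(), rc);
}

// [[Rcpp::export]]
DataFrame cpp_match_exact(CharacterVector chrom_seqs, CharacterVector queries,
                          int max_mm, std::string pam, bool pam_required) {
  const int nq = queries.size();
  if (nq == 0) return to_frame({});
  std::vector<std::string> fwd(nq), rev(nq);
  for (int q = 0; q < nq; ++q) {
    fwd[q] = as<std::string>(queries[q]);
    rev[q] = revcomp(fwd[q]);
  }
  const int W = fwd[0].size();
  for (int q = 0; q < nq; ++q)
    if ((int)fwd[q].size() != W) stop("all query sequences must have the same length");
  std::vector<int> pmf = pam_masks(pam);
  std::vector<int> pmr = rc_masks(pmf);
  std::vector<MatchRec> out;

  for (int c = 0; c < chrom_seqs.size(); ++c) {
    const std::string seq = as<std::string>(chrom_seqs[c]);
    const long L = seq.size();
    for (long i = 0; i + W <= L; ++i) {
      for (int q = 0; q < nq; ++q) {
        // plus strand
        int mm = 0;
        for (int j = 0; j < W; ++j) {
          if (seq[i + j] != fwd[q][j] || base_mask(seq[i + j]) == 0) {
            if (++mm > max_mm) break;
          }
        }
        if (mm <= max_mm &&
            (!pam_required || match_pam_ok(seq, i, W, 0, pmf, pmr)))
          out.push_back({q + 1, c + 1, i + 1, 0, mm});
        // minus strand: window must equal revcomp(query) on the plus strand
        mm = 0;
        for (int j = 0; j < W; ++j) {
          if (seq[i + j] != rev[q][j] || base_mask(seq[i + j]) == 0) {
            if (++mm > max_mm) break;
          }
        }
        if (mm <= max_mm &&
            (!pam_required || match_pam_ok(seq, i, W, 1, pmf, pmr)))
          out.push_back({q + 1, c + 1, i + 1, 1, mm});
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return to_frame(out);
}

// [[Rcpp::export]]
DataFrame cpp_match_seeded(CharacterVector chrom_seqs, CharacterVector queries,
                           int max_mm, std::string pam, bool pam_required) {
  const int nq = queries.size();
  if (nq == 0) return to_frame({});
  std::vector<std::string> pat;  // 2*nq patterns: fwd then matching rc
  pat.reserve(2 * nq);
  for (int q = 0; q < nq; ++q) pat.push_back(as<std::string>(queries[q]));
  for (int q = 0; q < nq; ++q) pat.push_back(revcomp(pat[q]));
  const int W = pat[0].size();
  for (auto& p : pat)
    if ((int)p.size() != W) stop("all query sequences must have the same length");
  std::vector<int> pmf = pam_masks(pam);
  std::vector<int> pmr = rc_masks(pmf);

  // pigeonhole partition of [0, W) into max_mm + 1 balanced chunks
  const int nseed = max_mm + 1;
  std::vector<int> off(nseed), len(nseed);
  {
    int base = W / nseed, extra = W % nseed, pos = 0;
    for (int s = 0; s < nseed; ++s) {
      len[s] = base + (s < extra ? 1 : 0);
      off[s] = pos;
      pos += len[s];
    }
  }
  // seed index: seed string -> list of (pattern index, seed slot)
  struct Loc { int p, s; };
  std::unordered_map<std::string, std::vector<Loc>> index;
  index.reserve(2 * nq * nseed);
  for (int p = 0; p < (int)pat.size(); ++p)
    for (int s = 0; s < nseed; ++s)
      index[pat[p].substr(off[s], len[s])].push_back({p, s});

  // distinct seed lengths to probe at each genome position
  std::vector<int> probe_lens;
  for (int s = 0; s < nseed; ++s)
    if (std::find(probe_lens.begin(), probe_lens.end(), len[s]) == probe_lens.end())
      probe_lens.push_back(len[s]);

  std::vector<MatchRec> out;
  std::unordered_map<uint64_t, int> seen;  // dedupe (pattern, window) pairs

  for (int c = 0; c < chrom_seqs.size(); ++c) {
    const std::string seq = as<std::string>(chrom_seqs[c]);
    const long L = seq.size();
    seen.clear();
    std::string key;
    for (long i = 0; i < L; ++i) {
      for (int pl : probe_lens) {
        if (i + pl > L) continue;
        key.assign(seq, i, pl);
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (const Loc& loc : it->second) {
          if (len[loc.s] != pl) continue;
          long w = i - off[loc.s];  // candidate window start
          if (w < 0 || w + W > L) continue;
          uint64_t id = ((uint64_t)loc.p << 40) | (uint64_t)w;
          if (seen.count(id)) continue;
          seen[id] = 1;
          const std::string& P = pat[loc.p];
          int mm = 0;
          for (int j = 0; j < W; ++j) {
            if (seq[w + j] != P[j] || base_mask(seq[w + j]) == 0) {
              if (++mm > max_mm) break;
            }
          }
          if (mm > max_mm) continue;
          int strand = loc.p < nq ? 0 : 1;
          int q = strand == 0 ? loc.p : loc.p - nq;
          if (pam_required && !match_pam_ok(seq, w, W, strand, pmf, pmr)) continue;
          out.push_back({q + 1, c + 1, w + 1, strand, mm});
        }
      }
      if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return to_frame(out);
}
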