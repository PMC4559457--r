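// Seed-and-extend local read aligner with free soft clips.
//
// The reference is indexed by exact k-mers (2-bit encoded, k <= 31).  A read
// is aligned on both strands: every exact seed hit proposes a diagonal, and
// each distinct (contig, diagonal) is scored by an ungapped local extension
// (maximum-scoring contiguous segment along the diagonal; match/mismatch
// scores, clipped ends free).  Gapped extension is intentionally absent:
// junction discovery relies on soft clips, not indel alignment.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

struct RefIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<int> lexrank;  // rank of each contig name in lexicographic order
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> table;
};

// best local ungapped segment along one diagonal (Kadane), leftmost on ties
struct Segment {
  long score = -1;
  int start = 0;  // 0-based read offset of first aligned base
  int len = 0;
  int nm = 0;     // mismatches inside the segment
};

Segment extend_diagonal(const std::string& read, const std::string& ref,
                        long diag, int match, int mismatch) {
  const long rlen = (long)read.size(), flen = (long)ref.size();
  long lo = std::max(0L, -diag), hi = std::min(rlen, flen - diag);
  Segment best;
  long cur = 0, cur_start = lo;
  for (long i = lo; i < hi; ++i) {
    int a = base_code(read[i]), b = base_code(ref[diag + i]);
    int sc = (a >= 0 && a == b) ? match : mismatch;
    cur += sc;
    if (cur > best.score) {
      best.score = cur;
      best.start = (int)cur_start;
      best.len = (int)(i - cur_start + 1);
    }
    if (cur < 0) { cur = 0; cur_start = i + 1; }
  }
  if (best.score >= 0) {
    int nm = 0;
    for (int i = 0; i < best.len; ++i) {
      int a = base_code(read[best.start + i]);
      int b = base_code(ref[diag + best.start + i]);
      if (a < 0 || a != b) ++nm;
    }
    best.nm = nm;
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_index_reference(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  RefIndex* idx = new RefIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < names.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
  }
  // lexicographic ranks for deterministic tie-breaking
  std::vector<int> ord(idx->names.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return idx->names[a] < idx->names[b];
  });
  idx->lexrank.resize(ord.size());
  for (size_t r = 0; r < ord.size(); ++r) idx->lexrank[ord[r]] = (int)r;

  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    if ((int)s.size() < k) continue;  // caller warns about short contigs
    uint64_t kmer = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int code = base_code(s[i]);
      if (code < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)code) & mask;
      if (++run >= k) {
        idx->table[kmer].push_back({(int32_t)c, (int32_t)(i - k + 1)});
      }
    }
  }
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["names"] = wrap(idx->names),
                      _["lengths"] = [&] {
                        IntegerVector L(idx->seqs.size());
                        for (size_t i = 0; i < idx->seqs.size(); ++i)
                          L[i] = (int)idx->seqs[i].size();
                        return L;
                      }(),
                      _["n_kmers"] = (double)idx->table.size());
}

// [[Rcpp::export]]
DataFrame cpp_lookup_kmer(SEXP xp, std::string kmer) {
  XPtr<RefIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("kmer length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int code = base_code(c);
    if (code < 0)
      return DataFrame::create(_["ref_name"] = CharacterVector(0),
                               _["pos"] = IntegerVector(0));
    key = (key << 2) | (uint64_t)code;
  }
  auto it = idx->table.find(key);
  if (it == idx->table.end())
    return DataFrame::create(_["ref_name"] = CharacterVector(0),
                             _["pos"] = IntegerVector(0));
  const auto& hits = it->second;
  CharacterVector rn(hits.size());
  IntegerVector pos(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    rn[i] = idx->names[hits[i].first];
    pos[i] = hits[i].second + 1;
  }
  return DataFrame::create(_["ref_name"] = rn, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(SEXP xp, CharacterVector reads, int match,
                          int mismatch, int max_hits_per_kmer) {
  XPtr<RefIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int n = reads.size();

  IntegerVector out_ref(n), out_pos(n), out_clipl(n), out_mlen(n),
      out_clipr(n), out_score(n), out_nm(n);
  LogicalVector out_rev(n);

  std::vector<uint64_t> cand;  // packed (contig, diagonal) candidates
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev(fwd.rbegin(), fwd.rend());
    for (auto& c : rev) c = comp_base(c);

    long best_score = -1;
    int best_ref = -1, best_start = 0, best_len = 0, best_nm = 0;
    bool best_rev = false;
    long best_pos0 = 0;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand == 0 ? fwd : rev;
      if ((int)s.size() < k) continue;
      cand.clear();
      uint64_t kmer = 0;
      int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int code = base_code(s[i]);
        if (code < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)code) & mask;
        if (++run < k) continue;
        auto it = idx->table.find(kmer);
        if (it == idx->table.end()) continue;
        const auto& hits = it->second;
        if ((int)hits.size() > max_hits_per_kmer) continue;
        long qpos = (long)i - k + 1;
        for (const auto& h : hits) {
          long diag = (long)h.second - qpos;  // ref offset of read position 0
          // pack: contig in high bits, diagonal (offset to keep nonnegative)
          uint64_t key = ((uint64_t)h.first << 40) |
                         (uint64_t)(diag + (1L << 35));
          cand.push_back(key);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t key : cand) {
        int contig = (int)(key >> 40);
        long diag = (long)(key & ((1ULL << 40) - 1)) - (1L << 35);
        Segment seg = extend_diagonal(s, idx->seqs[contig], diag, match,
                                      mismatch);
        if (seg.score < 0) continue;
        long pos0 = diag + seg.start;
        bool better = false;
        if (seg.score > best_score) {
          better = true;
        } else if (seg.score == best_score) {
          if (idx->lexrank[contig] < idx->lexrank[best_ref]) better = true;
          else if (idx->lexrank[contig] == idx->lexrank[best_ref]) {
            if (pos0 < best_pos0) better = true;
            else if (pos0 == best_pos0 && best_rev && strand == 0)
              better = true;
          }
        }
        if (better) {
          best_score = seg.score;
          best_ref = contig;
          best_pos0 = pos0;
          best_start = seg.start;
          best_len = seg.len;
          best_nm = seg.nm;
          best_rev = (strand == 1);
        }
      }
    }

    if (best_score < 0) {
      out_ref[r] = NA_INTEGER;
      out_pos[r] = NA_INTEGER;
      out_clipl[r] = NA_INTEGER;
      out_mlen[r] = 0;
      out_clipr[r] = NA_INTEGER;
      out_score[r] = NA_INTEGER;
      out_nm[r] = NA_INTEGER;
      out_rev[r] = false;
    } else {
      out_ref[r] = best_ref + 1;
      out_pos[r] = (int)best_pos0 + 1;
      out_clipl[r] = best_start;
      out_mlen[r] = best_len;
      out_clipr[r] = (int)fwd.size() - best_start - best_len;
      out_score[r] = (int)best_score;
      out_nm[r] = best_nm;
      out_rev[r] = best_rev;
    }
  }
  return DataFrame::create(
      _["ref_id"] = out_ref, _["pos"] = out_pos, _["reverse"] = out_rev,
      _["clip_left"] = out_clipl, _["m_len"] = out_mlen,
      _["clip_right"] = out_clipr, _["score"] = out_score, _["nm"] = out_nm,
      _["stringsAsFactors"] = false);
}

// Base counts per reference position from aligned M segments.
// seqs are in aligned (reference) orientation; pos is 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector seqs, IntegerVector pos,
                         IntegerVector clip_left, IntegerVector m_len,
                         int ref_len) {
  IntegerMatrix counts(5, ref_len);  // rows: A C G T other
  for (int r = 0; r < seqs.size(); ++r) {
    if (IntegerVector::is_na(pos[r])) continue;
    std::string s = as<std::string>(seqs[r]);
    int p0 = pos[r] - 1;
    for (int j = 0; j < m_len[r]; ++j) {
      int rp = p0 + j;
      if (rp < 0 || rp >= ref_len) continue;
      int code = base_code(s[clip_left[r] + j]);
      counts(code < 0 ? 4 : code, rp) += 1;
    }
  }
  return counts;
}
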