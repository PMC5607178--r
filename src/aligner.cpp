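// Seed-and-extend local nucleotide aligner.
//
// Subjects are indexed by exact k-mer (word) position; queries are scanned on
// both strands (minus strand = reverse-complemented query against the plus
// index, so subject coordinates are always reported on the subject plus
// strand). Seed hits are clustered by diagonal, extended ungapped with an
// x-drop cutoff, then refined by a banded affine-gap local DP with traceback
// so each HSP carries exact column, identity and score counts.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int8_t encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;  // N and anything else: never seeds, scores as mismatch
  }
}

std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = encode_base(s[i]);
  return v;
}

std::vector<int8_t> revcomp_codes(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? int8_t(-1) : int8_t(3 - c);
  }
  return r;
}

struct SeedIndex {
  int word_size;
  std::vector<std::string> ids;
  std::vector<std::vector<int8_t>> seqs;
  // k-mer code -> flat postings (subject, position)
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t>>> table;
};

struct Hsp {
  int subject;
  int strand;  // 0 plus, 1 minus
  int qs, qe, ss, se;
  int aln_len, identities, score;
};

// Scan a code vector emitting valid k-mer codes with their start positions.
template <typename F>
void for_each_kmer(const std::vector<int8_t>& seq, int k, F&& f) {
  const int n = (int)seq.size();
  uint32_t code = 0;
  int run = 0;  // length of current run of valid bases
  for (int i = 0; i < n; ++i) {
    if (seq[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)seq[i]) & ((1u << (2 * k)) - 1u);
    if (++run >= k) f(code, i - k + 1);
  }
}

// Ungapped x-drop extension from a seed; returns the best segment score.
int ungapped_xdrop(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                   int qpos, int spos, int k, int match, int mismatch, int x_drop) {
  auto sc = [&](int i, int j) {
    return (q[i] >= 0 && q[i] == s[j]) ? match : mismatch;
  };
  int score = k * match;  // exact seed
  // right
  int best = score, cur = score;
  for (int i = qpos + k, j = spos + k;
       i < (int)q.size() && j < (int)s.size(); ++i, ++j) {
    cur += sc(i, j);
    if (cur > best) best = cur;
    if (best - cur > x_drop) break;
  }
  // left
  int best2 = best; cur = best;
  for (int i = qpos - 1, j = spos - 1; i >= 0 && j >= 0; --i, --j) {
    cur += sc(i, j);
    if (cur > best2) best2 = cur;
    if (best2 - cur > x_drop) break;
  }
  return best2;
}

// Banded local affine-gap DP with traceback over diagonals [dlo, dhi].
// Returns the single best-scoring local alignment in the band, or score 0.
Hsp banded_local(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                 int dlo, int dhi, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int qn = (int)q.size(), sn = (int)s.size();
  const int W = dhi - dlo + 1;
  const int NEG = -1000000000;
  // H/E/F laid out as (qn+1) x W; column w corresponds to j = i + dlo + w.
  std::vector<int> H((size_t)(qn + 1) * W, NEG), E = H, F = H;
  std::vector<uint8_t> TB((size_t)(qn + 1) * W, 0);  // 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<uint8_t> TE((size_t)(qn + 1) * W, 0);  // 1 = extend (came from E)
  std::vector<uint8_t> TF((size_t)(qn + 1) * W, 0);
  auto at = [&](int i, int w) { return (size_t)i * W + w; };

  int best = 0, bi = -1, bw = -1;
  for (int i = 0; i <= qn; ++i) {
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > sn) continue;
      if (i == 0 || j == 0) { H[at(i, w)] = 0; continue; }
      // E: gap in query (consumes subject); predecessor (i, j-1) = (i, w-1)
      if (w - 1 >= 0) {
        int hprev = H[at(i, w - 1)], eprev = E[at(i, w - 1)];
        int open_sc = (hprev <= NEG / 2) ? NEG : hprev - gap_open - gap_extend;
        int ext_sc = (eprev <= NEG / 2) ? NEG : eprev - gap_extend;
        if (ext_sc > open_sc) { E[at(i, w)] = ext_sc; TE[at(i, w)] = 1; }
        else E[at(i, w)] = open_sc;
      }
      // F: gap in subject (consumes query); predecessor (i-1, j) = (i-1, w+1)
      if (w + 1 < W) {
        int hprev = H[at(i - 1, w + 1)], fprev = F[at(i - 1, w + 1)];
        int open_sc = (hprev <= NEG / 2) ? NEG : hprev - gap_open - gap_extend;
        int ext_sc = (fprev <= NEG / 2) ? NEG : fprev - gap_extend;
        if (ext_sc > open_sc) { F[at(i, w)] = ext_sc; TF[at(i, w)] = 1; }
        else F[at(i, w)] = open_sc;
      }
      int diag = H[at(i - 1, w)];  // (i-1, j-1) keeps the same diagonal
      int sub = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      int h = 0; uint8_t tb = 0;
      if (diag > NEG / 2 && diag + sub > h) { h = diag + sub; tb = 1; }
      if (E[at(i, w)] > h) { h = E[at(i, w)]; tb = 2; }
      if (F[at(i, w)] > h) { h = F[at(i, w)]; tb = 3; }
      H[at(i, w)] = h; TB[at(i, w)] = tb;
      if (h > best) { best = h; bi = i; bw = w; }
    }
  }

  Hsp out{}; out.score = 0;
  if (best <= 0) return out;
  // traceback
  int i = bi, w = bw;
  int qe = i, se = i + dlo + w;
  int cols = 0, ident = 0;
  int state = 0;  // 0 in H, 1 in E, 2 in F
  while (true) {
    if (state == 0) {
      uint8_t tb = TB[at(i, w)];
      if (tb == 0) break;
      if (tb == 1) {
        int j = i + dlo + w;
        ++cols;
        if (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ++ident;
        --i;  // w unchanged: same diagonal
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: consumed subject base, move to (i, w-1)
      ++cols;
      uint8_t ext = TE[at(i, w)];
      --w;
      if (!ext) state = 0;
    } else {  // F: consumed query base, move to (i-1, w+1)
      ++cols;
      uint8_t ext = TF[at(i, w)];
      --i; ++w;
      if (!ext) state = 0;
    }
  }
  out.qs = i; out.qe = qe;
  out.ss = i + dlo + w; out.se = se;
  out.aln_len = cols; out.identities = ident; out.score = best;
  return out;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int word_size) {
  if (seqs.size() == 0) stop("cannot index an empty subject collection");
  SeedIndex* idx = new SeedIndex();
  idx->word_size = word_size;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->ids.push_back(as<std::string>(ids[i]));
    idx->seqs.push_back(encode_seq(as<std::string>(seqs[i])));
    for_each_kmer(idx->seqs.back(), word_size, [&](uint32_t code, int pos) {
      idx->table[code].emplace_back((int32_t)i, (int32_t)pos);
    });
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
int cpp_index_n_kmers(SEXP index) {
  XPtr<SeedIndex> idx(index);
  size_t n = 0;
  for (auto& kv : idx->table) n += kv.second.size();
  return (int)n;
}

namespace {

std::vector<Hsp> align_query(const std::string& query, const SeedIndex* idxp,
                             int match, int mismatch, int gap_open,
                             int gap_extend, int x_drop, int band) {
  const SeedIndex* idx = idxp;
  const int k = idx->word_size;
  std::vector<Hsp> hsps;
  std::vector<int8_t> qplus = encode_seq(query);
  const int qn = (int)qplus.size();

  for (int strand = 0; strand < 2; ++strand) {
    std::vector<int8_t> q = (strand == 0) ? qplus : revcomp_codes(qplus);
    if ((int)q.size() < k) continue;
    // subject -> list of (diagonal, qpos, spos)
    std::unordered_map<int, std::vector<std::array<int, 3>>> by_subject;
    for_each_kmer(q, k, [&](uint32_t code, int qpos) {
      auto it = idx->table.find(code);
      if (it == idx->table.end()) return;
      for (auto& pr : it->second)
        by_subject[pr.first].push_back({pr.second - qpos, qpos, pr.second});
    });
    for (auto& kv : by_subject) {
      const int subj = kv.first;
      auto& hits = kv.second;
      std::sort(hits.begin(), hits.end(),
                [](const std::array<int, 3>& a, const std::array<int, 3>& b) {
                  return a[0] < b[0];
                });
      const std::vector<int8_t>& s = idx->seqs[subj];
      // cluster seed diagonals closer than the band width
      size_t lo = 0;
      while (lo < hits.size()) {
        size_t hi = lo;
        while (hi + 1 < hits.size() && hits[hi + 1][0] - hits[hi][0] <= band) ++hi;
        int dlo = hits[lo][0] - band, dhi = hits[hi][0] + band;
        // ungapped x-drop stage: best seed score gates the gapped extension
        int best_ungapped = 0;
        int last_d = INT32_MIN;
        for (size_t t = lo; t <= hi; ++t) {
          if (hits[t][0] == last_d) continue;  // one seed per diagonal suffices
          last_d = hits[t][0];
          int u = ungapped_xdrop(q, s, hits[t][1], hits[t][2], k, match, mismatch, x_drop);
          if (u > best_ungapped) best_ungapped = u;
        }
        if (best_ungapped >= k * match) {
          Hsp h = banded_local(q, s, dlo, dhi, match, mismatch, gap_open, gap_extend);
          if (h.score > 0) {
            h.subject = subj; h.strand = strand;
            if (strand == 1) {  // map back to original query coordinates
              int qs = qn - h.qe, qe = qn - h.qs;
              h.qs = qs; h.qe = qe;
            }
            hsps.push_back(h);
          }
        }
        lo = hi + 1;
      }
    }
  }

  // Collapse overlapping HSPs on the same (subject, strand): keep best score.
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.subject != b.subject) return a.subject < b.subject;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.ss < b.ss;
  });
  std::vector<Hsp> kept;
  for (auto& h : hsps) {
    bool drop = false;
    for (auto& g : kept) {
      if (g.subject == h.subject && g.strand == h.strand &&
          h.ss < g.se && g.ss < h.se) { drop = true; break; }
    }
    if (!drop) kept.push_back(h);
  }
  return kept;
}

DataFrame hsps_to_df(const std::vector<Hsp>& kept, const SeedIndex* idx,
                     const std::vector<int>* query_of) {
  const int n = (int)kept.size();
  CharacterVector subject_id(n);
  IntegerVector subject(n), qs(n), qe(n), ss(n), se(n), len(n), ident(n), score(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    subject[i] = kept[i].subject + 1;
    subject_id[i] = idx->ids[kept[i].subject];
    strand[i] = kept[i].strand == 0 ? "plus" : "minus";
    qs[i] = kept[i].qs; qe[i] = kept[i].qe;
    ss[i] = kept[i].ss; se[i] = kept[i].se;
    len[i] = kept[i].aln_len; ident[i] = kept[i].identities;
    score[i] = kept[i].score;
  }
  if (query_of != nullptr) {
    IntegerVector qidx(n);
    for (int i = 0; i < n; ++i) qidx[i] = (*query_of)[i];
    return DataFrame::create(
        _["query"] = qidx, _["subject"] = subject, _["subject_id"] = subject_id,
        _["strand"] = strand, _["qs"] = qs, _["qe"] = qe, _["ss"] = ss,
        _["se"] = se, _["alignment_length"] = len, _["identities"] = ident,
        _["score"] = score, _["stringsAsFactors"] = false);
  }
  return DataFrame::create(
      _["subject"] = subject, _["subject_id"] = subject_id, _["strand"] = strand,
      _["qs"] = qs, _["qe"] = qe, _["ss"] = ss, _["se"] = se,
      _["alignment_length"] = len, _["identities"] = ident, _["score"] = score,
      _["stringsAsFactors"] = false);
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, SEXP index, int match, int mismatch,
                          int gap_open, int gap_extend, int x_drop, int band) {
  XPtr<SeedIndex> idx(index);
  std::vector<Hsp> kept = align_query(query, idx.get(), match, mismatch,
                                      gap_open, gap_extend, x_drop, band);
  return hsps_to_df(kept, idx.get(), nullptr);
}

// [[Rcpp::export]]
DataFrame cpp_local_align_batch(CharacterVector queries, SEXP index, int match,
                                int mismatch, int gap_open, int gap_extend,
                                int x_drop, int band) {
  XPtr<SeedIndex> idx(index);
  std::vector<Hsp> all;
  std::vector<int> query_of;
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    std::vector<Hsp> h = align_query(as<std::string>(queries[i]), idx.get(),
                                     match, mismatch, gap_open, gap_extend,
                                     x_drop, band);
    for (auto& x : h) { all.push_back(x); query_of.push_back((int)(i + 1)); }
  }
  return hsps_to_df(all, idx.get(), &query_of);
}
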