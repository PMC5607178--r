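// Greedy overlap-layout-consensus assembler for per-gene read bins.
//
// Repeatedly merges the contig pair with the longest suffix-prefix overlap
// (either relative orientation) meeting a minimum length and identity, taking
// a per-column majority vote over the merged region. Per-column base counts
// are carried through merges so the consensus at any column is always a base
// observed in at least one member read at that column. Ties are broken
// deterministically (longest overlap, then smallest member index, then plus
// orientation), so assembly is reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N: counted separately, never outvotes a real base
  }
}

inline char code_char(int c) { return "ACGTN"[c]; }

struct Contig {
  std::vector<std::array<int32_t, 5>> counts;  // per-column A/C/G/T/N votes
  std::vector<char> cons;                      // cached consensus
  std::vector<int> members;                    // input read indices (0-based)
  bool alive = true;

  void refresh_consensus() {
    cons.resize(counts.size());
    for (size_t i = 0; i < counts.size(); ++i) {
      int best = 4, bestn = 0;  // only N votes -> N
      for (int b = 0; b < 4; ++b)
        if (counts[i][b] > bestn) { bestn = counts[i][b]; best = b; }
      cons[i] = code_char(best);
    }
  }
  int min_member() const {
    return *std::min_element(members.begin(), members.end());
  }
};

Contig from_read(const std::string& s, int idx) {
  Contig c;
  c.counts.resize(s.size());
  for (auto& a : c.counts) a.fill(0);
  for (size_t i = 0; i < s.size(); ++i) c.counts[i][base_code(s[i])]++;
  c.members.push_back(idx);
  c.refresh_consensus();
  return c;
}

Contig revcomp(const Contig& c) {
  Contig r;
  size_t n = c.counts.size();
  r.counts.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const auto& a = c.counts[n - 1 - i];
    r.counts[i] = {a[3], a[2], a[1], a[0], a[4]};
  }
  r.members = c.members;
  r.refresh_consensus();
  return r;
}

// Longest suffix(a)/prefix(b) overlap >= min_ov with identity >= min_ident.
int best_overlap(const std::vector<char>& a, const std::vector<char>& b,
                 int min_ov, double min_ident) {
  int la = (int)a.size(), lb = (int)b.size();
  int omax = std::min(la, lb);
  for (int o = omax; o >= min_ov; --o) {
    int need = (int)std::ceil(min_ident * o);
    int matches = 0, budget = o - need;  // allowed mismatches
    bool ok = true;
    const char* pa = a.data() + (la - o);
    for (int i = 0; i < o; ++i) {
      if (pa[i] == b[i] && pa[i] != 'N') ++matches;
      else if (--budget < 0) { ok = false; break; }
    }
    if (ok && matches >= need) return o;
  }
  return 0;
}

struct Cand { int ov; int a, b; int orient; };  // orient: 0 b-forward, 1 b-revcomp

// All four layouts of an unordered pair reduce (up to global reverse
// complement of the product) to: suffix(a)+prefix(b), suffix(b)+prefix(a),
// suffix(a)+prefix(rc(b)), suffix(rc(b))+prefix(a).
Cand pair_best(const std::vector<Contig>& tigs, int i, int j,
               int min_ov, double min_ident) {
  Cand best{0, -1, -1, 0};
  Contig rj = revcomp(tigs[j]);
  struct Try { const std::vector<char>*A; const std::vector<char>*B; int a, b, orient; };
  Try tries[4] = {
      {&tigs[i].cons, &tigs[j].cons, i, j, 0},
      {&tigs[j].cons, &tigs[i].cons, j, i, 0},
      {&tigs[i].cons, &rj.cons, i, j, 1},
      {&rj.cons, &tigs[i].cons, j, i, 1},
  };
  for (auto& t : tries) {
    int ov = best_overlap(*t.A, *t.B, min_ov, min_ident);
    if (ov > best.ov) best = {ov, t.a, t.b, t.orient};
  }
  return best;
}

Contig merge(const Contig& a, const Contig& b_in, int ov, bool rc_b) {
  Contig b = rc_b ? revcomp(b_in) : b_in;
  Contig m;
  size_t la = a.counts.size(), lb = b.counts.size();
  m.counts.resize(la + lb - ov);
  for (size_t i = 0; i < la; ++i) m.counts[i] = a.counts[i];
  for (size_t i = la; i < m.counts.size(); ++i) m.counts[i].fill(0);
  for (size_t i = 0; i < lb; ++i) {
    size_t pos = la - ov + i;
    for (int c = 0; c < 5; ++c) m.counts[pos][c] += b.counts[i][c];
  }
  m.members = a.members;
  m.members.insert(m.members.end(), b.members.begin(), b.members.end());
  std::sort(m.members.begin(), m.members.end());
  m.refresh_consensus();
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector reads, int min_overlap, double min_identity) {
  const int n = (int)reads.size();
  if (n == 0) stop("cannot assemble an empty read set");
  std::vector<Contig> tigs;
  tigs.reserve(n);
  for (int i = 0; i < n; ++i) tigs.push_back(from_read(as<std::string>(reads[i]), i));

  // cached best merge candidate per unordered pair, keyed on contig slots
  std::vector<int> alive;
  for (int i = 0; i < n; ++i) alive.push_back(i);
  std::vector<std::vector<Cand>> cand(tigs.size());
  auto compute_row = [&](int i) {
    cand[i].assign(tigs.size(), Cand{0, -1, -1, 0});
    for (int j : alive) {
      if (j >= i) continue;
      cand[i][j] = pair_best(tigs, i, j, min_overlap, min_identity);
    }
  };
  for (int i : alive) compute_row(i);

  while (true) {
    Cand best{0, -1, -1, 0};
    int bi = -1, bj = -1;
    for (int i : alive) {
      for (int j : alive) {
        if (j >= i) continue;
        const Cand& c = cand[i][j];
        if (c.ov == 0) continue;
        bool better = c.ov > best.ov;
        if (c.ov == best.ov && best.a >= 0) {
          int cm1 = tigs[c.a].min_member(), bm1 = tigs[best.a].min_member();
          if (cm1 != bm1) better = cm1 < bm1;
          else {
            int cm2 = tigs[c.b].min_member(), bm2 = tigs[best.b].min_member();
            if (cm2 != bm2) better = cm2 < bm2;
            else better = c.orient < best.orient;
          }
        }
        if (better) { best = c; bi = i; bj = j; }
      }
    }
    if (best.ov < min_overlap || bi < 0) break;

    Contig merged = merge(tigs[best.a], tigs[best.b], best.ov, best.orient == 1);
    tigs[bi].alive = false;
    tigs[bj].alive = false;
    alive.erase(std::remove(alive.begin(), alive.end(), bi), alive.end());
    alive.erase(std::remove(alive.begin(), alive.end(), bj), alive.end());
    tigs.push_back(std::move(merged));
    int ni = (int)tigs.size() - 1;
    cand.resize(tigs.size());
    alive.push_back(ni);
    cand[ni].assign(tigs.size(), Cand{0, -1, -1, 0});
    for (int j : alive) {
      if (j == ni) continue;
      cand[ni][j] = pair_best(tigs, ni, j, min_overlap, min_identity);
    }
  }

  // deterministic output order: by smallest member index
  std::sort(alive.begin(), alive.end(), [&](int x, int y) {
    return tigs[x].min_member() < tigs[y].min_member();
  });
  CharacterVector seqs(alive.size());
  List members(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) {
    const Contig& c = tigs[alive[i]];
    seqs[i] = std::string(c.cons.begin(), c.cons.end());
    IntegerVector mv(c.members.size());
    for (size_t k = 0; k < c.members.size(); ++k) mv[k] = c.members[k] + 1;
    members[i] = mv;
  }
  return List::create(_["sequence"] = seqs, _["members"] = members);
}
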