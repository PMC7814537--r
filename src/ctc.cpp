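// Core CTC recursions in log space. Alphabet is fixed as A,C,G,T,blank
// (columns 0..4 of every log-probability matrix passed in from R).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const int BLANK = 4;
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + std::log1p(std::exp(-std::fabs(a - b)));
}

// preferred = higher score; ties: shorter sequence, then lexicographic
static inline bool better(double sa, const std::string &a, double sb,
                          const std::string &b) {
  if (sa != sb) return sa > sb;
  if (a.size() != b.size()) return a.size() < b.size();
  return a < b;
}

// CTC forward log-probability of `seq` (0-based base codes 0..3) under the
// T x 5 log-probability matrix. Sum over all label paths collapsing to seq
// with the merge-repeats-then-drop-blanks rule.
// [[Rcpp::export]]
double ctc_forward_cpp(const NumericMatrix &lp, const IntegerVector &seq) {
  int T = lp.nrow(), L = seq.size();
  if (L == 0) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += lp(t, BLANK);
    return s;
  }
  if (L > T) return R_NegInf;
  int S = 2 * L + 1;  // blank-interleaved expanded labels
  std::vector<double> a(S, R_NegInf), an(S, R_NegInf);
  a[0] = lp(0, BLANK);
  a[1] = lp(0, seq[0]);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      int lab = (s % 2 == 0) ? BLANK : seq[s / 2];
      double v = a[s];
      if (s >= 1) v = lse2(v, a[s - 1]);
      if (s >= 2 && lab != BLANK && seq[s / 2 - 1] != lab)
        v = lse2(v, a[s - 2]);
      an[s] = (v == R_NegInf) ? R_NegInf : v + lp(t, lab);
    }
    std::swap(a, an);
  }
  return lse2(a[S - 1], a[S - 2]);
}

struct Mass {
  double b, nb;  // log mass of paths ending in blank / in the last base
  Mass() : b(R_NegInf), nb(R_NegInf) {}
  double total() const { return lse2(b, nb); }
};

// CTC prefix beam search on a single profile. Beams are sequence prefixes;
// each carries separate blank-ending and non-blank-ending forward masses.
// [[Rcpp::export]]
List ctc_beam_1d_cpp(const NumericMatrix &lp, int beam_width) {
  int T = lp.nrow();
  std::map<std::string, Mass> beam;
  Mass root;
  root.b = 0.0;  // empty prefix, zero frames consumed
  beam[""] = root;
  for (int t = 0; t < T; ++t) {
    std::map<std::string, Mass> next;
    for (std::map<std::string, Mass>::const_iterator it = beam.begin();
         it != beam.end(); ++it) {
      const std::string &pre = it->first;
      const Mass &m = it->second;
      double tot = m.total();
      if (tot == R_NegInf) continue;
      Mass &same = next[pre];
      same.b = lse2(same.b, tot + lp(t, BLANK));
      if (!pre.empty()) {
        // emitting the last base again merges into the same prefix
        int lastc = std::find(BASES, BASES + 4, pre[pre.size() - 1]) - BASES;
        same.nb = lse2(same.nb, m.nb + lp(t, lastc));
      }
      for (int c = 0; c < 4; ++c) {
        // extension needs an intervening blank when the base repeats
        double src = (!pre.empty() && pre[pre.size() - 1] == BASES[c]) ? m.b : tot;
        if (src == R_NegInf) continue;
        Mass &ext = next[pre + BASES[c]];
        ext.nb = lse2(ext.nb, src + lp(t, c));
      }
    }
    if ((int)next.size() > beam_width) {
      std::vector<std::pair<std::string, Mass> > v(next.begin(), next.end());
      std::sort(v.begin(), v.end(),
                [](const std::pair<std::string, Mass> &x,
                   const std::pair<std::string, Mass> &y) {
                  return better(x.second.total(), x.first, y.second.total(),
                                y.first);
                });
      v.resize(beam_width);
      next = std::map<std::string, Mass>(v.begin(), v.end());
    }
    beam.swap(next);
  }
  std::string bestseq;
  double bestscore = R_NegInf;
  bool first = true;
  for (std::map<std::string, Mass>::const_iterator it = beam.begin();
       it != beam.end(); ++it) {
    double s = it->second.total();
    if (first || better(s, it->first, bestscore, bestseq)) {
      bestseq = it->first;
      bestscore = s;
      first = false;
    }
  }
  return List::create(_["sequence"] = bestseq, _["log_prob"] = bestscore);
}

// ---------------------------------------------------------------------------
// Banded 2D pair beam search.
//
// Prefixes are shared nodes in a trie. The read-1 prefix masses are scalars
// advanced as t1 sweeps 0..T1-1 (standard prefix recursion). The read-2
// prefix masses are per-frame vectors over t2, computed lazily up to the
// envelope's hi(t1); mass at t2 below the envelope's lo at the prefix's
// creation time is excluded (the banding). Extending a node's vector needs
// its parent's vector over the same range, so ancestors of live beam members
// keep theirs; vectors of pruned candidates are freed and recomputed if the
// prefix is ever re-proposed.
// ---------------------------------------------------------------------------

struct Node2 {
  int parent;   // -1 for the empty-prefix root
  int ch;       // 0..3 base appended to parent
  int len;      // prefix length
  int lo0;      // t2 below this are excluded from the read-2 masses
  int h;        // read-2 masses computed for t2 in [0, h)
  int child[4];
  std::string seq;
  std::vector<double> b2, nb2;
  Node2() : parent(-1), ch(-1), len(0), lo0(0), h(0) {
    child[0] = child[1] = child[2] = child[3] = -1;
  }
};

static void extend_node(std::vector<Node2> &pool, int idx, int h_new,
                        const NumericMatrix &lp2) {
  int T2 = lp2.nrow();
  if (h_new > T2) h_new = T2;
  // collect the ancestry that still needs extending, root-most first
  std::vector<int> chain;
  for (int i = idx; i != -1; i = pool[i].parent) {
    if (pool[i].h >= h_new) break;
    chain.push_back(i);
  }
  for (std::vector<int>::reverse_iterator it = chain.rbegin();
       it != chain.rend(); ++it) {
    Node2 &n = pool[*it];
    if (n.b2.empty()) {
      n.b2.assign(T2, R_NegInf);
      n.nb2.assign(T2, R_NegInf);
      n.h = 0;
    }
    if (n.parent == -1) {  // empty prefix: blank-only paths
      for (int t2 = n.h; t2 < h_new; ++t2) {
        double prevb = (t2 == 0) ? 0.0 : n.b2[t2 - 1];
        n.b2[t2] = (prevb == R_NegInf) ? R_NegInf : prevb + lp2(t2, BLANK);
      }
    } else {
      const Node2 &p = pool[n.parent];
      int c = n.ch;
      for (int t2 = n.h; t2 < h_new; ++t2) {
        if (t2 < n.lo0) continue;  // outside the envelope at creation
        double ppb, ppnb;  // parent state one frame earlier
        if (t2 == 0) {
          ppb = (p.len == 0) ? 0.0 : R_NegInf;
          ppnb = R_NegInf;
        } else {
          ppb = p.b2.empty() ? R_NegInf : p.b2[t2 - 1];
          ppnb = p.nb2.empty() ? R_NegInf : p.nb2[t2 - 1];
        }
        double lpc = lp2(t2, c);
        double src = (p.len > 0 && p.ch == c) ? ppb : lse2(ppb, ppnb);
        double ext = (src == R_NegInf) ? R_NegInf : src + lpc;
        double selfnb = (t2 > 0) ? n.nb2[t2 - 1] : R_NegInf;
        double stay = (selfnb == R_NegInf) ? R_NegInf : selfnb + lpc;
        n.nb2[t2] = lse2(stay, ext);
        double selfb = (t2 > 0) ? n.b2[t2 - 1] : R_NegInf;
        double tot = lse2(selfb, selfnb);
        n.b2[t2] = (tot == R_NegInf) ? R_NegInf : tot + lp2(t2, BLANK);
      }
    }
    n.h = std::max(n.h, h_new);
  }
}

static int get_child(std::vector<Node2> &pool, int parent, int c, int lo0) {
  if (pool[parent].child[c] != -1) return pool[parent].child[c];
  Node2 nd;
  nd.parent = parent;
  nd.ch = c;
  nd.len = pool[parent].len + 1;
  nd.lo0 = lo0;
  nd.seq = pool[parent].seq + BASES[c];
  pool.push_back(nd);
  int id = (int)pool.size() - 1;
  pool[parent].child[c] = id;
  return id;
}

// lo, hi: 0-based per-t1 admissible half-open ranges of t2 (length T1)
// [[Rcpp::export]]
List ctc_beam_2d_cpp(const NumericMatrix &lp1, const NumericMatrix &lp2,
                     const IntegerVector &lo, const IntegerVector &hi,
                     int beam_width) {
  int T1 = lp1.nrow(), T2 = lp2.nrow();
  std::vector<Node2> pool;
  pool.reserve(4096);
  pool.push_back(Node2());  // root

  typedef std::map<int, Mass> Cand;
  Cand beam;
  Mass root;
  root.b = 0.0;
  beam[0] = root;

  for (int t1 = 0; t1 < T1; ++t1) {
    int row_lo = lo[t1], row_hi = hi[t1];
    Cand next;
    for (Cand::const_iterator it = beam.begin(); it != beam.end(); ++it) {
      int id = it->first;
      const Mass &m = it->second;
      double tot = m.total();
      if (tot == R_NegInf) continue;
      Mass &same = next[id];
      same.b = lse2(same.b, tot + lp1(t1, BLANK));
      int len = pool[id].len, lastc = pool[id].ch;
      if (len > 0) same.nb = lse2(same.nb, m.nb + lp1(t1, lastc));
      for (int c = 0; c < 4; ++c) {
        double src = (len > 0 && lastc == c) ? m.b : tot;
        if (src == R_NegInf) continue;
        int cid = get_child(pool, id, c, row_lo);
        Mass &ext = next[cid];
        ext.nb = lse2(ext.nb, src + lp1(t1, c));
      }
    }
    // score candidates: read-1 mass times best read-2 mass in the envelope row
    std::vector<std::pair<int, Mass> > v(next.begin(), next.end());
    std::vector<double> score(v.size());
    for (size_t k = 0; k < v.size(); ++k) {
      extend_node(pool, v[k].first, row_hi, lp2);
      const Node2 &n = pool[v[k].first];
      double best2 = R_NegInf;
      for (int t2 = row_lo; t2 < row_hi; ++t2)
        best2 = std::max(best2, lse2(n.b2[t2], n.nb2[t2]));
      double s1 = v[k].second.total();
      score[k] = (s1 == R_NegInf || best2 == R_NegInf) ? R_NegInf : s1 + best2;
    }
    std::vector<size_t> ord(v.size());
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](size_t x, size_t y) {
      return better(score[x], pool[v[x].first].seq, score[y],
                    pool[v[y].first].seq);
    });
    if ((int)ord.size() > beam_width) ord.resize(beam_width);
    Cand pruned;
    for (size_t k = 0; k < ord.size(); ++k)
      pruned[v[ord[k]].first] = v[ord[k]].second;
    // free read-2 vectors not needed by survivors or their ancestors
    std::vector<char> keep(pool.size(), 0);
    for (Cand::const_iterator it = pruned.begin(); it != pruned.end(); ++it)
      for (int i = it->first; i != -1; i = pool[i].parent) {
        if (keep[i]) break;
        keep[i] = 1;
      }
    for (size_t k = 0; k < v.size(); ++k) {
      int id = v[k].first;
      if (!keep[id] && !pool[id].b2.empty()) {
        std::vector<double>().swap(pool[id].b2);
        std::vector<double>().swap(pool[id].nb2);
        pool[id].h = 0;
      }
    }
    beam.swap(pruned);
  }

  std::string bestseq;
  double best = R_NegInf, best1 = R_NegInf, best2 = R_NegInf;
  bool first = true;
  for (Cand::const_iterator it = beam.begin(); it != beam.end(); ++it) {
    extend_node(pool, it->first, T2, lp2);
    const Node2 &n = pool[it->first];
    double s2 = lse2(n.b2[T2 - 1], n.nb2[T2 - 1]);
    double s1 = it->second.total();
    double s = (s1 == R_NegInf || s2 == R_NegInf) ? R_NegInf : s1 + s2;
    if (first || better(s, n.seq, best, bestseq)) {
      bestseq = n.seq;
      best = s;
      best1 = s1;
      best2 = s2;
      first = false;
    }
  }
  return List::create(_["sequence"] = bestseq, _["log_prob_1"] = best1,
                      _["log_prob_2"] = best2);
}
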