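// Deterministic structure-prediction engine and Pareto machinery.
//
// Nucleotide encoding: A=0, C=1, G=2, U=3.
// Pair scores: GC/CG=3, AU/UA=2, GU/UG=1, anything else unpairable (0);
// each stacked pair (a pair enclosing an adjacent pair, i.e. helix
// elongation) earns an additional STACK_BONUS, the discrete analogue of
// helix-stacking free energy.  The optimum maximizes the total score;
// residual ties are broken by preferring more stacked pairs, then
// deterministically (unpaired-first, leftmost partner).  Score and stack
// count are folded into one integer (score << 10 | stacks) so a plain max
// is a lexicographic max.
//
// Constraint codes per position:
//   0 = free
//   1 = enforce pair with a given partner (1-based, strand-local here)
//   2 = prohibit all pairs
//   3 = prohibit intramolecular pairs
//   4 = prohibit intermolecular pairs
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const int CONS_FREE = 0;
static const int CONS_ENFORCE = 1;
static const int CONS_NOPAIR = 2;
static const int CONS_NOINTRA = 3;
static const int CONS_NOINTER = 4;
static const int MIN_HAIRPIN = 3; // unpaired nt between i and j: j - i > MIN_HAIRPIN
static const int STACK_BONUS = 2; // score credit per stacked pair
static const long long NEG = std::numeric_limits<long long>::min() / 4;
static const int SHIFT = 10;      // stacks occupy the low 10 bits

static inline int pairScore(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
  return 0;
}

// Intramolecular folding ----------------------------------------------------

struct SingleFold {
  const std::vector<int>& seq;
  const std::vector<int>& code;
  const std::vector<int>& partner; // 0-based enforced partner, -1 if none
  int n;
  // C[i][j]: best combined value of [i..j]; P[i][j]: ditto given (i,j) paired
  std::vector<std::vector<long long> > C, P;

  SingleFold(const std::vector<int>& s, const std::vector<int>& c,
             const std::vector<int>& p)
    : seq(s), code(c), partner(p), n((int)s.size()),
      C(s.size(), std::vector<long long>(s.size(), NEG)),
      P(s.size(), std::vector<long long>(s.size(), NEG)) {}

  bool canUnpair(int i) const { return code[i] != CONS_ENFORCE; }

  bool canPair(int i, int j) const {
    if (j - i <= MIN_HAIRPIN) return false;
    if (pairScore(seq[i], seq[j]) == 0) return false;
    if (code[i] == CONS_NOPAIR || code[i] == CONS_NOINTRA) return false;
    if (code[j] == CONS_NOPAIR || code[j] == CONS_NOINTRA) return false;
    if (code[i] == CONS_ENFORCE && partner[i] != j) return false;
    if (code[j] == CONS_ENFORCE && partner[j] != i) return false;
    return true;
  }

  long long getC(int i, int j) const {
    if (i > j) return 0;
    return C[i][j];
  }

  // best value of the inner region [i+1 .. j-1] of pair (i, j), including
  // the stacking credit when (i+1, j-1) is itself a pair
  long long innerBest(int i, int j) const {
    int a = i + 1, b = j - 1;
    long long best = NEG;
    if (canPair(a, b) && P[a][b] > NEG / 2) {
      // one more stacked pair: scores STACK_BONUS, counts in the low bits
      long long v = P[a][b] + ((long long)STACK_BONUS << SHIFT) + 1;
      if (v > best) best = v;
    }
    if (canUnpair(a)) {
      long long v = getC(a + 1, b);
      if (v > NEG / 2 && v > best) best = v;
    }
    for (int k = a + MIN_HAIRPIN + 1; k < b; ++k) {
      if (!canPair(a, k) || P[a][k] <= NEG / 2) continue;
      long long rest = getC(k + 1, b);
      if (rest <= NEG / 2) continue;
      long long v = P[a][k] + rest;
      if (v > best) best = v;
    }
    return best;
  }

  long long solve() {
    for (int len = 1; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (canPair(i, j)) {
          long long inner = innerBest(i, j);
          if (inner > NEG / 2)
            P[i][j] = ((long long)pairScore(seq[i], seq[j]) << SHIFT) + inner;
        }
        long long best = NEG;
        if (canUnpair(i)) {
          long long v = getC(i + 1, j);
          if (v > NEG / 2) best = v;
        }
        for (int k = i + MIN_HAIRPIN + 1; k <= j; ++k) {
          if (!canPair(i, k) || P[i][k] <= NEG / 2) continue;
          long long rest = getC(k + 1, j);
          if (rest <= NEG / 2) continue;
          long long v = P[i][k] + rest;
          if (v > best) best = v;
        }
        C[i][j] = best;
      }
    }
    return n == 0 ? 0 : C[0][n - 1];
  }

  void tracebackC(int i, int j, std::vector<int>& out) const {
    if (i > j) return;
    long long here = C[i][j];
    if (here <= NEG / 2) return;
    if (canUnpair(i) && getC(i + 1, j) == here) {
      tracebackC(i + 1, j, out);
      return;
    }
    for (int k = i + MIN_HAIRPIN + 1; k <= j; ++k) {
      if (!canPair(i, k) || P[i][k] <= NEG / 2) continue;
      long long rest = getC(k + 1, j);
      if (rest <= NEG / 2) continue;
      if (P[i][k] + rest == here) {
        tracebackP(i, k, out);
        tracebackC(k + 1, j, out);
        return;
      }
    }
  }

  void tracebackP(int i, int j, std::vector<int>& out) const {
    out[i] = j;
    out[j] = i;
    long long here = P[i][j] - ((long long)pairScore(seq[i], seq[j]) << SHIFT);
    int a = i + 1, b = j - 1;
    if (canPair(a, b) && P[a][b] > NEG / 2 &&
        P[a][b] + ((long long)STACK_BONUS << SHIFT) + 1 == here) {
      tracebackP(a, b, out);
      return;
    }
    if (canUnpair(a) && getC(a + 1, b) == here) {
      tracebackC(a + 1, b, out);
      return;
    }
    for (int k = a + MIN_HAIRPIN + 1; k < b; ++k) {
      if (!canPair(a, k) || P[a][k] <= NEG / 2) continue;
      long long rest = getC(k + 1, b);
      if (rest <= NEG / 2) continue;
      if (P[a][k] + rest == here) {
        tracebackP(a, k, out);
        tracebackC(k + 1, b, out);
        return;
      }
    }
  }
};

static std::vector<int> asVec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export]]
List cpp_fold_single(IntegerVector seq, IntegerVector code, IntegerVector partner) {
  std::vector<int> s = asVec(seq), c = asVec(code);
  int n = (int)s.size();
  std::vector<int> p(n, -1);
  for (int i = 0; i < n; ++i)
    if (partner[i] != NA_INTEGER && partner[i] > 0) p[i] = partner[i] - 1;
  SingleFold f(s, c, p);
  long long combined = f.solve();
  if (combined <= NEG / 2)
    return List::create(_["ok"] = false);
  std::vector<int> pt(n, -1);
  if (n > 0) f.tracebackC(0, n - 1, pt);
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i)
    if (pt[i] >= 0) out[i] = pt[i] + 1;
  return List::create(_["ok"] = true, _["partner"] = out,
                      _["score"] = (int)(combined >> SHIFT));
}

// Intermolecular duplex windows --------------------------------------------

struct Window { int a, b, len, score; }; // 0-based: s1 a..a+len-1 pairs s2 b..b-len+1

// Greedily select up to maxRegions non-overlapping best-scoring duplex windows.
static std::vector<Window> selectWindows(const std::vector<int>& s1,
                                         const std::vector<int>& s2,
                                         const std::vector<int>& c1,
                                         const std::vector<int>& c2,
                                         int maxRegions, int maxLen) {
  int n1 = (int)s1.size(), n2 = (int)s2.size();
  std::vector<bool> used1(n1, false), used2(n2, false);
  std::vector<Window> picked;
  if (maxRegions <= 0 || maxLen <= 0) return picked;
  for (int round = 0; round < maxRegions; ++round) {
    Window best; best.score = 0; best.a = -1; best.b = -1; best.len = 0;
    for (int a = 0; a < n1; ++a) {
      for (int b = 0; b < n2; ++b) {
        int score = 0;
        int maxL = std::min(maxLen, std::min(n1 - a, b + 1));
        for (int L = 1; L <= maxL; ++L) {
          int i = a + L - 1, j = b - L + 1;
          if (used1[i] || used2[j]) break;
          if (c1[i] == CONS_NOPAIR || c1[i] == CONS_NOINTER ||
              c1[i] == CONS_ENFORCE) break;
          if (c2[j] == CONS_NOPAIR || c2[j] == CONS_NOINTER ||
              c2[j] == CONS_ENFORCE) break;
          int ps = pairScore(s1[i], s2[j]);
          if (ps == 0) break;
          score += ps + (L > 1 ? STACK_BONUS : 0); // duplex elongation stacks
          // tie-break: higher score, then leftmost strand-1 start, then
          // leftmost strand-2 start (b - L + 1), then shortest
          int start2 = b - L + 1;
          bool better = false;
          if (score > best.score) better = true;
          else if (score == best.score && best.a >= 0) {
            int bstart2 = best.b - best.len + 1;
            if (a < best.a) better = true;
            else if (a == best.a && start2 < bstart2) better = true;
            else if (a == best.a && start2 == bstart2 && L < best.len) better = true;
          }
          if (better) { best.a = a; best.b = b; best.len = L; best.score = score; }
        }
      }
    }
    if (best.score <= 0) break;
    for (int k = 0; k < best.len; ++k) {
      used1[best.a + k] = true;
      used2[best.b - k] = true;
    }
    picked.push_back(best);
  }
  return picked;
}

// [[Rcpp::export]]
List cpp_fold_joint(IntegerVector seq1, IntegerVector seq2,
                    IntegerVector code1, IntegerVector partner1,
                    IntegerVector code2, IntegerVector partner2,
                    int maxRegions, int maxLen) {
  std::vector<int> s1 = asVec(seq1), s2 = asVec(seq2);
  std::vector<int> c1 = asVec(code1), c2 = asVec(code2);
  int n1 = (int)s1.size(), n2 = (int)s2.size();
  std::vector<Window> regions = selectWindows(s1, s2, c1, c2, maxRegions, maxLen);

  int interScore = 0;
  IntegerVector partner(n1 + n2, NA_INTEGER);
  std::vector<int> cc1 = c1, cc2 = c2;
  for (size_t r = 0; r < regions.size(); ++r) {
    const Window& w = regions[r];
    interScore += w.score;
    for (int k = 0; k < w.len; ++k) {
      int i = w.a + k, j = w.b - k;
      partner[i] = n1 + j + 1;          // 1-based global
      partner[n1 + j] = i + 1;
      cc1[i] = CONS_NOPAIR;
      cc2[j] = CONS_NOPAIR;
    }
  }

  // fold the remainder of each strand intramolecularly
  long long total = interScore;
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int>& s = strand == 0 ? s1 : s2;
    std::vector<int>& cc = strand == 0 ? cc1 : cc2;
    const IntegerVector& pv = strand == 0 ? partner1 : partner2;
    int n = (int)s.size();
    std::vector<int> p(n, -1);
    for (int i = 0; i < n; ++i)
      if (pv[i] != NA_INTEGER && pv[i] > 0) p[i] = pv[i] - 1;
    SingleFold f(s, cc, p);
    long long combined = f.solve();
    if (combined <= NEG / 2) return List::create(_["ok"] = false);
    std::vector<int> pt(n, -1);
    if (n > 0) f.tracebackC(0, n - 1, pt);
    int off = strand == 0 ? 0 : n1;
    for (int i = 0; i < n; ++i)
      if (pt[i] >= 0) partner[off + i] = off + pt[i] + 1;
    total += combined >> SHIFT;
  }

  IntegerMatrix reg(regions.size(), 4);
  for (size_t r = 0; r < regions.size(); ++r) {
    reg(r, 0) = regions[r].a + 1;      // strand-1 start (1-based)
    reg(r, 1) = regions[r].b + 1;      // strand-2 position paired with start
    reg(r, 2) = regions[r].len;
    reg(r, 3) = regions[r].score;
  }
  return List::create(_["ok"] = true, _["partner"] = partner,
                      _["score"] = (int)total, _["regions"] = reg);
}

// Constraint-dominance Pareto ranks ----------------------------------------

// objs: n x m matrix of objective values (all minimized); v: overall violation.
// Returns 1-based front index per solution under constraint dominance.
// [[Rcpp::export]]
IntegerVector cpp_pareto_ranks(NumericMatrix objs, NumericVector v) {
  int n = objs.nrow(), m = objs.ncol();
  std::vector<std::vector<int> > dominated(n);
  std::vector<int> ndom(n, 0);

  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int res = 0; // 1: a dominates b, -1: b dominates a
      bool fa = v[a] <= 0, fb = v[b] <= 0;
      if (fa && !fb) res = 1;
      else if (!fa && fb) res = -1;
      else if (!fa && !fb) {
        if (v[a] < v[b]) res = 1;
        else if (v[b] < v[a]) res = -1;
      } else {
        bool aLEb = true, bLEa = true, diff = false;
        for (int j = 0; j < m; ++j) {
          double xa = objs(a, j), xb = objs(b, j);
          if (xa > xb) aLEb = false;
          if (xb > xa) bLEa = false;
          if (xa != xb) diff = true;
        }
        if (diff && aLEb) res = 1;
        else if (diff && bLEa) res = -1;
      }
      if (res == 1) { dominated[a].push_back(b); ndom[b]++; }
      else if (res == -1) { dominated[b].push_back(a); ndom[a]++; }
    }
  }

  IntegerVector rank(n, NA_INTEGER);
  std::vector<int> current;
  for (int i = 0; i < n; ++i) if (ndom[i] == 0) current.push_back(i);
  int front = 1;
  while (!current.empty()) {
    std::vector<int> next;
    for (size_t t = 0; t < current.size(); ++t) {
      int i = current[t];
      rank[i] = front;
      for (size_t u = 0; u < dominated[i].size(); ++u) {
        int j = dominated[i][u];
        if (--ndom[j] == 0) next.push_back(j);
      }
    }
    current = next;
    ++front;
  }
  return rank;
}

// Window selection only (no intramolecular refold): used by the seed
// procedure, whose result is the selected duplex region alone.
// [[Rcpp::export]]
IntegerMatrix cpp_best_windows(IntegerVector seq1, IntegerVector seq2,
                               IntegerVector code1, IntegerVector code2,
                               int maxRegions, int maxLen) {
  std::vector<int> s1 = asVec(seq1), s2 = asVec(seq2);
  std::vector<int> c1 = asVec(code1), c2 = asVec(code2);
  std::vector<Window> regions = selectWindows(s1, s2, c1, c2, maxRegions, maxLen);
  IntegerMatrix reg(regions.size(), 4);
  for (size_t r = 0; r < regions.size(); ++r) {
    reg(r, 0) = regions[r].a + 1;
    reg(r, 1) = regions[r].b + 1;
    reg(r, 2) = regions[r].len;
    reg(r, 3) = regions[r].score;
  }
  return reg;
}
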