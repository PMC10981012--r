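#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex scoring between a miRNA (5'->3') and a target site.
// The site is read antiparallel to the miRNA, so a valid pairing is a chain
// of base pairs with miRNA positions strictly increasing and site positions
// strictly decreasing. Pair scores: GC = +3, AU = +2, GU = +1. Unpaired
// stretches *between* two pairs are charged an affine gap cost per strand
// (open 2, extend 1); unpaired flanks are free. The empty pairing scores 0.

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return -1; // not pairable
}

static inline double gap_cost(int k) {
  return k <= 0 ? 0.0 : 2.0 + (k - 1) * 1.0;
}

// [[Rcpp::export(name = ".duplex_dp_cpp")]]
List duplex_dp_cpp(std::string mirna, std::string site) {
  const int n = mirna.size(), m = site.size();
  // M(i,j): best score of a chain whose last pair is (i, j); -inf if unpairable.
  NumericMatrix M(n, m);
  IntegerMatrix prev_i(n, m), prev_j(n, m);
  const double NEG = -1e18;
  double best = 0.0;
  int best_i = -1, best_j = -1;

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int ps = pair_score(mirna[i], site[j]);
      if (ps < 0) { M(i, j) = NEG; prev_i(i, j) = -2; continue; }
      double b = 0.0; // start a fresh chain: flanks are free
      int pi = -1, pj = -1;
      for (int i2 = 0; i2 < i; ++i2) {
        for (int j2 = m - 1; j2 > j; --j2) {
          if (prev_i(i2, j2) == -2) continue;
          double cand = M(i2, j2) - gap_cost(i - i2 - 1) - gap_cost(j2 - j - 1);
          if (cand > b) { b = cand; pi = i2; pj = j2; }
        }
      }
      M(i, j) = ps + b;
      prev_i(i, j) = pi; prev_j(i, j) = pj;
      if (M(i, j) > best) { best = M(i, j); best_i = i; best_j = j; }
    }
  }

  std::vector<int> out_i, out_j;
  int ci = best_i, cj = best_j;
  while (ci >= 0) {
    out_i.push_back(ci + 1); out_j.push_back(cj + 1);
    int ni = prev_i(ci, cj), nj = prev_j(ci, cj);
    ci = ni; cj = nj;
  }
  std::reverse(out_i.begin(), out_i.end());
  std::reverse(out_j.begin(), out_j.end());
  return List::create(_["score"] = best,
                      _["mirna_pos"] = wrap(out_i),
                      _["site_pos"] = wrap(out_j));
}

// Exhaustive reference: enumerate every non-crossing chain of pairs by
// depth-first search and return the maximum score. Exponential; intended for
// validating the DP on short sequences only.
struct EnumCtx {
  std::vector<int> pi, pj, ps; // candidate pairs sorted by (i asc, j desc)
  double best;
};

static void enum_rec(EnumCtx& ctx, int k, int last_i, int last_j, double acc) {
  const std::vector<int>& pi = ctx.pi;
  const std::vector<int>& pj = ctx.pj;
  const std::vector<int>& ps = ctx.ps;
  for (int t = k; t < (int)pi.size(); ++t) {
    if (last_i >= 0 && (pi[t] <= last_i || pj[t] >= last_j)) continue;
    double add = ps[t];
    if (last_i >= 0)
      add -= gap_cost(pi[t] - last_i - 1) + gap_cost(last_j - pj[t] - 1);
    double nacc = acc + add;
    if (nacc > ctx.best) ctx.best = nacc;
    enum_rec(ctx, t + 1, pi[t], pj[t], nacc);
  }
}

// [[Rcpp::export(name = ".duplex_enumerate_cpp")]]
double duplex_enumerate_cpp(std::string mirna, std::string site) {
  const int n = mirna.size(), m = site.size();
  EnumCtx ctx; ctx.best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = m - 1; j >= 0; --j) {
      int s = pair_score(mirna[i], site[j]);
      if (s > 0) { ctx.pi.push_back(i); ctx.pj.push_back(j); ctx.ps.push_back(s); }
    }
  enum_rec(ctx, 0, -1, -1, 0.0);
  return ctx.best;
}
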