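#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap of length k costs
// gap_open + k * gap_extend. Traceback is deterministic: at every cell the
// states are preferred in the order M (diagonal) > X (gap in b, "up") >
// Y (gap in a, "left"), and within a gap state opening is preferred over
// extending at equal score. This fixed tie-break is part of the contract:
// identical inputs always produce the identical alignment string pair.

static const double NEG = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double go = gap_open + gap_extend; // cost of a new gap of length 1

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // traceback: for each state, which predecessor state (0=M,1=X,2=Y)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + i * gap_extend);
    tbX[idx(i, 0)] = 1;
  }
  tbX[idx(1, 0)] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + j * gap_extend);
    tbY[idx(0, j)] = 2;
  }
  if (m >= 1) tbY[idx(0, 1)] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: prefer M > X > Y among equal predecessors
      {
        double bm = M[idx(i - 1, j - 1)];
        unsigned char t = 0;
        if (X[idx(i - 1, j - 1)] > bm) { bm = X[idx(i - 1, j - 1)]; t = 1; }
        if (Y[idx(i - 1, j - 1)] > bm) { bm = Y[idx(i - 1, j - 1)]; t = 2; }
        M[idx(i, j)] = bm + s;
        tbM[idx(i, j)] = t;
      }
      // X: gap in b (consume a[i-1]); open from M preferred at ties
      {
        double open_s = M[idx(i - 1, j)] - go;
        double ext_s = X[idx(i - 1, j)] - gap_extend;
        if (open_s >= ext_s) { X[idx(i, j)] = open_s; tbX[idx(i, j)] = 0; }
        else { X[idx(i, j)] = ext_s; tbX[idx(i, j)] = 1; }
      }
      // Y: gap in a (consume b[j-1])
      {
        double open_s = M[idx(i, j - 1)] - go;
        double ext_s = Y[idx(i, j - 1)] - gap_extend;
        if (open_s >= ext_s) { Y[idx(i, j)] = open_s; tbY[idx(i, j)] = 0; }
        else { Y[idx(i, j)] = ext_s; tbY[idx(i, j)] = 2; }
      }
    }
  }

  // terminal state: prefer M > X > Y
  int state = 0;
  double best = M[idx(n, m)];
  if (X[idx(n, m)] > best) { best = X[idx(n, m)]; state = 1; }
  if (Y[idx(n, m)] > best) { best = Y[idx(n, m)]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { // only possible at origin
        if (i > 0) state = 1;
        else state = 2;
        continue;
      }
      unsigned char t = tbM[idx(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = t;
    } else if (state == 1) {
      unsigned char t = tbX[idx(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = t;
    } else {
      unsigned char t = tbY[idx(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = t;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best);
}

// Best gapless antiparallel register of s against a second copy of itself.
// Pair scores: Watson-Crick +2, G.T (G.U on RNA) wobble +1, else 0.
// [[Rcpp::export(name = ".duplex_best_cpp")]]
List duplex_best_cpp(std::string s) {
  const int n = (int)s.size();
  auto pair_score = [](char x, char y) -> int {
    if ((x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
        (x == 'G' && y == 'C') || (x == 'C' && y == 'G')) return 2;
    if ((x == 'G' && y == 'T') || (x == 'T' && y == 'G')) return 1;
    return 0;
  };
  int best = 0, best_k = 0;
  for (int k = -(n - 1); k <= n - 1; ++k) {
    int sc = 0;
    for (int i = 1; i <= n; ++i) {
      int j = n - i + 1 - k;
      if (j >= 1 && j <= n) sc += pair_score(s[i - 1], s[j - 1]);
    }
    if (sc > best) { best = sc; best_k = k; }
  }
  return List::create(_["score"] = best, _["offset"] = best_k);
}
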