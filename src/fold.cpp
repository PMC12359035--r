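#include <Rcpp.h>
using namespace Rcpp;

// Weighted base-pair maximization over non-crossing structures in which every
// helix (maximal run of stacked pairs) has length >= min_helix and every
// hairpin loop has >= min_loop unpaired bases. The helix constraint is part of
// the recursion, so the returned score is the exact optimum over the
// constrained structure space.
//
// Bases are encoded A=0, C=1, G=2, U=3; wt is the 4x4 pair-weight matrix
// (0 where a pair is disallowed).

static const double EPS = 1e-9;

struct FoldCtx {
  int n;
  int min_loop;
  int min_helix;
  std::vector<int> code;
  const NumericMatrix* wt;
  std::vector<double> W; // n x n, best score on [i, j]
  double at(int i, int j) const {
    if (i > j) return 0.0;
    return W[(size_t)i * n + j];
  }
  double pw(int i, int j) const { return (*wt)(code[i], code[j]); }
};

// longest stacked run starting with pair (i, k): pairs (i+t, k-t) all have
// positive weight and the innermost pair keeps a loop of >= min_loop
static int max_stack(const FoldCtx& c, int i, int k) {
  int h = 0;
  while (true) {
    int a = i + h, b = k - h;
    if (b - a - 1 < c.min_loop) break;     // innermost pair would close too tight
    if (c.pw(a, b) <= 0.0) break;
    ++h;
  }
  return h;
}

static void fill_dp(FoldCtx& c) {
  int n = c.n;
  c.W.assign((size_t)n * n, 0.0);
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = c.at(i + 1, j); // i unpaired
      for (int k = i + c.min_loop + 1; k <= j; ++k) {
        int hmax = max_stack(c, i, k);
        if (hmax < c.min_helix) continue;
        double hs = 0.0;
        for (int h = 1; h <= hmax; ++h) {
          hs += c.pw(i + h - 1, k - h + 1);
          if (h < c.min_helix) continue;
          double cand = hs + c.at(i + h, k - h) + c.at(k + 1, j);
          if (cand > best + EPS) best = cand;
        }
      }
      c.W[(size_t)i * n + j] = best;
    }
  }
}

// Deterministic traceback: at [i, j], prefer pairing i, with the smallest
// admissible partner k (and shortest helix), recursing left to right.
static void traceback(const FoldCtx& c, int i, int j, std::string& db) {
  while (i <= j) {
    double target = c.at(i, j);
    if (target <= EPS) return; // all unpaired
    bool paired = false;
    for (int k = i + c.min_loop + 1; k <= j && !paired; ++k) {
      int hmax = max_stack(c, i, k);
      if (hmax < c.min_helix) continue;
      double hs = 0.0;
      for (int h = 1; h <= hmax; ++h) {
        hs += c.pw(i + h - 1, k - h + 1);
        if (h < c.min_helix) continue;
        double cand = hs + c.at(i + h, k - h) + c.at(k + 1, j);
        if (std::abs(cand - target) < EPS) {
          for (int t = 0; t < h; ++t) {
            db[i + t] = '(';
            db[k - t] = ')';
          }
          traceback(c, i + h, k - h, db);
          i = k + 1; // continue with the right remainder iteratively
          paired = true;
          break;
        }
      }
    }
    if (!paired) ++i; // optimum leaves i unpaired
  }
}

// [[Rcpp::export(name = ".fold_nussinov_cpp")]]
List fold_nussinov_cpp(std::string seq, int min_loop, int min_helix,
                       NumericMatrix wt) {
  int n = seq.size();
  FoldCtx c;
  c.n = n;
  c.min_loop = min_loop;
  c.min_helix = min_helix;
  c.wt = &wt;
  c.code.resize(n);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': c.code[i] = 0; break;
      case 'C': c.code[i] = 1; break;
      case 'G': c.code[i] = 2; break;
      case 'U': c.code[i] = 3; break;
      default:
        stop("illegal character '%s' in RNA sequence",
             std::string(1, seq[i]).c_str());
    }
  }
  std::string db(n, '.');
  double score = 0.0;
  if (n >= 2) {
    fill_dp(c);
    score = c.at(0, n - 1);
    traceback(c, 0, n - 1, db);
  }
  return List::create(_["dotbracket"] = db, _["score"] = score);
}
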