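#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recurrence).
//
// Gap model: a gap of length L costs open + extend * L, i.e. opening into a
// gap costs (open + extend) and each further column costs extend.  This is
// the same convention Biostrings::pairwiseAlignment uses, which keeps the
// two implementations directly comparable in tests.
//
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a) so
// output is bit-reproducible.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b,
                     NumericMatrix submat, CharacterVector sub_alpha,
                     double gap_open, double gap_extend, bool local) {
  int n = a.size(), m = b.size();
  std::string alpha = as<std::string>(sub_alpha[0]);
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alpha.size(); ++i) idx[(unsigned char)alpha[i]] = i;

  for (int i = 0; i < n; ++i)
    if (idx[(unsigned char)a[i]] < 0)
      stop("residue '%s' of sequence a not in substitution matrix", std::string(1, a[i]));
  for (int j = 0; j < m; ++j)
    if (idx[(unsigned char)b[j]] < 0)
      stop("residue '%s' of sequence b not in substitution matrix", std::string(1, b[j]));

  // M: a[i] aligned to b[j]; X: gap in b (a[i] over '-'); Y: gap in a.
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: matrix the cell value came from (0 = M, 1 = X, 2 = Y,
  // 3 = fresh start: matrix origin or local zero-floor)
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  double go = gap_open + gap_extend; // cost of the first gap column
  double ge = gap_extend;

  M(0, 0) = 0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF; tbM(0, 0) = 3;
  for (int i = 1; i <= n; ++i) {
    Y(i, 0) = NEG_INF;
    if (local) {
      M(i, 0) = 0; tbM(i, 0) = 3;
      X(i, 0) = NEG_INF;
    } else {
      M(i, 0) = NEG_INF;
      X(i, 0) = -(gap_open + ge * i);
      tbX(i, 0) = (i == 1) ? 0 : 1;
    }
  }
  for (int j = 1; j <= m; ++j) {
    X(0, j) = NEG_INF;
    if (local) {
      M(0, j) = 0; tbM(0, j) = 3;
      Y(0, j) = NEG_INF;
    } else {
      M(0, j) = NEG_INF;
      Y(0, j) = -(gap_open + ge * j);
      tbY(0, j) = (j == 1) ? 0 : 2;
    }
  }

  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      double s = submat(ai, idx[(unsigned char)b[j - 1]]);
      // M(i,j): tie order M > X > Y on the diagonal source
      double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
      double mv = vm; int mt = 0;
      if (vx > mv) { mv = vx; mt = 1; }
      if (vy > mv) { mv = vy; mt = 2; }
      double Mij = mv + s;
      int Mt = mt;
      if (local && Mij < 0) { Mij = 0; Mt = 3; }
      M(i, j) = Mij; tbM(i, j) = Mt;

      // X(i,j): gap in b, consumes a[i]
      double openx = M(i - 1, j) - go;
      double extx  = X(i - 1, j) - ge;
      if (openx >= extx) { X(i, j) = openx; tbX(i, j) = 0; }
      else               { X(i, j) = extx;  tbX(i, j) = 1; }

      // Y(i,j): gap in a, consumes b[j]; allow X -> Y so adjacent gaps in
      // both sequences are representable (never gap-vs-gap in one column)
      double openy = M(i, j - 1) - go;
      double fromx = X(i, j - 1) - go;
      double exty  = Y(i, j - 1) - ge;
      double yv = openy; int yt = 0;
      if (fromx > yv) { yv = fromx; yt = 1; }
      if (exty > yv)  { yv = exty;  yt = 2; }
      Y(i, j) = yv; tbY(i, j) = yt;

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  double score;
  int i, j, state; // 0 = M, 1 = X, 2 = Y
  if (local) {
    score = best; i = bi; j = bj; state = 0;
    if (score <= 0)
      return List::create(_["score"] = 0.0, _["aln_a"] = "", _["aln_b"] = "",
                          _["start_a"] = NA_INTEGER, _["start_b"] = NA_INTEGER);
  } else {
    double vm = M(n, m), vx = X(n, m), vy = Y(n, m);
    score = vm; state = 0;
    if (vx > score) { score = vx; state = 1; }
    if (vy > score) { score = vy; state = 2; }
    i = n; j = m;
  }

  std::string ga, gb;
  while (true) {
    if (i == 0 && j == 0) break;
    if (state == 0) {
      if (tbM(i, j) == 3) break; // fresh-start cell: nothing more to emit
      int prev = tbM(i, j);
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = prev;
    } else {
      int prev = tbY(i, j);
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  int start_a = 1, start_b = 1;
  if (local) { start_a = i + 1; start_b = j + 1; }
  return List::create(_["score"] = score, _["aln_a"] = ga, _["aln_b"] = gb,
                      _["start_a"] = start_a, _["start_b"] = start_b);
}
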