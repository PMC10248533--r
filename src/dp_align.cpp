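#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed score matrix S (m x n),
// where S(i, j) scores pairing row unit i (profile column / first profile)
// with column unit j (residue / second profile column).  Gap of length k
// costs open + (k - 1) * extend.  type: 0 = local (Smith-Waterman style),
// 1 = global with penalized terminal gaps (Needleman-Wunsch style).
//
// Returns the optimal score and the traceback path as a (k x 2) integer
// matrix of 1-based (i, j) pairs; 0 marks a gap on that side.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List cpp_affine_align(NumericMatrix S, double open, double extend, int type) {
  const int m = S.nrow(), n = S.ncol();
  // state matrices: M diagonal, X consumes i (gap in j), Y consumes j
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  // traceback: for each state, which state it came from (0=M,1=X,2=Y,3=start)
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 3);
  std::vector<unsigned char> tbX((m + 1) * (n + 1), 3);
  std::vector<unsigned char> tbY((m + 1) * (n + 1), 3);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  M[idx(0, 0)] = 0.0;
  if (type == 1) {
    for (int i = 1; i <= m; ++i) {
      X[idx(i, 0)] = -open - (i - 1) * extend;
      tbX[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n; ++j) {
      Y[idx(0, j)] = -open - (j - 1) * extend;
      tbY[idx(0, j)] = (j == 1) ? 0 : 2;
    }
  }
  // local mode: alignments start fresh via the tb==3 branch below, so
  // border cells other than (0,0) stay at -inf

  double best = (type == 0) ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)],
             dY = Y[idx(i - 1, j - 1)];
      double from = dM; unsigned char tb = 0;
      if (dX > from) { from = dX; tb = 1; }
      if (dY > from) { from = dY; tb = 2; }
      double mv = from + S(i - 1, j - 1);
      if (type == 0 && mv < S(i - 1, j - 1)) { // fresh local start
        mv = S(i - 1, j - 1); tb = 3;
      }
      if (type == 0 && mv < 0) { mv = NEG_INF; }
      M[idx(i, j)] = mv; tbM[idx(i, j)] = tb;
      if (type == 0 && mv > best) { best = mv; bi = i; bj = j; }
      // X: consume i
      double xM = M[idx(i - 1, j)] - open;
      double xX = X[idx(i - 1, j)] - extend;
      double xY = Y[idx(i - 1, j)] - open;
      double xv = xM; unsigned char xtb = 0;
      if (xX > xv) { xv = xX; xtb = 1; }
      if (xY > xv) { xv = xY; xtb = 2; }
      X[idx(i, j)] = xv; tbX[idx(i, j)] = xtb;
      // Y: consume j
      double yM = M[idx(i, j - 1)] - open;
      double yY = Y[idx(i, j - 1)] - extend;
      double yX = X[idx(i, j - 1)] - open;
      double yv = yM; unsigned char ytb = 0;
      if (yY > yv) { yv = yY; ytb = 2; }
      if (yX > yv) { yv = yX; ytb = 1; }
      Y[idx(i, j)] = yv; tbY[idx(i, j)] = ytb;
    }
  }

  int state; // 0=M,1=X,2=Y
  int ci, cj;
  if (type == 1) {
    double gM = M[idx(m, n)], gX = X[idx(m, n)], gY = Y[idx(m, n)];
    best = gM; state = 0;
    if (gX > best) { best = gX; state = 1; }
    if (gY > best) { best = gY; state = 2; }
    ci = m; cj = n;
  } else {
    ci = bi; cj = bj; state = 0;
    if (best <= 0.0) { // no positive-scoring local alignment
      return List::create(_["score"] = 0.0,
                          _["path"] = IntegerMatrix(0, 2),
                          _["i1"] = NA_INTEGER, _["i2"] = NA_INTEGER,
                          _["j1"] = NA_INTEGER, _["j2"] = NA_INTEGER);
    }
  }

  std::vector<int> pi_, pj_;
  while (ci > 0 || cj > 0) {
    unsigned char tb;
    if (state == 0) {
      if (ci == 0 && cj == 0) break;
      tb = tbM[idx(ci, cj)];
      pi_.push_back(ci); pj_.push_back(cj);
      --ci; --cj;
      if (type == 0 && tb == 3) break; // local start
      state = tb;
    } else if (state == 1) {
      tb = tbX[idx(ci, cj)];
      pi_.push_back(ci); pj_.push_back(0);
      --ci;
      state = tb;
    } else {
      tb = tbY[idx(ci, cj)];
      pi_.push_back(0); pj_.push_back(cj);
      --cj;
      state = tb;
    }
    if (type == 1 && ci == 0 && cj == 0) break;
  }
  const int k = (int) pi_.size();
  IntegerMatrix path(k, 2);
  for (int r = 0; r < k; ++r) { // reverse into forward order
    path(r, 0) = pi_[k - 1 - r];
    path(r, 1) = pj_[k - 1 - r];
  }
  int i1 = NA_INTEGER, i2 = NA_INTEGER, j1 = NA_INTEGER, j2 = NA_INTEGER;
  for (int r = 0; r < k; ++r) {
    if (path(r, 0) > 0) { if (i1 == NA_INTEGER) i1 = path(r, 0); i2 = path(r, 0); }
    if (path(r, 1) > 0) { if (j1 == NA_INTEGER) j1 = path(r, 1); j2 = path(r, 1); }
  }
  return List::create(_["score"] = best, _["path"] = path,
                      _["i1"] = i1, _["i2"] = i2, _["j1"] = j1, _["j2"] = j2);
}

// Score-only local (Smith-Waterman) alignment of a PSSM to a residue
// index vector, with rolling rows: used for the shuffle-null threshold
// calibration where tracebacks are not needed.  `scores` is the
// n_states x m profile matrix; `res` holds 1-based residue indices
// (0 = unknown, scoring 0 at every column).
// [[Rcpp::export]]
double cpp_pssm_local_score(NumericMatrix scores, IntegerVector res,
                            double open, double extend) {
  const int m = scores.ncol(), n = res.size();
  std::vector<double> M(n + 1, NEG_INF), Y(n + 1, NEG_INF);
  std::vector<double> Mp(n + 1, NEG_INF), Xp(n + 1, NEG_INF);
  std::vector<double> X(n + 1, NEG_INF);
  double best = 0.0;
  for (int j = 0; j <= n; ++j) { Mp[j] = NEG_INF; Xp[j] = NEG_INF; }
  Mp[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    M[0] = NEG_INF; X[0] = NEG_INF; Y[0] = NEG_INF;
    double diagM = Mp[0], diagX = Xp[0], diagY = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      double s = (res[j - 1] > 0) ? scores(res[j - 1] - 1, i - 1)
                                  : 0.0;
      double from = diagM;
      if (diagX > from) from = diagX;
      if (diagY > from) from = diagY;
      if (from < 0.0) from = 0.0;           // fresh local start
      double mv = from + s;
      diagM = Mp[j]; diagX = Xp[j]; diagY = Y[j];
      M[j] = mv;
      if (mv > best) best = mv;
      double xv = Mp[j] - open;
      if (Xp[j] - extend > xv) xv = Xp[j] - extend;
      X[j] = xv;
      double yv = M[j - 1] - open;
      if (Y[j - 1] - extend > yv) yv = Y[j - 1] - extend;
      if (X[j - 1] - open > yv) yv = X[j - 1] - open;
      Y[j] = yv;
    }
    std::swap(M, Mp);
    std::swap(X, Xp);
  }
  return best;
}
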