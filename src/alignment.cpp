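#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length L costs open + L * ext
// (BLAST convention, so open = 11, ext = 1 reproduces BLASTP defaults).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(List qs, List ss, IntegerMatrix sub,
                              int gap_open, int gap_ext) {
  const int nq = qs.size(), ns = ss.size();
  IntegerMatrix out(nq, ns);
  const int open_first = gap_open + gap_ext;
  // cache subject encodings
  std::vector<std::vector<int>> senc(ns);
  for (int j = 0; j < ns; ++j) {
    IntegerVector v = ss[j];
    senc[j].assign(v.begin(), v.end());
  }
  const int nsym = sub.nrow();
  std::vector<int> submat(nsym * nsym);
  for (int a = 0; a < nsym; ++a)
    for (int b = 0; b < nsym; ++b) submat[a * nsym + b] = sub(a, b);

  for (int qi = 0; qi < nq; ++qi) {
    IntegerVector qv = qs[qi];
    const int m = qv.size();
    std::vector<int> q(qv.begin(), qv.end());
    for (int sj = 0; sj < ns; ++sj) {
      const std::vector<int>& s = senc[sj];
      const int n = (int)s.size();
      std::vector<int> H(n + 1, 0), E(n + 1, INT_MIN / 4);
      int best = 0;
      for (int i = 1; i <= m; ++i) {
        const int* srow = &submat[q[i - 1] * nsym];
        int diag = 0;      // H[i-1][0]
        int Hij = 0;       // H[i][0]
        int F = INT_MIN / 4;
        for (int j = 1; j <= n; ++j) {
          int Eij = std::max(H[j] - open_first, E[j] - gap_ext);   // gap in query (vertical uses H[j] of prev row? careful)
          // E: gap in subject dimension handled per-column below; use two temps:
          // Here: E[j] tracks vertical gaps (along i), F tracks horizontal (along j).
          E[j] = Eij;
          F = std::max(Hij - open_first, F - gap_ext);
          int h = diag + srow[s[j - 1]];
          if (Eij > h) h = Eij;
          if (F > h) h = F;
          if (h < 0) h = 0;
          diag = H[j];
          H[j] = h;
          Hij = h;
          if (h > best) best = h;
        }
      }
      out(qi, sj) = best;
    }
  }
  return out;
}

// Local alignment with traceback. Returns 0-based positions per aligned
// column, -1 for a gap. Tie preference: diagonal, then up (gap in b), then
// left (gap in a); start cell = maximal H, earliest (i, j).
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(IntegerVector av, IntegerVector bv, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int m = av.size(), n = bv.size();
  const int open_first = gap_open + gap_ext;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), INT_MIN / 4);
  std::vector<int> F((m + 1) * (n + 1), INT_MIN / 4);
  std::vector<unsigned char> ptr((m + 1) * (n + 1), 0); // 0 stop 1 diag 2 up(E) 3 left(F)
  std::vector<unsigned char> eext((m + 1) * (n + 1), 0);
  std::vector<unsigned char> fext((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int up = at(i - 1, j), lf = at(i, j - 1), cur = at(i, j);
      int e_open = H[up] - open_first, e_ext = E[up] - gap_ext;
      E[cur] = std::max(e_open, e_ext);
      eext[cur] = e_ext > e_open;   // strictly prefer closing the gap on tie
      int f_open = H[lf] - open_first, f_ext = F[lf] - gap_ext;
      F[cur] = std::max(f_open, f_ext);
      fext[cur] = f_ext > f_open;
      int d = H[at(i - 1, j - 1)] + sub(av[i - 1], bv[j - 1]);
      int h = 0; unsigned char p = 0;
      if (d >= h && d > 0) { h = d; p = 1; }
      if (E[cur] > h) { h = E[cur]; p = 2; }
      if (F[cur] > h) { h = F[cur]; p = 3; }
      H[cur] = h; ptr[cur] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> acol, bcol;
  int i = bi, j = bj;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    int cur = at(i, j);
    if (state == 0) {
      unsigned char p = ptr[cur];
      if (p == 0) break;
      if (p == 1) { acol.push_back(i - 1); bcol.push_back(j - 1); --i; --j; }
      else if (p == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      acol.push_back(i - 1); bcol.push_back(-1);
      if (!eext[cur]) state = 0;
      --i;
    } else {
      acol.push_back(-1); bcol.push_back(j - 1);
      if (!fext[cur]) state = 0;
      --j;
    }
  }
  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(acol.begin(), acol.end()),
                      _["b_pos"] = IntegerVector(bcol.begin(), bcol.end()));
}

// Global profile-profile Needleman-Wunsch with affine gaps. A and B are
// alignment matrices (rows = sequences, cols = alignment columns) holding
// 0-based symbol indices, -1 for gap. Column frequency vectors are counts
// over all rows divided by the row count (gap cells contribute nothing, so
// gappy columns are down-weighted). Returns, for each merged column, the
// source column in A and in B (0-based) or -1 where a gap is inserted.
// [[Rcpp::export(name = ".nw_profile")]]
List nw_profile(IntegerMatrix A, IntegerMatrix B, NumericMatrix sub,
                double gap_open, double gap_ext) {
  const int nsym = sub.nrow();
  const int la = A.ncol(), lb = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();
  const double open_first = gap_open + gap_ext;

  NumericMatrix fa(nsym, la);
  for (int j = 0; j < la; ++j) {
    for (int i = 0; i < ra; ++i) if (A(i, j) >= 0) fa(A(i, j), j) += 1.0;
    for (int k = 0; k < nsym; ++k) fa(k, j) /= ra;
  }
  // mb(k, j) = sum_l sub(k, l) * freqB(l, j)
  NumericMatrix mb(nsym, lb);
  for (int j = 0; j < lb; ++j) {
    std::vector<double> fb(nsym, 0.0);
    for (int i = 0; i < rb; ++i) if (B(i, j) >= 0) fb[B(i, j)] += 1.0;
    for (int k = 0; k < nsym; ++k) fb[k] /= rb;
    for (int k = 0; k < nsym; ++k) {
      double v = 0.0;
      for (int l = 0; l < nsym; ++l) v += sub(k, l) * fb[l];
      mb(k, j) = v;
    }
  }
  auto cell = [&](int i, int j) {
    double v = 0.0;
    for (int k = 0; k < nsym; ++k) {
      double f = fa(k, i);
      if (f != 0.0) v += f * mb(k, j);
    }
    return v;
  };

  std::vector<double> H((la + 1) * (lb + 1), NEG_INF);
  std::vector<double> E((la + 1) * (lb + 1), NEG_INF);
  std::vector<double> F((la + 1) * (lb + 1), NEG_INF);
  std::vector<unsigned char> ptr((la + 1) * (lb + 1), 0); // 1 diag 2 up 3 left
  std::vector<unsigned char> eext((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> fext((la + 1) * (lb + 1), 0);
  auto at = [lb](int i, int j) { return i * (lb + 1) + j; };
  H[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    E[at(i, 0)] = -(gap_open + i * gap_ext);
    H[at(i, 0)] = E[at(i, 0)];
    ptr[at(i, 0)] = 2; eext[at(i, 0)] = i > 1;
  }
  for (int j = 1; j <= lb; ++j) {
    F[at(0, j)] = -(gap_open + j * gap_ext);
    H[at(0, j)] = F[at(0, j)];
    ptr[at(0, j)] = 3; fext[at(0, j)] = j > 1;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int up = at(i - 1, j), lf = at(i, j - 1), cur = at(i, j);
      double e_open = H[up] - open_first, e_ext = E[up] - gap_ext;
      E[cur] = std::max(e_open, e_ext); eext[cur] = e_ext > e_open;
      double f_open = H[lf] - open_first, f_ext = F[lf] - gap_ext;
      F[cur] = std::max(f_open, f_ext); fext[cur] = f_ext > f_open;
      double d = H[at(i - 1, j - 1)] + cell(i - 1, j - 1);
      double h = d; unsigned char p = 1;
      if (E[cur] > h) { h = E[cur]; p = 2; }
      if (F[cur] > h) { h = F[cur]; p = 3; }
      H[cur] = h; ptr[cur] = p;
    }
  }
  std::vector<int> acol, bcol;
  int i = la, j = lb, state = 0;
  while (i > 0 || j > 0) {
    int cur = at(i, j);
    if (state == 0) {
      unsigned char p = ptr[cur];
      if (p == 1) { acol.push_back(i - 1); bcol.push_back(j - 1); --i; --j; }
      else if (p == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      acol.push_back(i - 1); bcol.push_back(-1);
      if (!eext[cur]) state = 0;
      --i;
    } else {
      acol.push_back(-1); bcol.push_back(j - 1);
      if (!fext[cur]) state = 0;
      --j;
    }
  }
  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());
  return List::create(_["score"] = H[at(la, lb)],
                      _["a_col"] = IntegerVector(acol.begin(), acol.end()),
                      _["b_col"] = IntegerVector(bcol.begin(), bcol.end()));
}
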