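// Compiled kernels: pairwise sequence alignment (Gotoh, free end gaps),
// greedy identity clustering, and batched tensor primitives for the
// neural predictor heads.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct AlnStats {
  double identity, cov_a, cov_b;
  int matches, columns;
};

// Global alignment with free end gaps (overlap alignment), match +1,
// mismatch 0, affine interior gaps (open/ext penalties > 0).
// identity = matches / columns between first and last aligned pair;
// cov_x   = residues of x inside that window / length(x).
AlnStats align_pair(const arma::ivec &a, const arma::ivec &b,
                    double gap_open, double gap_ext) {
  const int n = a.n_elem, m = b.n_elem;
  const double NEG = -1e18;
  arma::mat M(n + 1, m + 1, arma::fill::value(NEG));
  arma::mat X(n + 1, m + 1, arma::fill::value(NEG)); // gap in b
  arma::mat Y(n + 1, m + 1, arma::fill::value(NEG)); // gap in a
  // traceback: 0 = start(boundary), 1 = from M, 2 = from X, 3 = from Y
  arma::imat tM(n + 1, m + 1, arma::fill::zeros);
  arma::imat tX(n + 1, m + 1, arma::fill::zeros);
  arma::imat tY(n + 1, m + 1, arma::fill::zeros);
  for (int i = 0; i <= n; ++i) M(i, 0) = 0.0; // free leading gaps
  for (int j = 0; j <= m; ++j) M(0, j) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? 1.0 : 0.0;
      // M: a[i] aligned to b[j]
      double best = M(i - 1, j - 1); int arg = 1;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 2; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 3; }
      M(i, j) = best + s;
      tM(i, j) = (i == 1 || j == 1) && best == 0.0 && arg == 1 &&
                 M(i - 1, j - 1) == 0.0 && (i - 1 == 0 || j - 1 == 0)
                 ? 0 : arg;
      // X: a[i] aligned to a gap
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_ext;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 1; }
      else          { X(i, j) = xe; tX(i, j) = 2; }
      // Y: b[j] aligned to a gap
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_ext;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = 1; }
      else          { Y(i, j) = ye; tY(i, j) = 3; }
    }
  }
  // free trailing gaps: end at an aligned pair on the last row or column
  int bi = n, bj = m; double best = M(n, m);
  for (int j = 1; j <= m; ++j) if (M(n, j) > best) { best = M(n, j); bi = n; bj = j; }
  for (int i = 1; i <= n; ++i) if (M(i, m) > best) { best = M(i, m); bi = i; bj = m; }
  AlnStats st{0.0, 0.0, 0.0, 0, 0};
  if (best <= NEG / 2) return st; // degenerate (empty input)
  int i = bi, j = bj, state = 1;
  int last_i = bi, last_j = bj, first_i = bi, first_j = bj;
  while (i > 0 && j > 0) {
    if (state == 1) {
      if (a[i - 1] == b[j - 1]) st.matches++;
      st.columns++;
      first_i = i; first_j = j;
      state = tM(i, j); --i; --j;
      if (state == 0) state = 1; // boundary start
    } else if (state == 2) {
      st.columns++;
      state = tX(i, j); --i;
    } else {
      st.columns++;
      state = tY(i, j); --j;
    }
  }
  st.identity = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
  st.cov_a = n > 0 ? (double)(last_i - first_i + 1) / n : 0.0;
  st.cov_b = m > 0 ? (double)(last_j - first_j + 1) / m : 0.0;
  (void)last_j; (void)first_j;
  return st;
}

} // namespace

// [[Rcpp::export(name = ".pairwise_identity_cpp")]]
NumericVector pairwise_identity_cpp(IntegerVector a, IntegerVector b,
                                    double gap_open, double gap_ext) {
  arma::ivec av(a.size()), bv(b.size());
  for (int i = 0; i < a.size(); ++i) av[i] = a[i];
  for (int i = 0; i < b.size(); ++i) bv[i] = b[i];
  AlnStats st = align_pair(av, bv, gap_open, gap_ext);
  return NumericVector::create(
      _["identity"] = st.identity, _["cov_a"] = st.cov_a,
      _["cov_b"] = st.cov_b, _["matches"] = (double)st.matches,
      _["columns"] = (double)st.columns);
}

// Greedy representative clustering: records pre-sorted by the caller;
// each record joins the first representative with identity >= min_id and
// both coverages >= min_cov, else founds a new cluster.
// [[Rcpp::export(name = ".cluster_identity_cpp")]]
IntegerVector cluster_identity_cpp(List seqs, double min_id, double min_cov,
                                   double gap_open, double gap_ext) {
  const int n = seqs.size();
  IntegerVector out(n);
  std::vector<arma::ivec> sv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    arma::ivec v(s.size());
    for (int k = 0; k < s.size(); ++k) v[k] = s[k];
    sv[i] = v;
  }
  std::vector<int> reps; // indices of representatives, in founding order
  for (int i = 0; i < n; ++i) {
    int assigned = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      // representatives precede the record in the sort order, so this is
      // the canonical (longer-first) orientation used by pairwise_identity
      AlnStats st = align_pair(sv[reps[r]], sv[i], gap_open, gap_ext);
      if (st.identity >= min_id && st.cov_a >= min_cov && st.cov_b >= min_cov) {
        assigned = (int)r;
        break;
      }
    }
    if (assigned < 0) {
      reps.push_back(i);
      assigned = (int)reps.size() - 1;
    }
    out[i] = assigned; // 0-based cluster id
  }
  return out;
}

// Batched matrix multiply over cube slices: C_k = op(A_k) * op(B_k).
// [[Rcpp::export(name = ".bmm_cpp")]]
arma::cube bmm_cpp(const arma::cube &A, const arma::cube &B,
                   bool ta, bool tb) {
  const arma::uword N = A.n_slices;
  arma::uword r = ta ? A.n_cols : A.n_rows;
  arma::uword c = tb ? B.n_rows : B.n_cols;
  arma::cube C(r, c, N);
  for (arma::uword k = 0; k < N; ++k) {
    const arma::mat &a = A.slice(k);
    const arma::mat &b = B.slice(k);
    if (!ta && !tb)      C.slice(k) = a * b;
    else if (ta && !tb)  C.slice(k) = a.t() * b;
    else if (!ta && tb)  C.slice(k) = a * b.t();
    else                 C.slice(k) = a.t() * b.t();
  }
  return C;
}

// Row-wise softmax per slice with a key mask (n_key x N, 1 = real token).
// Masked keys receive zero probability.
// [[Rcpp::export(name = ".masked_softmax_cpp")]]
arma::cube masked_softmax_cpp(const arma::cube &S, const arma::mat &key_mask) {
  arma::cube P = S;
  const arma::uword N = S.n_slices, Q = S.n_rows, K = S.n_cols;
  for (arma::uword k = 0; k < N; ++k) {
    for (arma::uword i = 0; i < Q; ++i) {
      double mx = -arma::datum::inf;
      for (arma::uword j = 0; j < K; ++j)
        if (key_mask(j, k) > 0.5 && S(i, j, k) > mx) mx = S(i, j, k);
      double Z = 0.0;
      for (arma::uword j = 0; j < K; ++j) {
        double v = key_mask(j, k) > 0.5 ? std::exp(S(i, j, k) - mx) : 0.0;
        P(i, j, k) = v;
        Z += v;
      }
      if (Z > 0) for (arma::uword j = 0; j < K; ++j) P(i, j, k) /= Z;
    }
  }
  return P;
}
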