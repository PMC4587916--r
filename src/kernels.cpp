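#include <Rcpp.h>
using namespace Rcpp;

// Pairwise plug-in mutual information (bits) from pre-binned data.
// D is N x G with integer bin labels in 1..B per column. Diagonal is 0 by
// convention (self-information is not an edge score).
// [[Rcpp::export]]
NumericMatrix mi_from_bins(IntegerMatrix D, int B) {
  const int N = D.nrow(), G = D.ncol();
  NumericMatrix M(G, G);
  std::vector<double> joint(B * B);
  std::vector<double> pi(B), pj(B);
  const double invN = 1.0 / N;
  for (int i = 0; i < G; ++i) {
    for (int j = i + 1; j < G; ++j) {
      std::fill(joint.begin(), joint.end(), 0.0);
      std::fill(pi.begin(), pi.end(), 0.0);
      std::fill(pj.begin(), pj.end(), 0.0);
      for (int k = 0; k < N; ++k) {
        int a = D(k, i) - 1, b = D(k, j) - 1;
        joint[a * B + b] += invN;
        pi[a] += invN;
        pj[b] += invN;
      }
      double mi = 0.0;
      for (int a = 0; a < B; ++a) {
        if (pi[a] == 0.0) continue;
        for (int b = 0; b < B; ++b) {
          double p = joint[a * B + b];
          if (p > 0.0) mi += p * std::log2(p / (pi[a] * pj[b]));
        }
      }
      if (mi < 0.0) mi = 0.0; // numeric floor
      M(i, j) = mi;
      M(j, i) = mi;
    }
  }
  return M;
}

// ARACNE data-processing-inequality pruning: in every triplet (i,j,k) the
// pair whose mutual information falls below the smaller of the other two by
// more than eps is removed. Returns the pruned (symmetric) matrix.
// [[Rcpp::export]]
NumericMatrix dpi_prune(NumericMatrix M, double eps) {
  const int G = M.nrow();
  LogicalMatrix drop(G, G);
  for (int i = 0; i < G; ++i) {
    for (int j = i + 1; j < G; ++j) {
      for (int k = j + 1; k < G; ++k) {
        double mij = M(i, j), mik = M(i, k), mjk = M(j, k);
        if (mij < std::min(mik, mjk) - eps) drop(i, j) = true;
        if (mik < std::min(mij, mjk) - eps) drop(i, k) = true;
        if (mjk < std::min(mij, mik) - eps) drop(j, k) = true;
      }
    }
  }
  NumericMatrix out(G, G);
  for (int i = 0; i < G; ++i)
    for (int j = i + 1; j < G; ++j)
      if (!drop(i, j)) { out(i, j) = M(i, j); out(j, i) = M(i, j); }
  return out;
}

// PCIT pruning: for every triplet, first-order partial correlations of each
// pair given the third gene define a local tolerance (mean of the three
// |partial|/|marginal| ratios); a pair is flagged non-significant in the
// triplet when its |r| falls below tolerance times both other |r|'s (a
// DPI-style comparison on correlations). Pairs flagged in every triplet
// they belong to are zeroed; survivors keep |r|.
// [[Rcpp::export]]
NumericMatrix pcit_prune(NumericMatrix R) {
  const int G = R.nrow();
  LogicalMatrix significant(G, G); // survives at least one triplet
  const double tiny = 1e-12;
  auto pcor = [&](double rij, double rik, double rjk) {
    double den = (1.0 - rik * rik) * (1.0 - rjk * rjk);
    if (den < tiny) den = tiny;
    return (rij - rik * rjk) / std::sqrt(den);
  };
  auto ratio = [&](double partial, double marginal) {
    double m = std::fabs(marginal);
    if (m < tiny) return 1.0;
    double r = std::fabs(partial) / m;
    return r > 1.0 ? 1.0 : r;
  };
  if (G < 3) {
    NumericMatrix out(G, G);
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < G; ++j)
        if (i != j) out(i, j) = std::fabs(R(i, j));
    return out;
  }
  for (int i = 0; i < G; ++i) {
    for (int j = i + 1; j < G; ++j) {
      for (int k = j + 1; k < G; ++k) {
        double rij = R(i, j), rik = R(i, k), rjk = R(j, k);
        double pij = pcor(rij, rik, rjk);
        double pik = pcor(rik, rij, rjk);
        double pjk = pcor(rjk, rij, rik);
        double eps = (ratio(pij, rij) + ratio(pik, rik) + ratio(pjk, rjk)) / 3.0;
        double aij = std::fabs(rij), aik = std::fabs(rik), ajk = std::fabs(rjk);
        if (!(aij < eps * aik && aij < eps * ajk)) significant(i, j) = true;
        if (!(aik < eps * aij && aik < eps * ajk)) significant(i, k) = true;
        if (!(ajk < eps * aij && ajk < eps * aik)) significant(j, k) = true;
      }
    }
  }
  NumericMatrix out(G, G);
  for (int i = 0; i < G; ++i)
    for (int j = i + 1; j < G; ++j)
      if (significant(i, j)) { out(i, j) = std::fabs(R(i, j)); out(j, i) = out(i, j); }
  return out;
}
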