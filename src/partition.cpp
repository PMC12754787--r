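// Simplified McCaskill-style partition function over canonical base pairs.
//
// Energy model: additive per-pair energies (GC, AU, GU; both strand orders),
// no loop terms, hairpin loops of at least `min_loop` unpaired bases,
// pseudoknot-free. Weights are exp(-E/RT).
//
// Inside recursion over intervals [i, j] (1-based):
//   Qb(i,j) = w(i,j) * Q(i+1, j-1)                     (i,j) admissible
//   Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
// Outside recursion, by decreasing span, decomposing on the innermost pair
// (k,l) enclosing (i,j):
//   Qout(i,j) = Q(1,i-1) * Q(j+1,L)
//             + sum_{k<i, l>j} w(k,l) * Q(k+1,i-1) * Q(j+1,l-1) * Qout(k,l)
// and P(i,j) = Qb(i,j) * Qout(i,j) / Q(1,L).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double pair_energy_c(char a, char b, double e_gc, double e_au,
                                   double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return NA_REAL;
}

// [[Rcpp::export]]
NumericMatrix cpp_bpp(std::string seq, double e_gc, double e_au, double e_gu,
                      double rt, int min_loop) {
  const int L = seq.size();
  NumericMatrix P(L, L);
  if (L < min_loop + 2) return P;

  // 1-based matrices with a guard column/row; entries for empty intervals
  // (j < i) are 1 by initialization.
  arma::mat Q(L + 2, L + 2, arma::fill::ones);
  arma::mat Qb(L + 2, L + 2, arma::fill::zeros);
  arma::mat W(L + 2, L + 2, arma::fill::zeros);  // Boltzmann pair weights

  for (int i = 1; i <= L; ++i)
    for (int j = i + min_loop + 1; j <= L; ++j) {
      double e = pair_energy_c(seq[i - 1], seq[j - 1], e_gc, e_au, e_gu);
      if (!ISNA(e)) W(i, j) = std::exp(-e / rt);
    }

  for (int len = 2; len <= L; ++len) {
    for (int i = 1; i + len - 1 <= L; ++i) {
      int j = i + len - 1;
      if (W(i, j) > 0.0) Qb(i, j) = W(i, j) * Q(i + 1, j - 1);
      double q = Q(i, j - 1);
      for (int k = i; k <= j - min_loop - 1; ++k)
        if (Qb(k, j) > 0.0) q += Q(i, k - 1) * Qb(k, j);
      Q(i, j) = q;
    }
  }
  const double Z = Q(1, L);
  if (!std::isfinite(Z))
    stop("partition function overflowed; sequence too long for the unscaled recursion");

  arma::mat Qout(L + 2, L + 2, arma::fill::zeros);
  for (int len = L; len >= min_loop + 2; --len) {
    for (int i = 1; i + len - 1 <= L; ++i) {
      int j = i + len - 1;
      if (Qb(i, j) == 0.0) continue;
      double qo = Q(1, i - 1) * Q(j + 1, L);
      for (int k = 1; k < i; ++k)
        for (int l = j + 1; l <= L; ++l)
          if (W(k, l) > 0.0 && Qout(k, l) > 0.0)
            qo += W(k, l) * Q(k + 1, i - 1) * Q(j + 1, l - 1) * Qout(k, l);
      Qout(i, j) = qo;
      double p = Qb(i, j) * qo / Z;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  }
  return P;
}
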