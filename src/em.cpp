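#include <Rcpp.h>
using namespace Rcpp;

// Two-locus haplotype-frequency EM on a 3x3 unphased genotype count
// table.  cnt[g1 + 3*g2] holds the number of individuals with dosage
// g1 at the first locus and g2 at the second (dosages count the A /
// B alleles).  Only the double heterozygote (1,1) is phase-ambiguous.
// Frequencies are initialized at linkage equilibrium and iterated
// until the largest absolute frequency change is below tol.
static void em_counts(const double cnt[9], double tol, int maxit,
                      double p[4], int *iters, bool *converged,
                      double *loglik) {
  // haplotype order: 0 = AB, 1 = Ab, 2 = aB, 3 = ab
  double n = 0.0;
  for (int i = 0; i < 9; ++i) n += cnt[i];
  if (n <= 0.0) {
    p[0] = p[1] = p[2] = p[3] = NA_REAL;
    *iters = 0; *converged = false; *loglik = NA_REAL;
    return;
  }
  // fully observed haplotype contributions (everything but (1,1))
  // genotype (g1,g2): counts of A = g1, B = g2 over two haplotypes
  const double nAA = cnt[2] + cnt[5] + cnt[8];           // g1 == 2 col sums
  const double n11 = cnt[4];                             // double het
  // allele counts
  double cA = 0.0, cB = 0.0;
  for (int g2 = 0; g2 < 3; ++g2)
    for (int g1 = 0; g1 < 3; ++g1) {
      cA += cnt[g1 + 3 * g2] * g1;
      cB += cnt[g1 + 3 * g2] * g2;
    }
  (void)nAA;
  const double two_n = 2.0 * n;
  const double pA = cA / two_n, pB = cB / two_n;
  // unambiguous haplotype counts
  // (2,2): 2 AB; (2,1): AB + Ab; (2,0): 2 Ab; (1,2): AB + aB;
  // (1,0): Ab + ab; (0,2): 2 aB; (0,1): aB + ab; (0,0): 2 ab
  const double base_AB = 2.0 * cnt[2 + 3 * 2] + cnt[2 + 3 * 1] + cnt[1 + 3 * 2];
  const double base_Ab = 2.0 * cnt[2 + 3 * 0] + cnt[2 + 3 * 1] + cnt[1 + 3 * 0];
  const double base_aB = 2.0 * cnt[0 + 3 * 2] + cnt[1 + 3 * 2] + cnt[0 + 3 * 1];
  const double base_ab = 2.0 * cnt[0 + 3 * 0] + cnt[1 + 3 * 0] + cnt[0 + 3 * 1];

  // init at linkage equilibrium
  p[0] = pA * pB; p[1] = pA * (1 - pB); p[2] = (1 - pA) * pB;
  p[3] = (1 - pA) * (1 - pB);
  *converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double w; // P(double het is AB/ab phase)
    const double coup = p[0] * p[3], rep = p[1] * p[2];
    if (coup + rep > 0.0) w = coup / (coup + rep); else w = 0.5;
    double q[4];
    q[0] = (base_AB + w * n11) / two_n;
    q[1] = (base_Ab + (1.0 - w) * n11) / two_n;
    q[2] = (base_aB + (1.0 - w) * n11) / two_n;
    q[3] = (base_ab + w * n11) / two_n;
    double delta = 0.0;
    for (int i = 0; i < 4; ++i) {
      double d = std::fabs(q[i] - p[i]);
      if (d > delta) delta = d;
      p[i] = q[i];
    }
    if (delta < tol) { *converged = true; ++it; break; }
  }
  *iters = it;
  // multinomial log-likelihood of the genotype table
  double pr[9];
  pr[2 + 3 * 2] = p[0] * p[0];
  pr[2 + 3 * 1] = 2.0 * p[0] * p[1];
  pr[2 + 3 * 0] = p[1] * p[1];
  pr[1 + 3 * 2] = 2.0 * p[0] * p[2];
  pr[1 + 3 * 1] = 2.0 * (p[0] * p[3] + p[1] * p[2]);
  pr[1 + 3 * 0] = 2.0 * p[1] * p[3];
  pr[0 + 3 * 2] = p[2] * p[2];
  pr[0 + 3 * 1] = 2.0 * p[2] * p[3];
  pr[0 + 3 * 0] = p[3] * p[3];
  double ll = 0.0;
  for (int i = 0; i < 9; ++i) {
    if (cnt[i] > 0.0) {
      if (pr[i] <= 0.0) { ll = R_NegInf; break; }
      ll += cnt[i] * std::log(pr[i]);
    }
  }
  *loglik = ll;
}

// [[Rcpp::export(name = ".em_pair_cpp")]]
NumericVector em_pair_cpp(NumericVector cnt9, double tol, int maxit) {
  double cnt[9];
  for (int i = 0; i < 9; ++i) cnt[i] = cnt9[i];
  double p[4]; int iters; bool conv; double ll;
  em_counts(cnt, tol, maxit, p, &iters, &conv, &ll);
  return NumericVector::create(p[0], p[1], p[2], p[3],
                               (double)iters, conv ? 1.0 : 0.0, ll);
}

// Mean D^2 over all different-chromosome variant pairs of a dosage
// matrix (samples x variants, NA = missing).  EM is run per pair on
// the samples non-missing at both loci.
// [[Rcpp::export(name = ".mean_d2_cross_cpp")]]
List mean_d2_cross_cpp(IntegerMatrix G, IntegerVector chrom,
                       double tol, int maxit) {
  const int n = G.nrow(), m = G.ncol();
  double sum_d2 = 0.0;
  R_xlen_t n_pairs = 0, n_nonconv = 0;
  for (int j = 0; j < m; ++j) {
    for (int k = j + 1; k < m; ++k) {
      if (chrom[j] == chrom[k]) continue;
      double cnt[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (int i = 0; i < n; ++i) {
        int g1 = G(i, j), g2 = G(i, k);
        if (g1 == NA_INTEGER || g2 == NA_INTEGER) continue;
        cnt[g1 + 3 * g2] += 1.0;
      }
      double p[4]; int iters; bool conv; double ll;
      em_counts(cnt, tol, maxit, p, &iters, &conv, &ll);
      if (ISNA(p[0])) continue;
      const double pA = p[0] + p[1], pB = p[0] + p[2];
      const double d = p[0] - pA * pB;
      sum_d2 += d * d;
      ++n_pairs;
      if (!conv) ++n_nonconv;
    }
  }
  return List::create(
    _["mean_d2"] = n_pairs > 0 ? sum_d2 / (double)n_pairs : NA_REAL,
    _["n_pairs"] = (double)n_pairs,
    _["n_nonconverged"] = (double)n_nonconv);
}
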