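#include <Rcpp.h>
using namespace Rcpp;

// Mosaic-of-founder-haplotypes genotype generator.
//
// Each of the 2*n_ind haplotypes walks along the variants, copying alleles
// from a pool of K founder haplotypes; between consecutive variants a
// recombination breakpoint occurs with probability 1 - exp(-ld_decay * dcM),
// after which a founder is re-drawn uniformly.  Population LD therefore
// decays approximately as exp(-ld_decay * d) times the founder-pool allele
// correlation, giving blocky LD that vanishes beyond a few cM.
//
// Founder alleles are drawn per variant with a frequency sampled uniformly
// in [maf_lo, maf_hi]; a draw is rejected (fresh frequency + alleles) until
// the empirical allele frequency implied by the realized haplotype
// assignments falls inside the MAF range, which also rules out monomorphic
// columns.  When `founder_alleles` is supplied (K x m), it is used as-is
// (no rejection) so that a second panel can share a drifted founder pool.
//
// Uses R's RNG throughout: results are reproducible under set.seed().
// [[Rcpp::export]]
List mosaic_genotypes_cpp(int n_ind,
                          NumericVector pos_cm,
                          int n_founders,
                          double ld_decay,
                          double maf_lo,
                          double maf_hi,
                          Nullable<IntegerMatrix> founder_alleles,
                          int max_tries) {

  const int m = pos_cm.size();
  const int n_hap = 2 * n_ind;
  const int K = n_founders;

  // breakpoint probability between variant j-1 and j
  std::vector<double> p_break(m, 1.0);
  for (int j = 1; j < m; j++) {
    double d = pos_cm[j] - pos_cm[j - 1];
    if (d < 0) stop("genetic positions must be non-decreasing");
    p_break[j] = (ld_decay == R_PosInf) ? 1.0 : 1.0 - std::exp(-ld_decay * d);
  }

  IntegerMatrix alleles(K, m);     // founder allele pool (0/1)
  bool have_pool = founder_alleles.isNotNull();
  if (have_pool) {
    IntegerMatrix given(founder_alleles);
    if (given.nrow() != K || given.ncol() != m)
      stop("founder_alleles must be n_founders x n_variants");
    alleles = given;
  }

  NumericMatrix G(n_ind, m);
  NumericVector freq(m);
  std::vector<int> cur(n_hap);     // current founder per haplotype
  std::vector<int> w(K);           // haplotype count per founder at site j

  for (int h = 0; h < n_hap; h++) cur[h] = (int)(unif_rand() * K) % K;

  for (int j = 0; j < m; j++) {
    if (j > 0 && p_break[j] > 0) {
      for (int h = 0; h < n_hap; h++)
        if (unif_rand() < p_break[j]) cur[h] = (int)(unif_rand() * K) % K;
    }
    std::fill(w.begin(), w.end(), 0);
    for (int h = 0; h < n_hap; h++) w[cur[h]]++;

    if (!have_pool) {
      // rejection: freq implied by assignments must give MAF in range
      double best_dist = R_PosInf;
      std::vector<int> best(K, 0), a(K);
      for (int t = 0; t < max_tries; t++) {
        double pj = maf_lo + unif_rand() * (maf_hi - maf_lo);
        if (unif_rand() < 0.5) pj = 1.0 - pj;  // either allele can be minor
        double f = 0.0;
        for (int k = 0; k < K; k++) {
          a[k] = (unif_rand() < pj) ? 1 : 0;
          f += (double)w[k] * a[k];
        }
        f /= n_hap;
        double maf = std::min(f, 1.0 - f);
        double dist = (maf < maf_lo) ? (maf_lo - maf)
                    : (maf > maf_hi) ? (maf - maf_hi) : 0.0;
        if (dist < best_dist) { best_dist = dist; best = a; }
        if (dist == 0.0) break;
      }
      for (int k = 0; k < K; k++) alleles(k, j) = best[k];
    }

    double f = 0.0;
    for (int i = 0; i < n_ind; i++) {
      double g = alleles(cur[2 * i], j) + alleles(cur[2 * i + 1], j);
      G(i, j) = g;
      f += g;
    }
    freq[j] = f / n_hap;
  }

  return List::create(_["G"] = G, _["freq"] = freq,
                      _["founder_alleles"] = alleles);
}
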