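#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler on the scaled-effect parameterization:
//   beta_hat | beta ~ N(R beta, diag(1/n_j)),  beta_j ~ p N(0, s2) + (1-p) d0,
// with s2 = h2 / (M p).  Residual u_j = beta_hat_j - c ((R beta)_j - beta_j)
// where c = shrink_corr multiplies off-diagonal LD only (sampler
// regularization; the h2 update below always uses the unshrunk R).
//
// Posterior inclusion probability and slab draw follow the standard
// conjugate forms; with allow_jump = false a draw whose sign differs from
// the variant's current non-zero effect is set to 0 for that sweep, forcing
// effects through zero before changing sign.
//
// auto mode: after each sweep, M_c = #{beta_j != 0},
//   p ~ Beta(1 + M_c, 1 + M - M_c),  h2 <- beta' R beta (unshrunk R).
//
// The rotated residual v = R beta is cached and updated only at coordinates
// whose effect changed, touching only stored neighbors.
// [[Rcpp::export]]
List gibbs_sampler_cpp(IntegerVector ld_p, IntegerVector ld_i, NumericVector ld_x,
                       NumericVector beta_hat, NumericVector n,
                       int burn_in, int num_iter,
                       double p_init, double h2_init, bool auto_mode,
                       double shrink, bool allow_jump, bool keep_samples,
                       double h2_div, double p_pin_thr, int p_pin_sweeps) {

  const int m = beta_hat.size();
  const int total = burn_in + num_iter;
  double p = p_init, h2 = h2_init;

  std::vector<double> beta(m, 0.0), v(m, 0.0);
  NumericVector postmean(m);
  NumericVector p_tr(total), h2_tr(total);
  IntegerVector mc_tr(total);
  NumericMatrix samples = keep_samples ? NumericMatrix(m, num_iter)
                                       : NumericMatrix(0, 0);

  bool divergent = false, aborted = false;
  int n_kept = 0, pin_run = 0, sweeps_done = 0;

  for (int t = 0; t < total; t++) {
    double s2 = h2 / (m * p);
    double log_odds_prior = std::log(p) - std::log1p(-p);

    for (int j = 0; j < m; j++) {
      double u = beta_hat[j] - shrink * (v[j] - beta[j]);
      double njs2 = n[j] * s2;
      double shrink_fac = njs2 / (1.0 + njs2);
      double logit = log_odds_prior - 0.5 * std::log1p(njs2)
                   + 0.5 * u * u * n[j] * shrink_fac;
      double pj = (logit > 35) ? 1.0 : (logit < -35) ? 0.0
                : 1.0 / (1.0 + std::exp(-logit));
      double bnew = 0.0;
      if (unif_rand() < pj) {
        bnew = u * shrink_fac + norm_rand() * std::sqrt(s2 / (1.0 + njs2));
        if (!allow_jump && beta[j] != 0.0 && bnew * beta[j] < 0) bnew = 0.0;
      }
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int k = ld_p[j]; k < ld_p[j + 1]; k++) v[ld_i[k]] += ld_x[k] * d;
        beta[j] = bnew;
      }
    }

    int Mc = 0;
    double h2_cur = 0.0;
    for (int j = 0; j < m; j++) {
      if (beta[j] != 0.0) Mc++;
      h2_cur += beta[j] * v[j];
    }

    if (!R_finite(h2_cur) || h2_cur > 4.0 * h2_div) {
      divergent = true; aborted = true; sweeps_done = t;
      break;
    }
    if (h2_cur > h2_div) divergent = true;
    if ((double)Mc / m >= p_pin_thr) {
      if (++pin_run > p_pin_sweeps) divergent = true;
    } else pin_run = 0;

    if (auto_mode) {
      p = R::rbeta(1.0 + Mc, 1.0 + m - Mc);
      if (p < 1e-5) p = 1e-5;
      if (p > 1 - 1e-5) p = 1 - 1e-5;
      // no floor: on null data the chain may collapse to the exact zero
      // state (h2 = 0 makes the slab degenerate at 0), which is the
      // correct absorbing posterior there
      h2 = std::max(h2_cur, 0.0);
    }

    p_tr[t] = p; h2_tr[t] = h2_cur; mc_tr[t] = Mc;

    if (t >= burn_in) {
      for (int j = 0; j < m; j++) postmean[j] += beta[j];
      if (keep_samples)
        for (int j = 0; j < m; j++) samples(j, n_kept) = beta[j];
      n_kept++;
    }
    sweeps_done = t + 1;
  }

  if (n_kept > 0) for (int j = 0; j < m; j++) postmean[j] /= n_kept;

  List out = List::create(_["postmean"] = postmean,
                          _["p_trace"] = p_tr, _["h2_trace"] = h2_tr,
                          _["mc_trace"] = mc_tr,
                          _["divergent"] = divergent, _["aborted"] = aborted,
                          _["n_kept"] = n_kept, _["sweeps_done"] = sweeps_done);
  if (keep_samples) out["samples"] = samples;
  return out;
}
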