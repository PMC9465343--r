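#include <Rcpp.h>
using namespace Rcpp;

// Per-variant simple linear regression (with intercept), each variant on an
// independent seeded subsample of the stated fraction -- emulating a
// meta-analysis where different cohorts cover different variants.
// Zero-variance variants within their subsample get NA effect/se and a flag.
// Uses R's RNG (partial Fisher-Yates) so set.seed() makes runs reproducible.
// [[Rcpp::export]]
List gwas_linreg_cpp(NumericMatrix X, NumericVector y, NumericVector frac) {
  const int n = X.nrow(), m = X.ncol();
  if (y.size() != n) stop("y length must equal nrow(X)");
  if (frac.size() != m) stop("frac must have one entry per variant");

  NumericVector beta(m), se(m), freq(m);
  IntegerVector nj(m), zero_var(m);
  std::vector<int> idx(n);

  for (int j = 0; j < m; j++) {
    double fr = frac[j];
    if (fr <= 0 || fr > 1) stop("subsample fractions must be in (0, 1]");
    int ns = (int)std::lround(fr * n);
    if (ns < 3) ns = std::min(3, n);
    nj[j] = ns;

    const double* xj = &X(0, j);
    double sx = 0, sy = 0, sxx = 0, sxy = 0, syy = 0;

    if (ns == n) {
      for (int i = 0; i < n; i++) {
        double xv = xj[i], yv = y[i];
        sx += xv; sy += yv; sxx += xv * xv; sxy += xv * yv; syy += yv * yv;
      }
    } else {
      // partial Fisher-Yates over 0..n-1, independent draw per variant
      for (int i = 0; i < n; i++) idx[i] = i;
      for (int t = 0; t < ns; t++) {
        int r = t + (int)(unif_rand() * (n - t));
        if (r >= n) r = n - 1;
        std::swap(idx[t], idx[r]);
        int i = idx[t];
        double xv = xj[i], yv = y[i];
        sx += xv; sy += yv; sxx += xv * xv; sxy += xv * yv; syy += yv * yv;
      }
    }

    double Sxx = sxx - sx * sx / ns;
    double Sxy = sxy - sx * sy / ns;
    double Syy = syy - sy * sy / ns;
    freq[j] = sx / (2.0 * ns);

    if (Sxx <= 0) {
      beta[j] = NA_REAL; se[j] = NA_REAL; zero_var[j] = 1;
      continue;
    }
    double b = Sxy / Sxx;
    double rss = Syy - b * Sxy;
    if (rss < 0) rss = 0;
    beta[j] = b;
    se[j] = (ns > 2) ? std::sqrt(rss / (ns - 2) / Sxx) : 0.0;
  }

  return List::create(_["beta"] = beta, _["se"] = se, _["n"] = nj,
                      _["freq"] = freq, _["zero_var"] = zero_var);
}
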