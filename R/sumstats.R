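#' Build a summary-statistics table
#'
#' Creates the per-variant GWAS summary-statistics container used throughout
#' the package: a `data.frame` with class `"sumstats"` and study-level
#' metadata stored as attributes.  Binary traits are handled on the
#' effective-sample-size scale: supply `n` already converted with
#' [effective_sample_size()], or per-variant `n_cases`/`n_controls` columns
#' from which `n` is derived at construction.
#'
#' @param chr chromosome label (recycled).
#' @param pos physical position, bp, 1-based.
#' @param a0,a1 reference and effect allele (non-identical strings).
#' @param beta per-allele marginal effect of `a1` (trait units per allele).
#' @param beta_se its standard error (> 0).
#' @param n per-variant sample size (effective sample size for binary
#'   traits).  Defaults to `N` for all variants.
#' @param freq optional allele frequency of `a1` in (0, 1).
#' @param info optional imputation INFO score in (0, 1].
#' @param N total (effective) sample size of the study; default `max(n)`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls study-level case/control counts (binary only).
#'
#' @return A `data.frame` of class `"sumstats"` with columns `chr`, `pos`,
#'   `a0`, `a1`, `beta`, `beta_se`, `n` and, when supplied, `freq`, `info`.
#' @export
sumstats <- function(chr, pos, a0, a1, beta, beta_se, n = NULL,
                     freq = NULL, info = NULL, N = NULL,
                     trait_type = c("quantitative", "binary"),
                     n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  m <- length(pos)
  if (is.null(n)) {
    if (is.null(N)) stop("supply per-variant `n` or a total `N`")
    n <- rep(N, m)
  }
  df <- data.frame(chr = rep_len(chr, m), pos = pos,
                   a0 = as.character(a0), a1 = as.character(a1),
                   beta = beta, beta_se = beta_se, n = n,
                   stringsAsFactors = FALSE)
  if (!is.null(freq)) df$freq <- freq
  if (!is.null(info)) df$info <- info

  # se = 0 is tolerated (perfect fits in noise-free simulations)
  ok_se <- is.na(df$beta_se) | df$beta_se >= 0
  if (!all(ok_se)) stop("beta_se must be >= 0 where present")
  if (!is.null(freq) && any(freq <= 0 | freq >= 1, na.rm = TRUE))
    stop("freq must be in (0, 1) where present")
  if (!is.null(info) && any(info <= 0 | info > 1, na.rm = TRUE))
    stop("info must be in (0, 1] where present")
  if (any(df$a0 == df$a1)) stop("a0 and a1 must differ")

  attr(df, "N") <- if (is.null(N)) max(df$n, na.rm = TRUE) else N
  attr(df, "trait_type") <- trait_type
  attr(df, "n_cases") <- n_cases
  attr(df, "n_controls") <- n_controls
  class(df) <- c("sumstats", "data.frame")
  df
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %d variants, trait = %s, N = %s\n",
              nrow(x), attr(x, "trait_type"),
              format(attr(x, "N"), big.mark = ",")))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

trait_type <- function(stats) attr(stats, "trait_type") %||% "quantitative"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotype standard deviations inferred from summary statistics
#'
#' For a quantitative trait, `sd(G_j) = sd(y) / sqrt(n_j se_j^2 + beta_j^2)`;
#' for a binary trait analysed with logistic regression,
#' `sd(G_j) = 2 / sqrt(n_eff_j se_j^2 + beta_j^2)` with `n` on the
#' effective-sample-size scale.  Variants with missing `se` or `n` yield
#' `NA` (a count is reported via a message; rows are never dropped).
#'
#' @param stats a [sumstats] table.
#' @param sd_y phenotype standard deviation (quantitative traits); when
#'   `NULL` it is estimated with [estimate_var_y()].
#' @return Numeric vector of inferred genotype standard deviations, aligned
#'   with `stats`.
#' @export
sd_from_sumstats <- function(stats, sd_y = NULL) {
  miss <- is.na(stats$beta_se) | is.na(stats$n) | is.na(stats$beta)
  if (any(miss))
    message(sum(miss), " variant(s) with missing se/n: NA emitted")
  denom <- sqrt(stats$n * stats$beta_se^2 + stats$beta^2)
  out <- if (trait_type(stats) == "binary") {
    2 / denom
  } else {
    if (is.null(sd_y)) sd_y <- sqrt(estimate_var_y(stats))
    sd_y / denom
  }
  out[miss] <- NA_real_
  out
}

#' Genotype standard deviations expected from allele frequencies
#'
#' Under Hardy-Weinberg equilibrium, `sd(G_j) = sqrt(2 f_j (1 - f_j))`;
#' for imputed dosages the variance is further multiplied by the INFO score,
#' so `sd_af_j = sqrt(2 f_j (1 - f_j) INFO_j)`.
#'
#' @param f allele-frequency vector in (0, 1); values outside give `NA`.
#' @param info optional INFO vector (default 1).
#' @return Numeric vector of expected genotype standard deviations.
#' @export
sd_from_af <- function(f, info = NULL) {
  if (is.null(info)) info <- 1
  bad <- !is.na(f) & (f <= 0 | f >= 1)
  f[bad] <- NA_real_
  sqrt(2 * f * (1 - f) * info)
}

#' Estimate the phenotypic variance from summary statistics
#'
#' Returns the first percentile over variants of
#' `0.5 (N se_j^2 + beta_j^2)`.  The maximum genotype variance under HWE is
#' 0.5 (at frequency one half), so this quantity is an upper envelope for
#' `var(y)` whose lower tail approximates the minimum while remaining robust
#' to outlier variants.  Percentiles use linear interpolation between order
#' statistics ([quantile()] type 7).
#'
#' @param stats a quantitative-trait [sumstats] table.
#' @param N total sample size; defaults to the table's `N` attribute.
#' @return Scalar estimate of `var(y)` (trait units squared).
#' @export
estimate_var_y <- function(stats, N = NULL) {
  if (trait_type(stats) == "binary")
    stop("var(y) is not needed for binary traits; use the effective-n path ",
         "(sd_from_sumstats / impute_n handle binary traits directly)")
  if (is.null(N)) N <- attr(stats, "N")
  x <- 0.5 * (N * stats$beta_se^2 + stats$beta^2)
  unname(quantile(x, 0.01, na.rm = TRUE, type = 7))
}

#' Impute per-variant GWAS sample sizes
#'
#' Inverts the standard-deviation identity: for quantitative traits
#' `n_j = (var(y) / var(G_j) - beta_j^2) / se_j^2`; for binary traits
#' `n_eff_j = (4 / var(G_j) - beta_j^2) / se_j^2`.  `var(G_j)` comes from
#' the reported allele frequencies (and INFO when present) via
#' [sd_from_af()].  Estimates are clamped to `[0.5 N, 1.1 N]` by default;
#' the returned object records which variants were clamped so QC can remove
#' them instead.
#'
#' @param stats a [sumstats] table with `freq` (and ideally `info`).
#' @param var_y phenotypic variance (quantitative); estimated with
#'   [estimate_var_y()] when `NULL`.
#' @param clamp two multipliers of `N` bounding the estimates, or `NULL`
#'   to disable clamping.
#' @param var_g optional genotype-variance vector overriding the
#'   frequency-based one.
#' @return A `data.frame` with columns `n_imp` (clamped estimate),
#'   `n_raw` (unclamped) and `clamped` (logical flag).
#' @export
impute_n <- function(stats, var_y = NULL, clamp = c(0.5, 1.1), var_g = NULL) {
  if (is.null(var_g)) {
    if (is.null(stats$freq)) stop("impute_n needs `freq` (or `var_g`)")
    var_g <- sd_from_af(stats$freq, stats$info)^2
  }
  num <- if (trait_type(stats) == "binary") {
    4 / var_g - stats$beta^2
  } else {
    if (is.null(var_y)) var_y <- estimate_var_y(stats)
    var_y / var_g - stats$beta^2
  }
  n_raw <- num / stats$beta_se^2
  n_raw[!is.na(var_g) & var_g <= 0] <- NA_real_
  n_imp <- n_raw
  clamped <- rep(FALSE, length(n_raw))
  if (!is.null(clamp)) {
    N <- attr(stats, "N")
    lo <- clamp[1] * N; hi <- clamp[2] * N
    clamped <- !is.na(n_raw) & (n_raw < lo | n_raw > hi)
    n_imp <- pmin(pmax(n_raw, lo), hi)
    n_imp[is.na(n_raw)] <- NA_real_
  }
  data.frame(n_imp = n_imp, n_raw = n_raw, clamped = clamped)
}

#' Effective sample size of case-control studies
#'
#' Per study, `n_eff = 4 / (1/n_cases + 1/n_controls)`, with the continuity
#' convention that a study with zero cases or zero controls contributes 0.
#' For a meta-analysis, supply per-study vectors: the effective sample size
#' of the meta-analysis is the sum of the per-study values -- not the value
#' computed from the total numbers of cases and controls, which can be
#' grossly overestimated when studies are imbalanced.
#'
#' @param n_cases,n_controls non-negative per-study counts (same length).
#' @return Scalar: the summed effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (length(n_cases) != length(n_controls))
    stop("n_cases and n_controls must have the same length")
  if (any(n_cases < 0) || any(n_controls < 0))
    stop("counts must be non-negative")
  per_study <- ifelse(n_cases == 0 | n_controls == 0, 0,
                      4 / (1 / n_cases + 1 / n_controls))
  sum(per_study)
}

#' Scaled (correlation-scale) marginal effects
#'
#' Converts per-allele GWAS effects to the standardized-genotype,
#' standardized-phenotype scale used by the PGS solvers:
#' `beta_scaled_j = beta_j / sqrt(n_j se_j^2 + beta_j^2)`, numerically the
#' marginal correlation `Z / sqrt(n + Z^2)`.  The inverse map is
#' [per_allele_effects()], exact on the same table.
#'
#' @param stats a [sumstats] table.
#' @param sd_y phenotype sd used for the reported `sd_ss` (quantitative);
#'   estimated when `NULL`.
#' @return A list of class `"scaled_stats"` with `beta_hat` (scaled
#'   effects), `z`, `sd_ss` (inferred genotype sd), `n`, and `sd_y`.
#' @export
scaled_effects <- function(stats, sd_y = NULL) {
  denom <- sqrt(stats$n * stats$beta_se^2 + stats$beta^2)
  beta_hat <- stats$beta / denom
  beta_hat[!is.na(denom) & denom == 0] <- NA_real_
  if (trait_type(stats) == "binary") {
    sd_y <- 2
  } else if (is.null(sd_y)) {
    sd_y <- sqrt(estimate_var_y(stats))
  }
  structure(list(beta_hat = beta_hat,
                 z = stats$beta / stats$beta_se,
                 sd_ss = sd_y / denom,
                 n = stats$n, sd_y = sd_y),
            class = "scaled_stats")
}

#' Convert scaled effects back to the per-allele scale
#'
#' `beta_j = beta_scaled_j * sd(y) / sd_ss_j`, the exact inverse of
#' [scaled_effects()] on the same summary statistics.  Used to turn fitted
#' scaled effect vectors into polygenic-score weights.
#'
#' @param beta_scaled scaled effect vector (or matrix, one fit per column).
#' @param stats the [sumstats] table the scaling came from.
#' @param sd_y phenotype sd; must match the one used in [scaled_effects()].
#' @return Per-allele effects with the shape of `beta_scaled`.
#' @export
per_allele_effects <- function(beta_scaled, stats, sd_y = NULL) {
  sc <- scaled_effects(stats, sd_y = sd_y)
  beta_scaled * (sc$sd_y / sc$sd_ss)
}

#' INFO-based corrections of summary statistics
#'
#' A correction is a named exponent triple `(a_beta, a_se, a_n)` applied as
#' `beta * INFO^a_beta`, `se * INFO^a_se`, `n * INFO^a_n`.  Presets:
#' `sqrt_info = (1/2, 1/2, 0)` (rescales effect and standard error together,
#' preserving Z), `info = (1, 0, 1)` (matches the multiple-imputation
#' relation, with `n INFO` as the new sample size), and
#' `in_between = (1, 1/2, 1)`.  The name-to-triple mapping is configuration:
#' pass `exponents` for a custom triple.
#'
#' @param name one of `"sqrt_info"`, `"info"`, `"in_between"`, `"custom"`.
#' @param exponents numeric length-3 vector for `name = "custom"`.
#' @return An object of class `"info_correction"`.
#' @export
info_correction <- function(name = c("sqrt_info", "info", "in_between", "custom"),
                            exponents = NULL) {
  name <- match.arg(name)
  presets <- list(sqrt_info = c(0.5, 0.5, 0),
                  info = c(1, 0, 1),
                  in_between = c(1, 0.5, 1))
  if (name == "custom") {
    if (is.null(exponents) || length(exponents) != 3)
      stop("custom correction needs a length-3 exponent triple")
  } else {
    exponents <- presets[[name]]
  }
  if (any(exponents < 0 | exponents > 1)) stop("exponents must be in [0, 1]")
  structure(list(name = name,
                 exponents = stats::setNames(exponents, c("beta", "se", "n"))),
            class = "info_correction")
}

#' Apply an INFO-based correction to summary statistics
#'
#' Returns a copy of `stats` with `beta`, `beta_se` and `n` rescaled by the
#' correction's exponent triple (see [info_correction()]).  The correction
#' applied is recorded in the `info_correction` attribute of the result.
#'
#' @param stats a [sumstats] table with an `info` column.
#' @param correction an [info_correction()] object or a preset name.
#' @param default_info fallback INFO used (with a warning) when the `info`
#'   column is absent; `NULL` (default) makes that an error.
#' @return The corrected [sumstats] table.
#' @export
apply_info_correction <- function(stats, correction = "sqrt_info",
                                  default_info = NULL) {
  if (is.character(correction)) correction <- info_correction(correction)
  stopifnot(inherits(correction, "info_correction"))
  info <- stats$info
  if (is.null(info)) {
    if (is.null(default_info))
      stop("`info` column missing and no default_info fallback given")
    warning("`info` missing; using default_info = ", default_info)
    info <- rep(default_info, nrow(stats))
  }
  e <- correction$exponents
  out <- stats
  out$beta <- stats$beta * info^e[["beta"]]
  out$beta_se <- stats$beta_se * info^e[["se"]]
  out$n <- stats$n * info^e[["n"]]
  attr(out, "info_correction") <- correction
  out
}

#' Power ratio of mixed-model versus linear-regression association tests
#'
#' Summarizes the chi-squared boost of a BOLT-LMM-style analysis over plain
#' linear regression across (genome-wide significant) variants, interpreted
#' as the multiplicative increase in effective sample size.  Both the mean
#' of per-variant ratios (default) and the ratio of means are computed; the
#' latter is invariant to common rescaling of both vectors, both are
#' invariant to permuting variants.
#'
#' @param chi2_boosted,chi2_linear aligned chi-squared vectors.
#' @param significant_mask logical vector selecting the variants to use.
#' @param type which summary to return.
#' @return Scalar ratio, with both summaries in attribute `"diagnostics"`.
#' @export
estimate_power_ratio <- function(chi2_boosted, chi2_linear, significant_mask,
                                 type = c("mean_of_ratios", "ratio_of_means")) {
  type <- match.arg(type)
  stopifnot(length(chi2_boosted) == length(chi2_linear),
            length(significant_mask) == length(chi2_linear))
  b <- chi2_boosted[significant_mask]
  l <- chi2_linear[significant_mask]
  if (length(b) == 0) stop("significant_mask selects no variants")
  diag <- c(mean_of_ratios = mean(b / l), ratio_of_means = mean(b) / mean(l))
  structure(unname(diag[[type]]), diagnostics = diag)
}

#' Global effective sample size from a percentile of imputed values
#'
#' Summarizes per-variant imputed (effective) sample sizes by a percentile
#' of their distribution (default the 80th), tracking the upper plateau of
#' well-covered variants rather than the mean.  Percentiles use linear
#' interpolation between order statistics ([quantile()] type 7).
#'
#' @param imputed_neff vector of unclamped imputed effective sample sizes.
#' @param percentile fraction in (0, 1); default 0.8.
#' @param reported optional case/control-based effective size; when given,
#'   the ratio percentile/reported is attached as attribute `"ratio"`.
#' @return Scalar percentile value.
#' @export
global_neff_percentile <- function(imputed_neff, percentile = 0.8,
                                   reported = NULL) {
  if (length(imputed_neff) == 0) stop("empty input")
  val <- unname(quantile(imputed_neff, percentile, na.rm = TRUE, type = 7))
  if (!is.null(reported)) attr(val, "ratio") <- val / reported
  val
}

#' Recompute INFO scores from dosages
#'
#' MACH-style imputation quality: `INFO_j = var(D_j) / (2 f_j (1 - f_j))`
#' with `f_j = mean(D_j) / 2`, clipped to (0, 1].  Monomorphic columns are
#' flagged and yield `NA` rather than 0.  INFO should always be recomputed
#' on the homogeneous subset of individuals actually analysed.
#'
#' @param dosages a dosage matrix (individuals x variants) or a
#'   [simulate_dosages()] panel.
#' @return Numeric INFO vector with attribute `"monomorphic"` (logical).
#' @export
recompute_info <- function(dosages) {
  D <- if (is.matrix(dosages)) dosages else dosages$D
  if (nrow(D) < 2) stop("need at least 2 individuals")
  f <- colMeans(D) / 2
  v <- matrixStats_colVars(D)
  mono <- v == 0 | f <= 0 | f >= 1
  info <- v / (2 * f * (1 - f))
  info <- pmin(info, 1)
  info[mono] <- NA_real_
  attr(info, "monomorphic") <- mono
  info
}

# column variances without a hard dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}
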