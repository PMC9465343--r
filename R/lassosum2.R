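#' Hyper-parameter grid for the elastic-net solver
#'
#' Builds the default lassosum2 grid: 30 lambda values log-spaced between
#' `lambda0` and `lambda0 / 100`, where `lambda0 = max_j |beta_hat_j|` is
#' the smallest L1 penalty at which no variable enters the model, crossed
#' with `delta` in \{0.001, 0.01, 0.1, 1\}.  Per-variant penalty factors
#' `q_j = max_k(n_k) / n_j` multiply both lambda and delta internally, so
#' variants with smaller GWAS sample sizes are penalized more; with equal
#' `n` the factors are identically 1.
#'
#' @param beta_hat scaled marginal effects (or a [scaled_effects()] object).
#' @param n per-variant GWAS sample sizes.
#' @param n_lambda,lambda_min_ratio lambda path length and lower end as a
#'   fraction of `lambda0`.
#' @param delta L2 penalties to try.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per sweep; default `1e-5 * lambda0`.
#' @param maxiter sweep cap per fit (default 500).
#' @param guard divergence guard on `max |beta|` (scaled effects are
#'   correlations, so 5 is far outside the valid region).
#' @return A list of class `"lassosum_grid"`.
#' @export
lassosum_grid <- function(beta_hat, n, n_lambda = 30, lambda_min_ratio = 0.01,
                          delta = c(0.001, 0.01, 0.1, 1), tol = NULL,
                          maxiter = 500, guard = 5) {
  if (inherits(beta_hat, "scaled_stats")) beta_hat <- beta_hat$beta_hat
  lambda0 <- max(abs(beta_hat), na.rm = TRUE)
  lambda <- exp(seq(log(lambda0), log(lambda0 * lambda_min_ratio),
                    length.out = n_lambda))
  if (any(delta <= 0)) stop("delta must be > 0")
  n <- rep_len(n, length(beta_hat))
  structure(list(lambda = lambda, delta = delta, lambda0 = lambda0,
                 q = max(n) / n,
                 tol = tol %||% 1e-5 * lambda0,
                 maxiter = maxiter, guard = guard),
            class = "lassosum_grid")
}

#' Fit the elastic-net summary-statistics model (lassosum2)
#'
#' Cyclic coordinate descent with soft-thresholding on the scaled-effect
#' parameterization: `beta_j <- soft(u_j, lambda q_j) / (1 + delta q_j)`
#' with `u_j = beta_hat_j - (R beta)_j + beta_j`.  The rotated residual
#' `R beta` is cached and updated incrementally, touching only the stored
#' LD neighbors of a coordinate that changed; warm starts run along
#' decreasing lambda within each delta.  At `lambda >= lambda0` the
#' solution is exactly zero.  Fits whose coefficients exceed the divergence
#' guard are flagged, not raised.
#'
#' @param beta_hat scaled effects (vector or [scaled_effects()] object),
#'   all finite with `|beta_hat| < 1`.
#' @param ld an [build_ld()] matrix aligned with `beta_hat`.
#' @param n per-variant GWAS sample sizes (drives the penalty factors).
#' @param grid a [lassosum_grid()]; built with defaults when `NULL`.
#' @param debug recompute the cached residual after every sweep and record
#'   the maximum deviation (slow; for validation).
#' @return A list of class `"lassosum_path"`: `beta` (variants x fits),
#'   `grid` (data.frame with `lambda`, `delta` per fit), `iters`,
#'   `converged`, `divergent`, `lambda0`, `debug_max_err`.
#' @export
fit_lassosum2 <- function(beta_hat, ld, n, grid = NULL, debug = FALSE) {
  if (inherits(beta_hat, "scaled_stats")) beta_hat <- beta_hat$beta_hat
  m <- length(beta_hat)
  if (nrow(ld$R) != m) stop("beta_hat and ld dimensions differ")
  if (any(!is.finite(beta_hat))) stop("NaN/NA in beta_hat")
  if (any(abs(beta_hat) >= 1))
    stop("scaled effects must satisfy |beta_hat| < 1")
  if (is.null(grid)) grid <- lassosum_grid(beta_hat, n)

  R <- methods::as(ld$R, "CsparseMatrix")
  res <- lassosum_cd_cpp(R@p, R@i, R@x, beta_hat, grid$lambda, grid$delta,
                         grid$q, grid$tol, as.integer(grid$maxiter),
                         grid$guard, debug)
  gr <- expand.grid(lambda = grid$lambda, delta = grid$delta,
                    KEEP.OUT.ATTRS = FALSE)
  structure(list(beta = res$beta, grid = gr, iters = res$iters,
                 converged = res$converged == 1,
                 divergent = res$divergent == 1,
                 lambda0 = grid$lambda0,
                 debug_max_err = res$debug_max_err),
            class = "lassosum_path")
}

#' @export
print.lassosum_path <- function(x, ...) {
  cat(sprintf("<lassosum_path> %d fits (%d lambda x %d delta), %d diverged\n",
              nrow(x$grid), length(unique(x$grid$lambda)),
              length(unique(x$grid$delta)), sum(x$divergent)))
  invisible(x)
}

#' Select the best fit on a validation score
#'
#' Returns the grid point maximizing the validation score; ties are broken
#' toward more regularization (larger lambda, then larger delta).  Diverged
#' fits are excluded; if every fit diverged this is an error.
#'
#' @param path a [fit_lassosum2()] path.
#' @param scores one validation score per fit (higher is better).
#' @return A list with `lambda`, `delta`, `beta`, `score`, `index`.
#' @export
pick_best <- function(path, scores) {
  stopifnot(length(scores) == nrow(path$grid))
  ok <- !path$divergent & !is.na(scores)
  if (!any(ok)) stop("all fits diverged (or have missing scores)")
  ord <- order(-scores, -path$grid$lambda, -path$grid$delta)
  best <- ord[ok[ord]][1]
  list(lambda = path$grid$lambda[best], delta = path$grid$delta[best],
       beta = path$beta[, best], score = scores[best], index = best)
}

#' Serialize a fitted path
#'
#' Writes one TSV of per-variant per-allele effects with one column per
#' grid point (converted via [per_allele_effects()]), plus a JSON manifest
#' of the grid (lambda, delta, iterations, convergence and divergence
#' flags, lambda0).
#'
#' @param path a [fit_lassosum2()] result.
#' @param stats the [sumstats] table the scaled effects came from.
#' @param prefix output prefix (`.effects.tsv` and `.grid.json` appended).
#' @param sd_y phenotype sd used for the conversion.
#' @return `prefix`, invisibly.
#' @export
write_lassosum_path <- function(path, stats, prefix, sd_y = NULL) {
  eff <- per_allele_effects(path$beta, stats, sd_y = sd_y)
  colnames(eff) <- sprintf("fit%03d", seq_len(ncol(eff)))
  out <- cbind(data.frame(chr = stats$chr, pos = stats$pos,
                          a0 = stats$a0, a1 = stats$a1), eff)
  write.table(out, paste0(prefix, ".effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- cbind(path$grid,
                    data.frame(iters = path$iters,
                               converged = path$converged,
                               divergent = path$divergent))
  jsonlite::write_json(list(lambda0 = path$lambda0, fits = manifest),
                       paste0(prefix, ".grid.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
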