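#' LD-score-regression heritability estimate
#'
#' Weighted least squares of `chi2_j = Z_j^2` on `x_j = l_j n_j / M` with an
#' intercept; on this scaled parameterization the slope is the SNP
#' heritability.  Two-step weighting: a provisional slope `b` from an
#' initial `1/l`-weighted fit, then weights `1 / (2 (1 + x_j b)^2 l_j)`
#' (heteroskedasticity x LD-induced correlation), refit twice.  Standard
#' errors come from a delete-one block jackknife over contiguous variant
#' blocks.
#'
#' @param z per-variant Z scores.
#' @param ld_scores LD scores from [ld_scores()] (must be positive).
#' @param n per-variant sample sizes (scalar or vector).
#' @param M number of variants the heritability refers to; default
#'   `length(z)`.
#' @param n_blocks jackknife block count (default 200, capped at `M/2`).
#' @return A list of class `"ldsc_fit"`: `h2` (slope), `h2_se`,
#'   `intercept`, `intercept_se`.
#' @export
ldsc_h2 <- function(z, ld_scores, n, M = NULL, n_blocks = 200) {
  if (any(ld_scores <= 0)) stop("ld_scores must be positive")
  m <- length(z)
  if (m < 2) stop("need at least 2 variants")
  if (is.null(M)) M <- m
  n <- rep_len(n, m)
  chi2 <- z^2
  x <- ld_scores * n / M

  wls <- function(w, keep = TRUE) {
    fit <- lm(chi2[keep] ~ x[keep], weights = w[keep])
    coef(fit)
  }
  b <- wls(1 / ld_scores)[2]
  for (it in 1:2) {
    w <- 1 / (2 * (1 + pmax(x * b, 0))^2 * ld_scores)
    cf <- wls(w)
    b <- cf[2]
  }

  n_blocks <- max(2, min(n_blocks, floor(m / 2)))
  grp <- ceiling(seq_len(m) / (m / n_blocks))
  jack <- vapply(seq_len(n_blocks), function(k) {
    keep <- grp != k
    wls(w, keep)
  }, numeric(2))
  jse <- sqrt((n_blocks - 1) * apply(jack, 1, var))

  structure(list(h2 = unname(b), h2_se = jse[2],
                 intercept = unname(cf[1]), intercept_se = jse[1]),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> h2 = %.4f (se %.4f), intercept = %.3f (se %.3f)\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Infinitesimal model (closed form)
#'
#' Posterior-mean effects under the infinitesimal prior:
#' `beta = (R + M/(n h2) I)^{-1} beta_hat`, solved independently per LD
#' block (the whole matrix counts as one block when none are assigned).
#' Deterministic; the ridge term makes the system non-singular.
#'
#' @param beta_hat scaled effects (vector or [scaled_effects()] object).
#' @param ld an [build_ld()] matrix.
#' @param n GWAS sample size (scalar or per-variant).
#' @param h2 heritability parameter (> 0).
#' @return Numeric vector of posterior-mean scaled effects.
#' @export
fit_inf <- function(beta_hat, ld, n, h2) {
  if (inherits(beta_hat, "scaled_stats")) beta_hat <- beta_hat$beta_hat
  if (h2 <= 0) stop("h2 must be > 0")
  m <- length(beta_hat)
  n <- rep_len(n, m)
  blocks <- ld$blocks %||% rep(1L, m)
  out <- numeric(m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    A <- ld$R[idx, idx, drop = FALSE] + Matrix::Diagonal(x = m / (n[idx] * h2))
    out[idx] <- as.numeric(Matrix::solve(A, beta_hat[idx]))
  }
  out
}

#' Gibbs-sampler configuration
#'
#' Tunables of the spike-and-slab sampler.  `shrink_corr` multiplies the
#' off-diagonal LD entries inside the sampler only (a regularization; the
#' heritability update keeps the unshrunk LD); `allow_jump_sign = FALSE`
#' forces effects to pass through zero before changing sign across sweeps,
#' preventing oscillation under misspecification.  The robust presets used
#' by `gibbs_config_rob()` are `shrink_corr = 0.9` (simulation context) or
#' `0.95` (real data) with `allow_jump_sign = FALSE`.
#'
#' @param p proportion of causal variants (fixed in grid mode).
#' @param h2 heritability (fixed in grid mode; initial value in auto mode).
#' @param shrink_corr off-diagonal shrink factor in \[0, 1\].
#' @param allow_jump_sign may an effect flip sign between sweeps?
#' @param burn_in,num_iter discarded and kept sweeps (defaults 100/400).
#' @param chains auto-mode chain count (default 10), initial `p` values
#'   log-spaced in `[1e-4, 0.2]` unless `init_p` is given.
#' @param init_p optional initial `p` per chain (auto mode).
#' @param h2_div,p_pin_thr,p_pin_sweeps divergence heuristics: flag when
#'   the `h2` trace exceeds `h2_div`, or when the causal fraction stays
#'   above `p_pin_thr` for more than `p_pin_sweeps` consecutive sweeps.
#' @param keep_samples keep the full per-sweep effect samples (small
#'   systems only).
#' @return A list of class `"gibbs_config"`.
#' @export
gibbs_config <- function(p = 0.01, h2 = 0.2, shrink_corr = 1,
                         allow_jump_sign = TRUE, burn_in = 100,
                         num_iter = 400, chains = 10, init_p = NULL,
                         h2_div = 1.5, p_pin_thr = 0.95, p_pin_sweeps = 50,
                         keep_samples = FALSE) {
  stopifnot(p > 0, p <= 1, h2 > 0, shrink_corr >= 0, shrink_corr <= 1)
  structure(list(p = p, h2 = h2, shrink_corr = shrink_corr,
                 allow_jump_sign = allow_jump_sign, burn_in = burn_in,
                 num_iter = num_iter, chains = chains,
                 init_p = init_p %||% exp(seq(log(1e-4), log(0.2),
                                              length.out = chains)),
                 h2_div = h2_div, p_pin_thr = p_pin_thr,
                 p_pin_sweeps = p_pin_sweeps, keep_samples = keep_samples),
            class = "gibbs_config")
}

#' @rdname gibbs_config
#' @param context robust preset flavor: `shrink_corr = 0.9` for simulated
#'   data, `0.95` for real data; both disable sign jumps.
#' @param ... passed on to [gibbs_config()].
#' @export
gibbs_config_rob <- function(context = c("simulation", "real"), ...) {
  context <- match.arg(context)
  gibbs_config(shrink_corr = if (context == "simulation") 0.9 else 0.95,
               allow_jump_sign = FALSE, ...)
}

#' Fit the spike-and-slab model by Gibbs sampling
#'
#' Scaled-effect spike-and-slab sampler (see [gibbs_config()] for the
#' model).  In `"grid"` mode `(p, h2)` stay fixed and one chain runs.  In
#' `"auto"` mode both parameters are estimated from the data: after each
#' sweep the causal count updates `p ~ Beta(1 + M_c, 1 + M - M_c)` and
#' `h2 <- beta' R beta` (unshrunk `R`); several chains with different
#' initial `p` run and non-divergent chains are averaged.  If every chain
#' is flagged divergent the averaged result is still returned, flagged.
#'
#' @param beta_hat scaled effects (vector or [scaled_effects()] object).
#' @param ld an [build_ld()] matrix.
#' @param n per-variant sample sizes.
#' @param config a [gibbs_config()].
#' @param mode `"grid"` or `"auto"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"gibbs_result"`: `beta` (posterior mean),
#'   `p_est`, `h2_est`, `chains` (per-chain traces and flags),
#'   `divergent` (per chain), `all_divergent`, `mode`.
#' @export
gibbs_fit <- function(beta_hat, ld, n, config = gibbs_config(),
                      mode = c("grid", "auto"), seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(beta_hat, "scaled_stats")) beta_hat <- beta_hat$beta_hat
  if (any(!is.finite(beta_hat))) stop("NaN/NA in beta_hat")
  m <- length(beta_hat)
  if (nrow(ld$R) != m) stop("beta_hat and ld dimensions differ")
  n <- rep_len(n, m)
  if (!is.null(seed)) set.seed(seed)
  R <- methods::as(ld$R, "CsparseMatrix")

  init_p <- if (mode == "auto") config$init_p else config$p
  chains <- vector("list", length(init_p))
  for (k in seq_along(init_p)) {
    res <- gibbs_sampler_cpp(R@p, R@i, R@x, beta_hat, n,
                             as.integer(config$burn_in),
                             as.integer(config$num_iter),
                             init_p[k], config$h2, mode == "auto",
                             config$shrink_corr, config$allow_jump_sign,
                             config$keep_samples, config$h2_div,
                             config$p_pin_thr,
                             as.integer(config$p_pin_sweeps))
    sw <- res$sweeps_done
    res$p_trace <- res$p_trace[seq_len(sw)]
    res$h2_trace <- res$h2_trace[seq_len(sw)]
    res$mc_trace <- res$mc_trace[seq_len(sw)]
    chains[[k]] <- res
  }

  div <- vapply(chains, function(ch) isTRUE(ch$divergent), logical(1))
  usable <- vapply(chains, function(ch) ch$n_kept > 0, logical(1))
  keep <- usable & !div
  all_div <- !any(keep)
  if (all_div) keep <- usable
  if (!any(keep)) keep <- rep(TRUE, length(chains))  # degenerate: all aborted

  beta <- rowMeans(vapply(chains[keep], function(ch) ch$postmean,
                          numeric(m)))
  kept_mean <- function(field) {
    mean(vapply(chains[keep], function(ch) {
      tr <- ch[[field]]
      nk <- min(ch$n_kept, length(tr))
      if (nk > 0) mean(tr[(length(tr) - nk + 1):length(tr)]) else NA_real_
    }, numeric(1)), na.rm = TRUE)
  }
  structure(list(beta = beta, p_est = kept_mean("p_trace"),
                 h2_est = kept_mean("h2_trace"), chains = chains,
                 divergent = div, all_divergent = all_div,
                 mode = mode, config = config),
            class = "gibbs_result")
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("<gibbs_result> mode %s, %d chain(s) (%d divergent), p = %.3g, h2 = %.3g\n",
              x$mode, length(x$chains), sum(x$divergent), x$p_est, x$h2_est))
  invisible(x)
}

#' Heritability grids anchored on the LDSC estimate
#'
#' `"real"` mode multiplies the LDSC heritability by \{0.3, 0.7, 1, 1.4\};
#' `"simulation"` mode (for strong misspecifications) uses the larger grid
#' \{0.01, 0.1, 0.3, 0.7, 1, 1.4\}.  The added low multipliers give the
#' sampler room for extra shrinkage when inputs are misspecified.
#'
#' @param h2_ldsc positive heritability estimate (e.g. from [ldsc_h2()]).
#' @param mode grid flavor.
#' @return Numeric vector of h2 values.
#' @export
build_h2_grid <- function(h2_ldsc, mode = c("real", "simulation")) {
  mode <- match.arg(mode)
  if (h2_ldsc <= 0) stop("h2_ldsc must be > 0")
  mult <- if (mode == "real") c(0.3, 0.7, 1, 1.4)
          else c(0.01, 0.1, 0.3, 0.7, 1, 1.4)
  mult * h2_ldsc
}

#' Default proportion-causal grid
#'
#' 21 values log-spaced in `[1e-5, 1]` (configuration, not model).
#'
#' @param length grid length.
#' @return Numeric vector.
#' @export
default_p_grid <- function(length = 21) {
  signif(exp(seq(log(1e-5), log(1), length.out = length)), 4)
}

#' Grid search over (p, h2) with validation tuning
#'
#' Runs [gibbs_fit()] in grid mode over the Cartesian product of `p_grid`
#' and `h2_grid`, scores every fit with `scorer`, and returns the argmax;
#' ties break toward more regularization (smaller h2, then smaller p).
#' Divergent fits are excluded; all-divergent is an error.
#'
#' @param beta_hat,ld,n as in [gibbs_fit()].
#' @param p_grid,h2_grid hyper-parameter grids.
#' @param scorer `function(beta_scaled) -> scalar` validation score.
#' @param config base [gibbs_config()] (its `p`/`h2` are overridden).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list: `p`, `h2`, `beta`, `score`, and the full `table`
#'   (data.frame with p, h2, score, divergent) plus `beta_all`.
#' @export
grid_search <- function(beta_hat, ld, n, p_grid, h2_grid, scorer,
                        config = gibbs_config(), seed = NULL) {
  if (!length(p_grid) || !length(h2_grid)) stop("grids must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(beta_hat, "scaled_stats")) beta_hat <- beta_hat$beta_hat
  tab <- expand.grid(p = p_grid, h2 = h2_grid, KEEP.OUT.ATTRS = FALSE)
  B <- matrix(NA_real_, length(beta_hat), nrow(tab))
  score <- rep(NA_real_, nrow(tab))
  divergent <- rep(FALSE, nrow(tab))
  for (k in seq_len(nrow(tab))) {
    cfg <- config
    cfg$p <- tab$p[k]; cfg$h2 <- tab$h2[k]
    fit <- gibbs_fit(beta_hat, ld, n, cfg, mode = "grid")
    B[, k] <- fit$beta
    divergent[k] <- fit$all_divergent || any(fit$divergent)
    if (!divergent[k]) score[k] <- scorer(fit$beta)
  }
  tab$score <- score; tab$divergent <- divergent
  ok <- !divergent & !is.na(score)
  if (!any(ok)) stop("all grid fits diverged")
  ord <- order(-ifelse(ok, score, -Inf), tab$h2, tab$p)
  best <- ord[1]
  list(p = tab$p[best], h2 = tab$h2[best], beta = B[, best],
       score = score[best], table = tab, beta_all = B, index = best)
}
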