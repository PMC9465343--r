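#' Benchmark configuration
#'
#' Problem sizes and sampler settings for [run_benchmark()].  The defaults
#' are the package's desk scale -- 2,500 variants, 10,000 training / 2,000
#' validation / 3,000 test individuals per scenario seed -- chosen so a
#' full multi-seed benchmark runs in minutes on one core while preserving
#' the directional behavior of the methods.  Grid-mode sweeps and the
#' solver tolerance are looser than the per-fit defaults because the
#' benchmark averages over many grid points and seeds.
#'
#' @param scenario_params overrides for [build_scenario()].
#' @param window_cm LD window.
#' @param p_grid proportion-causal grid for the tuned sampler.
#' @param grid_burn,grid_iter sweeps for grid-mode fits.
#' @param auto_chains,auto_burn,auto_iter auto-mode chain count and sweeps.
#' @param split_max_block,split_max_r2 block-splitting settings.
#' @param lassosum_tol_factor,lassosum_maxiter coordinate-descent stopping
#'   rule used inside the benchmark (tolerance as a fraction of lambda0).
#' @param n_boot bootstrap replicates for the CI of the mean.
#' @return A list of class `"bench_config"`.
#' @export
bench_config <- function(scenario_params = list(), window_cm = 3,
                         p_grid = c(1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03,
                                    0.1, 0.3, 1),
                         grid_burn = 40, grid_iter = 100,
                         auto_chains = 5, auto_burn = 60, auto_iter = 180,
                         split_max_block = 500, split_max_r2 = 0.3,
                         split_n_blocks = c(5, 15), split_weight = 0.002,
                         lassosum_tol_factor = 1e-4, lassosum_maxiter = 150,
                         n_boot = 1000) {
  structure(list(scenario_params = scenario_params, window_cm = window_cm,
                 p_grid = p_grid, grid_burn = grid_burn,
                 grid_iter = grid_iter, auto_chains = auto_chains,
                 auto_burn = auto_burn, auto_iter = auto_iter,
                 split_max_block = split_max_block,
                 split_max_r2 = split_max_r2, split_n_blocks = split_n_blocks,
                 split_weight = split_weight,
                 lassosum_tol_factor = lassosum_tol_factor,
                 lassosum_maxiter = lassosum_maxiter, n_boot = n_boot),
            class = "bench_config")
}

#' Define a benchmark method cell
#'
#' One cell of the benchmark design: a PGS method plus its sample-size
#' treatment (`"true"` per-variant n, `"max"` a single maximum value,
#' `"imputed"` from the sd identity), LD treatment (`"full"` windowed
#' matrix or `"blocks"` after independent-block splitting), LD source
#' (`"matched"` validation panel or `"mismatched"` drifted panel, where the
#' scenario provides one), and an optional INFO correction applied to the
#' summary statistics first.
#'
#' @param method one of `"lassosum2"`, `"ldpred2-inf"`, `"ldpred2-grid"`,
#'   `"ldpred2-low-h2"`, `"ldpred2-auto"`, `"ldpred2-auto-rob"`.
#' @param n_treatment,ld_treatment,ld_source,correction see above.
#' @param label optional display label.
#' @return A list of class `"bench_method"`.
#' @export
bench_method <- function(method = c("lassosum2", "ldpred2-inf",
                                    "ldpred2-grid", "ldpred2-low-h2",
                                    "ldpred2-auto", "ldpred2-auto-rob"),
                         n_treatment = c("true", "max", "imputed"),
                         ld_treatment = c("full", "blocks"),
                         ld_source = c("matched", "mismatched"),
                         correction = NULL, label = NULL) {
  method <- match.arg(method)
  n_treatment <- match.arg(n_treatment)
  ld_treatment <- match.arg(ld_treatment)
  ld_source <- match.arg(ld_source)
  structure(list(method = method, n_treatment = n_treatment,
                 ld_treatment = ld_treatment, ld_source = ld_source,
                 correction = correction,
                 label = label %||% paste(method, n_treatment, ld_treatment,
                                          ld_source,
                                          correction %||% "none",
                                          sep = "|")),
            class = "bench_method")
}

#' Run a multi-seed benchmark
#'
#' Per seed: simulate the scenario, run the GWAS, fit every requested
#' method (tuning on the validation individuals where the method tunes),
#' and score the squared correlation between the polygenic score and the
#' phenotype on the held-out test individuals.  Train/validation/test
#' partitions are disjoint by construction and tuning never sees test
#' data.  Expensive intermediates (LD matrices, block splits, scaled
#' effects, shared grid fits) are cached within a seed.  Method divergence
#' is recorded, not raised.
#'
#' @param scenario scenario name for [build_scenario()], or a
#'   `function(seed)` returning a `"sim_scenario"`.
#' @param methods list of [bench_method()] cells.
#' @param n_seeds number of independent simulation seeds.
#' @param config a [bench_config()].
#' @param base_seed seeds used are `base_seed + (0:(n_seeds-1))`.
#' @return A list of class `"bench_result"`: `results` (one row per seed x
#'   method: label, seed, r2, divergent) and `summary` (per method: mean
#'   r2 and bootstrap CI of the mean over seeds).
#' @export
run_benchmark <- function(scenario, methods, n_seeds = 10,
                          config = bench_config(), base_seed = 1) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s - 1
    sc <- if (is.function(scenario)) scenario(seed)
          else build_scenario(scenario, config$scenario_params, seed)
    res <- bench_one_seed(sc, methods, config)
    res$seed <- seed
    rows[[s]] <- res
    rm(sc); gc(FALSE)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = summarize_benchmark(results, config$n_boot)),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat("<bench_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summarize per-seed benchmark results
#'
#' Mean test r2 per method with a non-parametric bootstrap CI of the mean
#' (95%, `n_boot` replicates of resampled per-seed means).
#'
#' @param results the `results` data.frame of [run_benchmark()].
#' @param n_boot bootstrap replicates (>= 1000 recommended).
#' @return A data.frame: label, n_seeds, mean_r2, ci_lo, ci_hi.
#' @export
summarize_benchmark <- function(results, n_boot = 1000) {
  out <- lapply(split(results, results$label), function(d) {
    ci <- bootstrap_ci_mean(d$r2, n_boot)
    data.frame(label = d$label[1], n_seeds = nrow(d),
               mean_r2 = mean(d$r2), ci_lo = ci[1], ci_hi = ci[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname summarize_benchmark
#' @param x numeric vector of per-seed values.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 1000) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  reps <- vapply(seq_len(n_boot),
                 function(i) mean(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  unname(quantile(reps, c(0.025, 0.975), type = 7))
}

# ---- one-seed pipeline ------------------------------------------------------

bench_one_seed <- function(sc, methods, config) {
  stopifnot(!any(sc$train %in% sc$valid), !any(sc$train %in% sc$test),
            !any(sc$valid %in% sc$test))
  Xv <- sc$panel$G[sc$valid, , drop = FALSE]
  Xt <- sc$panel$G[sc$test, , drop = FALSE]
  yv <- sc$pheno$y[sc$valid]
  yt <- sc$pheno$y[sc$test]
  cache <- new.env(parent = emptyenv())

  get_ld <- function(source, treatment) {
    key <- paste0("ld_", source, "_", treatment)
    if (!is.null(cache[[key]])) return(cache[[key]])
    base_key <- paste0("ld_", source, "_full")
    if (is.null(cache[[base_key]])) {
      panel <- if (source == "mismatched") {
        if (is.null(sc$ld_panel)) stop("scenario has no mismatched LD panel")
        sc$ld_panel
      } else subset_panel(sc$panel, sc$valid)
      cache[[base_key]] <- build_ld(panel, window_cm = config$window_cm)
    }
    ld <- cache[[base_key]]
    if (treatment == "blocks") {
      split <- split_blocks(ld, max_block_size = config$split_max_block,
                            n_blocks_range = config$split_n_blocks,
                            max_r2 = config$split_max_r2,
                            weight = config$split_weight)
      if (!split$feasible)
        split <- split_blocks(ld, max_block_size = config$split_max_block,
                              n_blocks_range = config$split_n_blocks,
                              weight = config$split_weight)
      ld <- apply_blocks(ld, split)
      cache[[key]] <- ld
    }
    ld
  }

  get_stats <- function(mt) {
    key <- paste0("st_", mt$n_treatment, "_", mt$correction %||% "none")
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- sc$stats
    if (!is.null(mt$correction))
      st <- apply_info_correction(st, mt$correction)
    ok <- is.finite(st$beta) & is.finite(st$beta_se) & st$beta_se > 0
    if (any(!ok)) {  # flagged variants: neutralize rather than drop
      st$beta[!ok] <- 0
      st$beta_se[!ok] <- 1
    }
    if (mt$n_treatment == "max") {
      st$n <- rep(max(st$n), nrow(st))
    } else if (mt$n_treatment == "imputed") {
      imp <- impute_n(st)
      st$n <- ifelse(is.na(imp$n_imp), st$n, imp$n_imp)
    }
    sdy <- sqrt(estimate_var_y(st, N = max(st$n)))
    scl <- scaled_effects(st, sd_y = sdy)
    scl$beta_hat[!ok] <- 0
    scl$beta_hat[!is.finite(scl$beta_hat)] <- 0
    scl$beta_hat <- pmin(pmax(scl$beta_hat, -0.999), 0.999)
    val <- list(stats = st, scaled = scl)
    cache[[key]] <- val
    val
  }

  get_ldsc <- function(mt, ld) {
    key <- paste0("ldsc_", mt$n_treatment, "_", mt$correction %||% "none",
                  "_", mt$ld_source)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ss <- get_stats(mt)
    z <- ss$scaled$z
    z[!is.finite(z)] <- 0
    fit <- ldsc_h2(z, ld_scores(ld), ss$stats$n)
    h2 <- min(max(fit$h2, 0.001), 1)
    cache[[key]] <- h2
    h2
  }

  # grid-mode fits over the union h2 grid, shared by grid and low-h2
  get_grid_fits <- function(mt, ld) {
    key <- paste0("grid_", mt$n_treatment, "_", mt$correction %||% "none",
                  "_", mt$ld_treatment, "_", mt$ld_source)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ss <- get_stats(mt)
    h2l <- get_ldsc(mt, ld)
    h2_union <- build_h2_grid(h2l, "simulation")
    conv <- ss$scaled$sd_y / ss$scaled$sd_ss
    scorer <- make_scorer(Xv, yv, conv)
    cfg <- gibbs_config(burn_in = config$grid_burn,
                        num_iter = config$grid_iter)
    gs <- grid_search(ss$scaled$beta_hat, ld, ss$stats$n,
                      p_grid = config$p_grid, h2_grid = h2_union,
                      scorer = scorer, config = cfg)
    val <- list(gs = gs, h2_ldsc = h2l, conv = conv)
    cache[[key]] <- val
    val
  }

  out <- lapply(methods, function(mt) {
    ld <- get_ld(mt$ld_source, mt$ld_treatment)
    ss <- get_stats(mt)
    conv <- ss$scaled$sd_y / ss$scaled$sd_ss
    divergent <- FALSE

    beta_scaled <- switch(
      mt$method,
      "lassosum2" = {
        lg <- lassosum_grid(ss$scaled$beta_hat, ss$stats$n,
                            maxiter = config$lassosum_maxiter)
        lg$tol <- config$lassosum_tol_factor * lg$lambda0
        path <- fit_lassosum2(ss$scaled$beta_hat, ld, ss$stats$n, grid = lg)
        scores <- apply(path$beta, 2, make_scorer(Xv, yv, conv))
        scores[path$divergent] <- NA
        divergent <- all(path$divergent)
        pick_best(path, scores)$beta
      },
      "ldpred2-inf" = {
        h2l <- get_ldsc(mt, ld)
        fit_inf(ss$scaled$beta_hat, ld, ss$stats$n, h2l)
      },
      "ldpred2-grid" = ,
      "ldpred2-low-h2" = {
        gf <- get_grid_fits(mt, ld)
        tab <- gf$gs$table
        h2_keep <- if (mt$method == "ldpred2-grid") {
          build_h2_grid(gf$h2_ldsc, "real")
        } else unique(tab$h2)
        ok <- tab$h2 %in% h2_keep & !tab$divergent & !is.na(tab$score)
        divergent <- !any(ok)
        if (divergent) rep(0, ncol(Xv)) else {
          ord <- order(-ifelse(ok, tab$score, -Inf), tab$h2, tab$p)
          gf$gs$beta_all[, ord[1]]
        }
      },
      "ldpred2-auto" = ,
      "ldpred2-auto-rob" = {
        h2l <- get_ldsc(mt, ld)
        cfg <- if (mt$method == "ldpred2-auto-rob") {
          gibbs_config_rob("simulation", h2 = h2l,
                           burn_in = config$auto_burn,
                           num_iter = config$auto_iter,
                           chains = config$auto_chains)
        } else {
          gibbs_config(h2 = h2l, burn_in = config$auto_burn,
                       num_iter = config$auto_iter,
                       chains = config$auto_chains)
        }
        fit <- gibbs_fit(ss$scaled$beta_hat, ld, ss$stats$n, cfg,
                         mode = "auto")
        divergent <- fit$all_divergent
        fit$beta
      })

    r2 <- score_r2(Xt, yt, beta_scaled * conv)
    data.frame(label = mt$label, r2 = r2, divergent = divergent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

make_scorer <- function(X, y, conv) {
  function(beta_scaled) score_r2(X, y, beta_scaled * conv)
}

score_r2 <- function(X, y, effects) {
  prs <- as.numeric(X %*% effects)
  if (sd(prs) == 0) return(0)
  cor(prs, y)^2
}
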