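ld3 <- function() {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  dense_ld(R)
}

test_that("LDSC regression recovers slope and intercept properties", {
  # null simulation: chi2 ~ 1, slope ~ 0, intercept ~ 1
  set.seed(90)
  m <- 2000
  l <- runif(m, 1, 10)
  z <- rnorm(m)
  fit0 <- ldsc_h2(z, l, n = 10000, M = m)
  expect_lt(abs(fit0$h2), 3 * fit0$h2_se + 0.01)
  expect_lt(abs(fit0$intercept - 1), 3 * fit0$intercept_se + 0.05)

  # doubling n with fixed Z halves the slope exactly (weights invariant)
  chi_sim <- 1 + 0.3 * l * rchisq(m, df = 1)
  z2 <- sqrt(chi_sim)
  f1 <- ldsc_h2(z2, l, n = 5000, M = m)
  f2 <- ldsc_h2(z2, l, n = 10000, M = m)
  expect_equal(f2$h2, f1$h2 / 2, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-10)

  expect_error(ldsc_h2(z, c(-1, l[-1]), 100), "positive")
})

test_that("LDSC recovers the simulated heritability", {
  sc <- build_scenario("sample-size",
                       list(n_train = 8000, n_valid = 2000, n_test = 100),
                       seed = 91)
  ld <- build_ld(robpgs:::subset_panel(sc$panel, sc$valid), window_cm = 3)
  scl <- scaled_effects(sc$stats)
  fit <- ldsc_h2(scl$z, ld_scores(ld), sc$stats$n)
  expect_lt(abs(fit$h2 - 0.2), 0.05)
})

test_that("infinitesimal closed form matches hand solves and limits", {
  # diagonal case
  bh <- c(0.1, -0.05, 0.02)
  out <- fit_inf(bh, dense_ld(diag(3)), n = 1000, h2 = 0.1)
  expect_equal(out, bh / (1 + 3 / (1000 * 0.1)))

  # 3-variant hand solve
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  expect_equal(fit_inf(bh, ld3(), 1000, 0.1),
               as.numeric(solve(R + (3 / 100) * diag(3), bh)))

  # limits: strong data -> joint effects; weak data -> zero
  strong <- fit_inf(bh, ld3(), 1e9, 0.5)
  expect_equal(strong, as.numeric(solve(R, bh)), tolerance = 1e-5)
  weak <- fit_inf(bh, ld3(), 1, 1e-6)
  expect_lt(max(abs(weak)), 1e-5)

  # blocks solve independently
  R4 <- diag(4); R4[1, 2] <- R4[2, 1] <- 0.7; R4[3, 4] <- R4[4, 3] <- 0.3
  ldb <- dense_ld(R4); ldb$blocks <- c(1, 1, 2, 2)
  bh4 <- c(0.1, 0, -0.1, 0.05)
  expect_equal(fit_inf(bh4, ldb, 500, 0.2),
               as.numeric(solve(R4 + (4 / 100) * diag(4), bh4)))

  expect_error(fit_inf(bh, ld3(), 1000, 0), "h2")
})

test_that("Gibbs sampler returns null posterior on null data", {
  set.seed(92)
  bh <- rep(0, 50)
  ld <- dense_ld(diag(50))
  fit <- gibbs_fit(bh, ld, 1000, gibbs_config(chains = 3, burn_in = 50,
                                              num_iter = 200),
                   mode = "auto", seed = 1)
  expect_lt(max(abs(fit$beta)), 0.005)
  expect_lt(fit$p_est, 0.05)
  expect_lt(fit$h2_est, 0.01)
})

test_that("grid mode with p = 1 converges to the infinitesimal closed form", {
  bh <- c(0.02, 0.01, -0.01)
  cfg <- gibbs_config(p = 1 - 1e-12, h2 = 0.1, burn_in = 500,
                      num_iter = 20000)
  fit <- gibbs_fit(bh, ld3(), 1000, cfg, mode = "grid", seed = 2)
  expect_equal(fit$beta, fit_inf(bh, ld3(), 1000, 0.1), tolerance = 0.01)
})

test_that("stationary distribution matches the analytic 2-variant posterior", {
  bh <- c(0.3, 0.1); r <- 0.4; n <- 50; p <- 0.3; s2 <- 0.05
  R <- matrix(c(1, r, r, 1), 2)
  cfg <- gibbs_config(p = p, h2 = s2 * 2 * p, burn_in = 2000,
                      num_iter = 50000, keep_samples = TRUE)
  fit <- gibbs_fit(bh, dense_ld(R), n, cfg, mode = "grid", seed = 3)
  samples <- fit$chains[[1]]$samples[1, ]
  cdf <- posterior2_cdf(bh, r, n, p, s2)
  xs <- sort(c(seq(-0.3, 0.6, length.out = 400), -1e-12, 0))
  ks <- max(abs(vapply(xs, function(x) mean(samples <= x) - cdf(x),
                       numeric(1))))
  expect_lt(ks, 0.02)
})

test_that("sign jumps are forbidden when allow_jump_sign is off", {
  set.seed(93)
  p <- simulate_genotypes(800, 40, c(0.1, 0.5), 1, 6, spacing_cm = 0.05)
  ph <- simulate_phenotype(p, 0.5, 10)
  ss <- run_gwas_linear(p, ph$y)
  sc <- scaled_effects(ss, sd_y = sd(ph$y))
  ld <- build_ld(p, window_cm = 3)
  cfg <- gibbs_config(p = 0.3, h2 = 0.5, allow_jump_sign = FALSE,
                      burn_in = 0, num_iter = 300, keep_samples = TRUE)
  fit <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg, mode = "grid", seed = 4)
  S <- fit$chains[[1]]$samples
  prod_consec <- S[, -1] * S[, -ncol(S)]
  expect_true(all(prod_consec >= 0))

  # with jumps allowed, sign flips do occur on the same data
  cfg2 <- cfg; cfg2$allow_jump_sign <- TRUE
  fit2 <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg2, mode = "grid", seed = 4)
  S2 <- fit2$chains[[1]]$samples
  expect_gt(sum(S2[, -1] * S2[, -ncol(S2)] < 0), 0)
})

test_that("shrink_corr equals running the plain sampler on c R + (1-c) I", {
  set.seed(94)
  p <- simulate_genotypes(500, 25, c(0.1, 0.5), 1, 6, spacing_cm = 0.1)
  ph <- simulate_phenotype(p, 0.5, 5)
  ss <- run_gwas_linear(p, ph$y)
  sc <- scaled_effects(ss, sd_y = sd(ph$y))
  ld <- build_ld(p, window_cm = 3)
  cfg <- gibbs_config(p = 0.2, h2 = 0.3, shrink_corr = 0.9, burn_in = 10,
                      num_iter = 100, keep_samples = TRUE)
  f1 <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg, mode = "grid", seed = 5)
  cfg2 <- cfg; cfg2$shrink_corr <- 1
  f2 <- gibbs_fit(sc$beta_hat, shrink_offdiag(ld, 0.9), ss$n, cfg2,
                  mode = "grid", seed = 5)
  expect_equal(f1$chains[[1]]$samples, f2$chains[[1]]$samples,
               tolerance = 1e-12)
})

test_that("fixed seeds give identical traces; relabeling permutes the mean", {
  set.seed(95)
  p <- simulate_genotypes(500, 30, c(0.1, 0.5), 1, 6, spacing_cm = 0.1)
  ph <- simulate_phenotype(p, 0.5, 5)
  ss <- run_gwas_linear(p, ph$y)
  sc <- scaled_effects(ss, sd_y = sd(ph$y))
  ld <- build_ld(p, window_cm = 3)
  cfg <- gibbs_config(chains = 2, burn_in = 20, num_iter = 80)
  f1 <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg, mode = "auto", seed = 6)
  f2 <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg, mode = "auto", seed = 6)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$chains[[1]]$p_trace, f2$chains[[1]]$p_trace)
})

test_that("h2 grids use the published multiplier sets", {
  expect_equal(build_h2_grid(0.1, "real"), c(0.03, 0.07, 0.1, 0.14))
  g <- build_h2_grid(0.2, "simulation")
  expect_equal(g, c(0.002, 0.02, 0.06, 0.14, 0.2, 0.28))
  # multiplicative equivariance
  expect_equal(build_h2_grid(3 * 0.1, "real"), 3 * build_h2_grid(0.1, "real"))
  expect_error(build_h2_grid(0), "> 0")
  expect_equal(length(default_p_grid()), 21)
  expect_equal(range(default_p_grid()), c(1e-5, 1))
})

test_that("grid search scores the Cartesian grid with regularized ties", {
  set.seed(96)
  p <- simulate_genotypes(600, 30, c(0.1, 0.5), 1, 6, spacing_cm = 0.1)
  ph <- simulate_phenotype(p, 0.5, 5)
  ss <- run_gwas_linear(p, ph$y)
  sc <- scaled_effects(ss, sd_y = sd(ph$y))
  ld <- build_ld(p, window_cm = 3)
  cfg <- gibbs_config(burn_in = 20, num_iter = 60)

  # 1x1 grid is gibbs_fit
  set.seed(7)
  gs <- grid_search(sc$beta_hat, ld, ss$n, p_grid = 0.1, h2_grid = 0.3,
                    scorer = function(b) sum(b^2), config = cfg)
  cfg1 <- cfg; cfg1$p <- 0.1; cfg1$h2 <- 0.3
  set.seed(7)
  single <- gibbs_fit(sc$beta_hat, ld, ss$n, cfg1, mode = "grid")
  expect_equal(gs$beta, single$beta)

  # constant scorer: ties resolved toward smaller h2 then smaller p
  gs2 <- grid_search(sc$beta_hat, ld, ss$n, p_grid = c(0.01, 0.1),
                     h2_grid = c(0.1, 0.3), scorer = function(b) 0,
                     config = cfg, seed = 8)
  expect_equal(gs2$p, 0.01)
  expect_equal(gs2$h2, 0.1)

  expect_error(grid_search(sc$beta_hat, ld, ss$n, numeric(0), 0.1,
                           function(b) 0), "non-empty")
})

test_that("null-phenotype validation selects the most regularized model", {
  set.seed(97)
  p <- simulate_genotypes(900, 40, c(0.1, 0.5), 1, 6, spacing_cm = 0.1)
  ph <- simulate_phenotype(p, 0.4, 8)
  ss <- run_gwas_linear(robpgs:::subset_panel(p, 1:600), ph$y[1:600])
  sc <- scaled_effects(ss, sd_y = sd(ph$y[1:600]))
  ld <- build_ld(robpgs:::subset_panel(p, 601:900), window_cm = 3)
  y_null <- rnorm(300)
  Xv <- p$G[601:900, ]
  conv <- sc$sd_y / sc$sd_ss
  # a null validation phenotype gives ~0 scores everywhere; the tie-break
  # must return the most regularized corner of the grid
  scorer <- function(b) round(robpgs:::score_r2(Xv, y_null, b * conv), 2)
  gs <- grid_search(sc$beta_hat, ld, ss$n, p_grid = c(0.01, 0.3),
                    h2_grid = c(0.05, 0.4),
                    scorer = scorer,
                    config = gibbs_config(burn_in = 20, num_iter = 60),
                    seed = 9)
  expect_equal(gs$h2, 0.05)
})
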