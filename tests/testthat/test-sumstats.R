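mk_stats <- function(beta, se, n, freq = NULL, info = NULL, N = NULL,
                     trait_type = "quantitative") {
  m <- length(beta)
  sumstats(chr = 1, pos = seq_len(m), a0 = "A", a1 = "C", beta = beta,
           beta_se = se, n = rep_len(n, m), freq = freq, info = info,
           N = N %||% max(n), trait_type = trait_type)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sd inference matches the quantitative and binary identities", {
  # plug-in with beta = 0: sd = sd_y / sqrt(n se^2)
  st <- mk_stats(0, 0.01, 1e4)
  expect_equal(sd_from_sumstats(st, sd_y = 1), 1)

  stb <- mk_stats(0, 0.02, 1e4, trait_type = "binary")
  expect_equal(sd_from_sumstats(stb), 1)  # 2 / sqrt(1e4 * 4e-4)

  # general hand value
  st2 <- mk_stats(0.3, 0.05, 400)
  expect_equal(sd_from_sumstats(st2, sd_y = 2),
               2 / sqrt(400 * 0.05^2 + 0.09))

  st3 <- mk_stats(c(0.1, NA), c(0.01, 0.01), 100)
  expect_message(out <- sd_from_sumstats(st3, sd_y = 1), "missing")
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("sd from allele frequencies follows HWE with INFO adjustment", {
  expect_equal(sd_from_af(0.5), sqrt(0.5))
  expect_equal(sd_from_af(0.5, 0.64), sqrt(0.5 * 0.64))
  expect_true(is.na(sd_from_af(0)))
  expect_true(is.na(sd_from_af(1.2)))

  p <- simulate_genotypes(3000, 50, c(0.1, 0.5), 1, 10, seed = 50)
  d <- simulate_dosages(p, 0.8, seed = 51, clip = FALSE)
  expect_equal(sd_from_af(colMeans(d$D) / 2, d$info),
               apply(d$D, 2, sd), tolerance = 0.03)
})

test_that("var(y) estimate is the first percentile and is outlier-robust", {
  # constant vector: N se^2 + beta^2 = 2 everywhere -> estimate 1
  st <- mk_stats(1, sqrt(1 / 300), 300, N = 300)
  expect_equal(estimate_var_y(st), 1)

  # simulated GWAS with var(y) = 1
  p <- simulate_genotypes(4000, 1000, c(0.05, 0.5), 1, 10, seed = 52)
  ph <- simulate_phenotype(p, 0.3, 50, seed = 53)
  y <- ph$y / sd(ph$y)
  ss <- run_gwas_linear(p, y)
  expect_equal(estimate_var_y(ss), 1, tolerance = 0.05)

  # one gross outlier among many leaves the estimate unchanged to 3 decimals
  base <- estimate_var_y(ss)
  ss_out <- ss
  ss_out$beta_se[1] <- 50
  expect_equal(estimate_var_y(ss_out), base, tolerance = 5e-4)

  stb <- mk_stats(0, 0.02, 100, trait_type = "binary")
  expect_error(estimate_var_y(stb), "effective-n")
})

test_that("sample-size imputation inverts the sd identity and clamps", {
  # round trip: se generated from the identity, n recovered exactly
  n_true <- c(5000, 8000, 10000)
  var_g <- c(0.2, 0.35, 0.48)
  beta <- c(0.01, -0.02, 0.005)
  var_y <- 1.3
  se <- sqrt((var_y / var_g - beta^2) / n_true)
  st <- mk_stats(beta, se, 10000, N = 10000)
  imp <- impute_n(st, var_y = var_y, clamp = NULL, var_g = var_g)
  expect_equal(imp$n_raw, n_true, tolerance = 1e-10)

  # binary hand value: (4 / 0.32) / 0.0125^2 = 80,000
  stb <- mk_stats(0, 0.0125, 8e4, trait_type = "binary", N = 8e4)
  impb <- impute_n(stb, clamp = NULL, var_g = 0.32)
  expect_equal(impb$n_raw, 80000)

  # true n = 0.3 N -> clamped to 0.5 N with the flag set
  n_low <- 3000; N <- 10000
  se2 <- sqrt((var_y / 0.3) / n_low)
  st2 <- mk_stats(0, se2, N, N = N)
  imp2 <- impute_n(st2, var_y = var_y, var_g = 0.3)
  expect_equal(imp2$n_imp, 5000)
  expect_true(imp2$clamped)
})

test_that("effective sample size uses the zero-count continuity convention", {
  expect_equal(effective_sample_size(500, 500), 1000)
  expect_equal(effective_sample_size(500, 2000), 1600)
  expect_equal(effective_sample_size(c(1000, 0), c(0, 1000)), 0)
  expect_equal(effective_sample_size(c(500, 250), c(500, 250)), 1500)
  expect_error(effective_sample_size(-1, 10), "non-negative")
})

test_that("scaled effects are marginal correlations with an exact inverse", {
  # gamma = se, n = 3: beta_scaled = 1/2
  st <- mk_stats(0.04, 0.04, 3)
  expect_equal(scaled_effects(st, sd_y = 1)$beta_hat, 0.5)

  # matches empirical marginal correlation in a full-sample GWAS
  stx <- tiny_study()
  sc <- scaled_effects(stx$stats, sd_y = sd(stx$pheno$y))
  emp <- as.numeric(cor(stx$panel$G, stx$pheno$y))
  expect_true(all(abs(sc$beta_hat - emp) < 0.01))
  expect_true(all(abs(sc$beta_hat) < 1))

  # exact round trip scaled -> per-allele -> scaled
  per_allele <- per_allele_effects(sc$beta_hat, stx$stats,
                                   sd_y = sd(stx$pheno$y))
  st2 <- stx$stats
  st2$beta <- per_allele
  expect_equal(per_allele, stx$stats$beta, tolerance = 1e-12)
})

test_that("INFO corrections apply exponent triples with preset identities", {
  st <- mk_stats(c(0.10, 0.2), c(0.020, 0.05), 1000,
                 info = c(0.64, 0.81))

  # sqrt_info hand value: gamma' = 0.08, se' = 0.016 at INFO 0.64
  cs <- apply_info_correction(st, "sqrt_info")
  expect_equal(cs$beta[1], 0.08)
  expect_equal(cs$beta_se[1], 0.016)
  expect_equal(cs$n, st$n)
  # Z preserved for every variant
  expect_equal(cs$beta / cs$beta_se, st$beta / st$beta_se)

  # info preset preserves se and multiplies n by INFO
  ci <- apply_info_correction(st, "info")
  expect_equal(ci$beta_se, st$beta_se)
  expect_equal(ci$n, st$n * st$info)

  # INFO = 1 everywhere: identity for every preset
  st1 <- mk_stats(c(0.1, 0.2), c(0.02, 0.05), 1000, info = c(1, 1))
  for (nm in c("sqrt_info", "info", "in_between")) {
    cc <- apply_info_correction(st1, nm)
    expect_equal(cc$beta, st1$beta)
    expect_equal(cc$beta_se, st1$beta_se)
    expect_equal(cc$n, st1$n)
  }

  st_no <- mk_stats(0.1, 0.02, 1000)
  expect_error(apply_info_correction(st_no, "sqrt_info"), "info")
  expect_warning(apply_info_correction(st_no, "sqrt_info",
                                       default_info = 0.9), "default_info")
  expect_error(info_correction("custom", exponents = c(2, 0, 0)), "\\[0, 1\\]")
})

test_that("power ratio summaries behave under scaling and permutation", {
  set.seed(1)
  chi_lin <- rchisq(50, df = 1) + 30
  expect_equal(as.numeric(estimate_power_ratio(chi_lin, chi_lin,
                                               rep(TRUE, 50))), 1)
  r <- estimate_power_ratio(1.2 * chi_lin, chi_lin, rep(TRUE, 50))
  expect_equal(as.numeric(r), 1.2)
  expect_equal(unname(attr(r, "diagnostics")["ratio_of_means"]), 1.2)

  # heteroskedastic 3-variant toy: the two summaries differ, both reported
  b <- c(2, 10, 60); l <- c(1, 10, 20)
  d <- attr(estimate_power_ratio(b, l, rep(TRUE, 3)), "diagnostics")
  expect_gt(abs(d[["mean_of_ratios"]] - d[["ratio_of_means"]]), 0.1)

  # ratio-of-means invariant to common scaling; both to permutation
  perm <- c(3, 1, 2)
  expect_equal(estimate_power_ratio(b[perm], l[perm], rep(TRUE, 3),
                                    "ratio_of_means")[1],
               estimate_power_ratio(2 * b, 2 * l, rep(TRUE, 3),
                                    "ratio_of_means")[1])
  expect_equal(estimate_power_ratio(b[perm], l[perm], rep(TRUE, 3))[1],
               estimate_power_ratio(b, l, rep(TRUE, 3))[1])
  expect_error(estimate_power_ratio(b, l, rep(FALSE, 3)), "no variants")
})

test_that("global effective-n percentile uses linear interpolation", {
  expect_equal(global_neff_percentile(rep(7, 10), 0.5), 7)
  # pinned convention: 1..100 at the 80th percentile -> 80.2
  expect_equal(global_neff_percentile(1:100, 0.8), 80.2)
  # mixture: tracks the upper plateau, not the mean
  neff <- c(rep(50000, 70), rep(25000, 30))
  est <- global_neff_percentile(neff, 0.8, reported = 50000)
  expect_equal(as.numeric(est), 50000)
  expect_equal(attr(est, "ratio"), 1)
  expect_gt(as.numeric(est), mean(neff))
  expect_error(global_neff_percentile(numeric(0)), "empty")
})

test_that("recompute_info matches MACH form and flags degenerate columns", {
  # hard genotypes in HWE: INFO ~ 1
  set.seed(2)
  G <- matrix(rbinom(4000 * 20, 2, 0.3), 4000, 20)
  info <- recompute_info(G)
  expect_true(all(abs(info - 1) < 0.06))

  # constant column flagged missing, not 0
  G2 <- cbind(G, 1)
  info2 <- recompute_info(G2)
  expect_true(is.na(info2[21]))
  expect_true(attr(info2, "monomorphic")[21])
})

test_that("sumstats TSV dialect round-trips with column mapping", {
  st <- mk_stats(c(0.1, -0.2), c(0.02, 0.03), c(900, 1000),
                 freq = c(0.3, 0.6), info = c(0.9, 0.8))
  f <- file.path(tempdir(), "ss.tsv")
  write_sumstats(st, f)
  back <- read_sumstats(f)
  expect_equal(back$beta, st$beta)
  expect_equal(back$info, st$info)

  # external headers via mapping
  df <- read.delim(f)
  names(df)[names(df) == "beta"] <- "b"
  names(df)[names(df) == "beta_se"] <- "se_b"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_sumstats(f, mapping = c(beta = "b", beta_se = "se_b"))
  expect_equal(back2$beta, st$beta)
  expect_error(read_sumstats(f, mapping = c(beta = "nope")), "available")
})
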