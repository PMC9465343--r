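test_that("genotype panel respects MAF range, positions, and determinism", {
  p1 <- simulate_genotypes(500, 100, c(0.1, 0.4), ld_decay = 1,
                           n_founder_haplotypes = 10, seed = 1)
  p2 <- simulate_genotypes(500, 100, c(0.1, 0.4), ld_decay = 1,
                           n_founder_haplotypes = 10, seed = 1)
  expect_identical(p1$G, p2$G)
  expect_identical(p1$pos_cm, p2$pos_cm)
  expect_true(all(p1$G %in% 0:2))
  maf <- pmin(p1$freq, 1 - p1$freq)
  expect_true(all(maf >= 0.1 & maf <= 0.4))
  expect_equal(colMeans(p1$G) / 2, p1$freq)
  expect_false(is.unsorted(p1$pos_cm))
  expect_error(simulate_genotypes(10, 0), "empty")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("LD decays with genetic distance at the requested rate", {
  # independence limit: breakpoint between every pair
  p_ind <- simulate_genotypes(1500, 60, c(0.2, 0.5), ld_decay = Inf,
                              n_founder_haplotypes = 10, seed = 2)
  C <- cor(p_ind$G)
  expect_lt(mean(abs(C[upper.tri(C)])), 0.035)  # ~ MC error at n = 1500

  # degenerate founder pool: two founders, no recombination
  p2f <- simulate_genotypes(800, 30, c(0.2, 0.5), ld_decay = 0,
                            n_founder_haplotypes = 2, seed = 3)
  C2 <- abs(cor(p2f$G))
  # variants where the two founders differ are perfectly correlated
  differs <- apply(p2f$founder_alleles, 2, function(a) a[1] != a[2])
  if (sum(differs) >= 2) {
    sub <- C2[differs, differs]
    expect_true(all(sub[upper.tri(sub)] > 0.99))
  }

  # decreasing r2 ~ distance (direct empirical LD oracle)
  p <- simulate_genotypes(2000, 500, c(0.05, 0.5), ld_decay = 1,
                          n_founder_haplotypes = 10, seed = 4)
  C <- cor(p$G)^2
  d <- abs(outer(p$pos_cm, p$pos_cm, "-"))
  ut <- upper.tri(C)
  ct <- suppressWarnings(cor.test(C[ut], d[ut], method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("dosage construction hits target INFO and conditional-expectation", {
  p <- simulate_genotypes(5000, 150, c(0.1, 0.5), 1, 10, seed = 5)

  d1 <- simulate_dosages(p, 1, seed = 6)
  expect_identical(d1$D, p$G)   # identity at INFO = 1

  d <- simulate_dosages(p, 0.5, seed = 7, clip = FALSE)
  sd_ratio <- apply(d$D, 2, sd) / apply(p$G, 2, sd)
  expect_equal(mean(sd_ratio), sqrt(0.5), tolerance = 0.02)
  expect_true(all(abs(d$info - 0.5) < 0.06))
  # cov(D, G) = var(D): the dosage is a conditional expectation
  cv <- vapply(seq_len(50), function(j)
    cov(d$D[, j], p$G[, j]) / var(d$D[, j]), numeric(1))
  expect_equal(mean(cv), 1, tolerance = 0.02)

  # clipping keeps [0,2] and the stored realized INFO is post-clipping
  dc <- simulate_dosages(p, 0.5, seed = 7, clip = TRUE)
  expect_true(all(dc$D >= 0 & dc$D <= 2))
  expect_equal(dc$info, as.numeric(recompute_info(dc$D)))

  expect_error(simulate_dosages(p, 0), "target_info")
})

test_that("realized INFO round-trips through recompute_info at target 0.7", {
  p <- simulate_genotypes(5000, 100, c(0.15, 0.5), 1, 10, seed = 8)
  d <- simulate_dosages(p, 0.7, seed = 9, clip = FALSE)
  info <- recompute_info(d)
  expect_true(all(abs(info - 0.7) < 0.05))
  expect_equal(mean(info), 0.7, tolerance = 0.02)
})

test_that("phenotype has exact in-sample heritability and valid edge cases", {
  p <- simulate_genotypes(3000, 400, c(0.05, 0.5), 1, 10, seed = 10)
  ph <- simulate_phenotype(p, 0.2, 20, seed = 11)
  expect_equal(var(ph$genetic) / var(ph$y), 0.2, tolerance = 1e-12)
  expect_length(ph$causal_set, 20)
  expect_true(all(ph$gamma_scaled[-ph$causal_set] == 0))

  ph0 <- simulate_phenotype(p, 0, 5, seed = 12)
  expect_true(all(ph0$genetic == 0))
  ph1 <- simulate_phenotype(p, 1, 5, seed = 13)
  expect_identical(ph1$y, ph1$genetic)

  # without rescaling the target is only met in expectation
  phn <- simulate_phenotype(p, 0.2, 20, seed = 14, rescale_noise = FALSE)
  expect_equal(var(phn$genetic) / var(phn$y), 0.2, tolerance = 0.05)

  expect_error(simulate_phenotype(p, 1.2, 5), "h2")
})

test_that("per-variant GWAS matches closed-form OLS", {
  # 5-individual toy, hand-checkable
  g <- c(0, 1, 2, 1, 0)
  y <- c(0.1, 1.2, 1.9, 0.8, 0.0)
  ss <- run_gwas_linear(matrix(g, 5, 1), y)
  fit <- lm(y ~ g)
  expect_equal(ss$beta, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(ss$beta_se, unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-12)

  # perfect fit: slope 1, se 0
  ss2 <- run_gwas_linear(matrix(g, 5, 1), g)
  expect_equal(ss2$beta, 1)
  expect_equal(ss2$beta_se, 0)

  # zero-variance variant flagged as missing
  suppressMessages(
    ss3 <- run_gwas_linear(cbind(g, rep(1, 5)), y))
  expect_true(is.na(ss3$beta[2]))
  expect_false(is.na(ss3$beta[1]))
})

test_that("GWAS subsampling yields the stated per-variant n", {
  st <- tiny_study()
  ss <- run_gwas_linear(st$panel, st$pheno$y,
                        subsample_fraction = c(1, 0.8, 0.6), seed = 20)
  n <- nrow(st$panel$G)
  expect_true(all(ss$n %in% round(c(1, 0.8, 0.6) * n)))
  expect_equal(ss$n[1:3], round(c(1, 0.8, 0.6) * n))
})

test_that("sd inferred from full-sample GWAS matches empirical genotype sd", {
  # the foundational identity: relative error < 1% at n = 10,000
  p <- simulate_genotypes(10000, 150, c(0.05, 0.5), 1, 10, seed = 21)
  ph <- simulate_phenotype(p, 0.3, 10, seed = 22)
  ss <- run_gwas_linear(p, ph$y)
  sd_ss <- sd_from_sumstats(ss, sd_y = sd(ph$y))
  sd_emp <- apply(p$G, 2, sd)
  expect_true(all(abs(sd_ss / sd_emp - 1) < 0.01))
  fit <- lm(sd_ss ~ 0 + sd_emp)
  expect_equal(unname(coef(fit)), 1, tolerance = 0.01)
})

test_that("multiple-imputation GWAS pools by Rubin's rules", {
  p <- simulate_genotypes(1200, 80, c(0.1, 0.5), 1, 10, seed = 23)
  ph <- simulate_phenotype(p, 0.3, 8, seed = 24)

  # INFO = 1: all imputations identical, pooled = single GWAS
  d1 <- simulate_dosages(p, 1, seed = 25)
  mi <- run_gwas_multiple_imputation(d1, ph$y, n_imputations = 3, seed = 26)
  single <- run_gwas_linear(p, ph$y)
  expect_equal(mi$beta, single$beta, tolerance = 1e-12)
  expect_equal(mi$beta_se, single$beta_se, tolerance = 1e-12)

  # pooled se shrinks toward the within-variance as m grows
  d <- simulate_dosages(p, 0.6, seed = 27)
  mi2 <- run_gwas_multiple_imputation(d, ph$y, n_imputations = 2, seed = 28)
  mi20 <- run_gwas_multiple_imputation(d, ph$y, n_imputations = 20, seed = 28)
  expect_lt(mean(mi20$beta_se), mean(mi2$beta_se))

  expect_error(run_gwas_multiple_imputation(d, ph$y, n_imputations = 1),
               "at least 2")
})

test_that("MI estimates track dosage estimates scaled by INFO", {
  p <- simulate_genotypes(4000, 120, c(0.15, 0.5), 1, 8, seed = 29)
  d <- simulate_dosages(p, runif(120, 0.4, 0.9), seed = 30)
  hc <- hard_call_dosages(d, seed = 31)
  ph <- simulate_phenotype(hc, 0.4, 12, seed = 32)
  gimp <- run_gwas_linear(d, ph$y)
  mi <- run_gwas_multiple_imputation(d, ph$y, n_imputations = 10, seed = 33)
  # exact attenuation ratio var(D)/var(G*); the MACH INFO approximates it
  atten <- apply(d$D, 2, var) / apply(hc$G, 2, var)
  fit <- lm(mi$beta ~ 0 + I(gimp$beta * atten))
  expect_equal(unname(coef(fit)), 1, tolerance = 0.05)
  expect_gt(cor(mi$beta, gimp$beta * d$info), 0.98)
})

test_that("hard calls are consistent with dosages", {
  p <- simulate_genotypes(3000, 60, c(0.1, 0.5), 1, 10, seed = 34)
  d <- simulate_dosages(p, 0.7, seed = 35)
  hc <- hard_call_dosages(d, seed = 36)
  expect_true(all(hc$G %in% 0:2))
  expect_equal(colMeans(hc$G), colMeans(d$D), tolerance = 0.03)
  # integer dosages round-trip exactly
  d1 <- simulate_dosages(p, 1)
  expect_identical(hard_call_dosages(d1)$G, p$G)
})

test_that("scenarios are seeded, labelled, and correctly proportioned", {
  sc <- build_scenario("sample-size",
                       list(n_train = 300, n_valid = 100, n_test = 100,
                            n_variants = 8, n_causal = 2), seed = 9)
  # 8 variants: exactly 4 at fraction 1.0, 2 at 0.8, 2 at 0.6
  expect_equal(sort(table(sc$fractions), decreasing = TRUE),
               sort(table(c(1, 1, 1, 1, 0.8, 0.8, 0.6, 0.6)),
                    decreasing = TRUE), ignore_attr = TRUE)
  expect_equal(sc$stats$n, round(sc$fractions * 300))

  sc2 <- build_scenario("sample-size",
                        list(n_train = 300, n_valid = 100, n_test = 100,
                             n_variants = 8, n_causal = 2), seed = 9)
  expect_identical(sc$panel$G, sc2$panel$G)
  expect_identical(sc$stats$beta, sc2$stats$beta)

  expect_error(build_scenario("nonsense"), "arg")
})

test_that("dosage scenario with INFO = 1 makes corrections no-ops", {
  sc <- build_scenario("dosage",
                       list(n_train = 500, n_valid = 100, n_test = 100,
                            n_variants = 40, n_causal = 5,
                            info_range = c(1, 1)), seed = 10)
  # scenario INFO is recomputed from the data, so it is 1 only up to
  # sampling noise; the correction must be a no-op to that accuracy
  corrected <- apply_info_correction(sc$stats, "sqrt_info")
  expect_equal(corrected$beta, sc$stats$beta, tolerance = 0.02)
  expect_equal(corrected$beta_se, sc$stats$beta_se, tolerance = 0.02)
  # true panel equals dosages exactly at INFO 1
  expect_identical(sc$panel$G, sc$dosages$D)
})

test_that("ld-mismatch panels are exchangeable at drift 0", {
  sc <- build_scenario("ld-mismatch",
                       list(n_train = 400, n_valid = 200, n_test = 100,
                            n_variants = 60, n_causal = 6, drift = 0),
                       seed = 11)
  expect_identical(sc$ld_panel$founder_alleles, sc$panel$founder_alleles)
  expect_gt(cor(sc$panel$freq, sc$ld_panel$freq), 0.95)
})

test_that("panels and phenotypes round-trip through the on-disk container", {
  st <- tiny_study()
  prefix <- file.path(tempdir(), "panel_rt")
  panel_write(st$panel, prefix)
  back <- panel_read(prefix)
  expect_equal(back$G, st$panel$G, ignore_attr = TRUE)
  expect_equal(back$pos_cm, st$panel$pos_cm)
  expect_identical(back$a0, st$panel$a0)
  pheno_write(st$pheno, file.path(tempdir(), "y.tsv"))
  y2 <- read.delim(file.path(tempdir(), "y.tsv"))$y
  expect_equal(y2, st$pheno$y)
})
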