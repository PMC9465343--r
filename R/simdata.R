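#' Simulate a genotype panel with blocky LD
#'
#' Mosaic-of-founder-haplotypes construction: each of the `2 n` haplotypes
#' copies segments from a pool of `n_founder_haplotypes` founders, with
#' recombination breakpoints occurring at rate `ld_decay` per cM, so the
#' correlation between two variants decays approximately as
#' `exp(-ld_decay * d)` times the founder-pool allele correlation.  Smaller
#' founder pools give stronger LD (adjacent r2 of order `1/K`).  Founder
#' alleles are drawn per variant with rejection so the empirical minor
#' allele frequency falls in `maf_range` (which also rules out monomorphic
#' columns).  Genetic positions are a Poisson process with mean gap
#' `spacing_cm`, plus recombination hotspots (an extra `hotspot_jump_cm`
#' centimorgans every `hotspot_spacing_cm` on average) that produce the
#' blocky LD structure of real genomes; physical positions use the
#' 1 cM = 1 Mbp fallback map.
#'
#' @param n_individuals,n_variants panel dimensions (both >= 1).
#' @param maf_range length-2 interval inside (0, 0.5].
#' @param ld_decay recombination rate per cM; `Inf` gives independent
#'   variants, 0 gives no recombination.
#' @param n_founder_haplotypes founder pool size (>= 2; default 50).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param spacing_cm mean genetic gap between adjacent variants (cM).
#' @param hotspot_spacing_cm mean background distance between recombination
#'   hotspots (cM); `Inf` disables hotspots.
#' @param hotspot_jump_cm extra genetic distance added at a hotspot (cM).
#' @param chromosome chromosome label for the variant metadata.
#' @param founder_alleles optional K x m 0/1 matrix reusing a founder pool
#'   (e.g. after drift), bypassing the MAF rejection step.
#'
#' @return A list of class `"geno_panel"`: `G` (n x m matrix in 0..2),
#'   `freq`, `pos_bp`, `pos_cm`, `chr`, `a0`, `a1`, `founder_alleles`.
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.05, 0.5), ld_decay = 1,
                               n_founder_haplotypes = 50, seed = NULL,
                               spacing_cm = 0.02, hotspot_spacing_cm = 2,
                               hotspot_jump_cm = 1, chromosome = 22L,
                               founder_alleles = NULL) {
  if (n_variants < 1) stop("cannot build an empty panel (n_variants >= 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval inside (0, 0.5]")
  if (n_founder_haplotypes < 2) stop("need at least 2 founder haplotypes")
  if (!is.null(seed)) set.seed(seed)

  gaps <- stats::rexp(n_variants, rate = 1 / spacing_cm)
  if (is.finite(hotspot_spacing_cm)) {
    hot <- runif(n_variants) < spacing_cm / hotspot_spacing_cm
    gaps <- gaps + hot * hotspot_jump_cm
  }
  pos_cm <- cumsum(gaps)
  pos_bp <- cumsum(pmax(1, round(gaps * 1e6)))

  res <- mosaic_genotypes_cpp(n_individuals, pos_cm,
                              as.integer(n_founder_haplotypes),
                              ld_decay, maf_range[1], maf_range[2],
                              founder_alleles, 200L)

  bases <- c("A", "C", "G", "T")
  a0 <- sample(bases, n_variants, replace = TRUE)
  partner <- list(A = c("C", "G"), C = c("A", "T"),
                  G = c("A", "T"), T = c("C", "G"))
  a1 <- vapply(a0, function(b) sample(partner[[b]], 1), character(1))

  structure(list(G = res$G, freq = res$freq, pos_bp = pos_bp,
                 pos_cm = pos_cm, chr = rep(chromosome, n_variants),
                 a0 = a0, a1 = unname(a1),
                 founder_alleles = res$founder_alleles),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d individuals x %d variants, chr %s, %.1f cM\n",
              nrow(x$G), ncol(x$G), x$chr[1], diff(range(x$pos_cm))))
  invisible(x)
}

#' Simulate imputed allele dosages with target INFO
#'
#' Linear conditional-expectation construction:
#' `D_j = 2 f_j + INFO_j (G_j - 2 f_j + eps_j)` with Gaussian `eps_j` of
#' variance `var(G_j) (1/INFO_j - 1)`, so that `var(D_j) = INFO_j var(G_j)`
#' and `cov(D_j, G_j) = var(D_j)` (the dosage is an unbiased conditional
#' expectation of the genotype).  With `clip = TRUE` (default) dosages are
#' then clipped to \[0, 2\]; because the Gaussian noise places appreciable
#' mass outside the box for boundary genotypes, clipping lowers the dosage
#' variance, so the realized INFO (always recomputed post-clipping with
#' [recompute_info()] and stored) sits below the target -- the stored value
#' is the one downstream corrections should use.  `clip = FALSE` keeps the
#' construction exact: realized INFO then matches the target up to sampling
#' error.  `target_info = 1` returns the genotypes unchanged.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param target_info INFO targets in (0, 1], recycled over variants.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param clip clip dosages to \[0, 2\] (default TRUE).
#' @return A list of class `"dosage_panel"`: `D`, `target_info`, `info`
#'   (realized, post-clipping), `freq` (dosage-based) plus the panel's
#'   variant metadata.
#' @export
simulate_dosages <- function(panel, target_info, seed = NULL, clip = TRUE) {
  if (any(target_info <= 0 | target_info > 1))
    stop("target_info must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  G <- panel$G
  n <- nrow(G); m <- ncol(G)
  info <- rep_len(target_info, m)
  f <- colMeans(G) / 2
  vg <- matrixStats_colVars(G)
  sd_eps <- sqrt(pmax(vg * (1 / info - 1), 0))
  D <- sweep(G, 2, 2 * f, "-") +
    matrix(rnorm(n * m), n, m) %*% diag(sd_eps, m, m)
  D <- sweep(D, 2, info, "*")
  D <- sweep(D, 2, 2 * f, "+")
  if (clip) { D[D < 0] <- 0; D[D > 2] <- 2 }
  exact <- info == 1
  if (any(exact)) D[, exact] <- G[, exact]

  realized <- recompute_info(D)
  structure(list(D = D, target_info = info,
                 info = as.numeric(realized), freq = colMeans(D) / 2,
                 pos_bp = panel$pos_bp, pos_cm = panel$pos_cm,
                 chr = panel$chr, a0 = panel$a0, a1 = panel$a1),
            class = "dosage_panel")
}

#' Sample hard-called genotypes consistent with dosages
#'
#' Each dosage `d` is resolved to one of its two adjacent integer genotypes
#' with probabilities chosen so the expectation equals `d` (for `d <= 1`,
#' genotype 1 with probability `d`; for `d > 1`, genotype 2 with probability
#' `d - 1`).  Integer dosages are kept as-is, so INFO = 1 dosages round-trip
#' exactly.  This emulates reading imputed data as hard calls sampled from
#' the imputation probabilities, the counterpart of reading it as dosages.
#'
#' @param dosages a [simulate_dosages()] panel (or dosage matrix).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `"geno_panel"` whose `G` are synthetic hard calls.
#' @export
hard_call_dosages <- function(dosages, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- if (is.matrix(dosages)) dosages else dosages$D
  lo <- floor(D)
  G <- lo + (matrix(runif(length(D)), nrow(D)) < (D - lo))
  meta <- if (is.matrix(dosages)) {
    list(pos_bp = seq_len(ncol(D)), pos_cm = seq_len(ncol(D)) * 1e-6,
         chr = rep(NA, ncol(D)), a0 = rep("A", ncol(D)), a1 = rep("C", ncol(D)))
  } else dosages
  structure(list(G = G, freq = colMeans(G) / 2, pos_bp = meta$pos_bp,
                 pos_cm = meta$pos_cm, chr = meta$chr,
                 a0 = meta$a0, a1 = meta$a1, founder_alleles = NULL),
            class = "geno_panel")
}

#' Simulate a quantitative phenotype with fixed heritability
#'
#' Samples `n_causal` causal variants uniformly without replacement, draws
#' their effects i.i.d. `N(0, h2 / n_causal)` on the scaled-genotype scale,
#' and adds Gaussian noise.  With `rescale_noise = TRUE` (default) the noise
#' is first residualized against the genetic component and then rescaled so
#' the realized in-sample heritability equals `h2` exactly.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param h2 target heritability in \[0, 1\].
#' @param n_causal number of causal variants (1..m).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param rescale_noise make the in-sample heritability exact (default).
#' @return A list of class `"pheno_model"`: `y`, `causal_set`,
#'   `gamma_scaled` (length m, zero off the causal set), `genetic`
#'   (the genetic component), `h2_target`, `h2_realized`, `n_causal`.
#' @export
simulate_phenotype <- function(panel, h2, n_causal, seed = NULL,
                               rescale_noise = TRUE) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  G <- panel$G
  n <- nrow(G); m <- ncol(G)
  if (n_causal < 1 || n_causal > m) stop("n_causal must be in 1..n_variants")
  if (!is.null(seed)) set.seed(seed)

  causal <- sort(sample.int(m, n_causal))
  gamma <- rep(0, m)
  if (h2 > 0) {
    gamma[causal] <- rnorm(n_causal, sd = sqrt(h2 / n_causal))
    Xs <- scale(G[, causal, drop = FALSE])
    g <- drop(Xs %*% gamma[causal])
  } else {
    g <- rep(0, n)
  }

  if (h2 == 0) {
    y <- rnorm(n)
  } else if (h2 == 1) {
    y <- g
  } else {
    e <- rnorm(n)
    if (rescale_noise) {
      e <- e - g * sum(e * g) / sum(g^2)        # exactly orthogonal to g
      e <- e * sqrt(var(g) * (1 - h2) / h2 / var(e))
    } else {
      e <- e * sqrt(var(g) * (1 - h2) / h2)
    }
    y <- g + e
  }
  h2_real <- if (h2 %in% c(0, 1)) h2 else var(g) / var(y)

  structure(list(y = y, causal_set = causal, gamma_scaled = gamma,
                 genetic = g, h2_target = h2, h2_realized = h2_real,
                 n_causal = n_causal),
            class = "pheno_model")
}

#' Per-variant linear-regression GWAS with independent subsamples
#'
#' Runs a simple linear regression of `y` on each variant separately, each
#' variant on its own seeded subsample of the stated fraction (emulating a
#' meta-analysis where cohorts cover different variants).  Zero-variance
#' variants within their subsample are flagged and emitted as missing.
#'
#' @param x a genotype/dosage panel or a plain numeric matrix.
#' @param y phenotype vector, one value per individual.
#' @param subsample_fraction fraction(s) in (0, 1], recycled over variants.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [sumstats] table with per-variant `n = round(fraction * n)`,
#'   panel allele frequencies and (for dosage panels) realized INFO copied
#'   into the output; flagged variants have `NA` effect and se.
#' @export
run_gwas_linear <- function(x, y, subsample_fraction = 1, seed = NULL) {
  X <- if (is.matrix(x)) x else if (inherits(x, "dosage_panel")) x$D else x$G
  if (length(y) != nrow(X)) stop("y length must equal the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(X)
  frac <- rep_len(subsample_fraction, m)
  res <- gwas_linreg_cpp(X, y, frac)
  if (any(res$zero_var == 1))
    message(sum(res$zero_var), " zero-variance variant(s) flagged as missing")

  meta <- if (is.matrix(x)) {
    list(chr = rep(NA_integer_, m), pos_bp = seq_len(m),
         a0 = rep("A", m), a1 = rep("C", m), freq = res$freq, info = NULL)
  } else x
  ss <- sumstats(chr = meta$chr, pos = meta$pos_bp, a0 = meta$a0,
                 a1 = meta$a1, beta = res$beta, beta_se = res$se,
                 n = res$n, freq = meta$freq,
                 info = if (inherits(x, "dosage_panel")) x$info else NULL,
                 N = max(res$n))
  attr(ss, "zero_var") <- res$zero_var == 1
  ss
}

#' Multiple-imputation GWAS from dosages
#'
#' Forms `n_imputations` datasets of hard-called genotypes sampled from the
#' dosages (see [hard_call_dosages()]), runs a full-sample GWAS on each, and
#' pools by Rubin's rules: the pooled estimate is the mean, the total
#' variance is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param dosages a [simulate_dosages()] panel.
#' @param y phenotype vector.
#' @param n_imputations number of imputed datasets (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A pooled [sumstats] table.
#' @export
run_gwas_multiple_imputation <- function(dosages, y, n_imputations = 20,
                                         seed = NULL) {
  if (n_imputations < 2) stop("need at least 2 imputations")
  D <- dosages$D
  if (any(D < 0 | D > 2)) stop("degenerate dosages outside [0, 2]")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(D)
  est <- se2 <- matrix(NA_real_, m, n_imputations)
  for (i in seq_len(n_imputations)) {
    hc <- hard_call_dosages(dosages)
    r <- gwas_linreg_cpp(hc$G, y, rep(1, m))
    est[, i] <- r$beta
    se2[, i] <- r$se^2
  }
  pooled <- rowMeans(est)
  W <- rowMeans(se2)
  B <- apply(est, 1, var)
  tot <- W + (1 + 1 / n_imputations) * B
  sumstats(chr = dosages$chr, pos = dosages$pos_bp, a0 = dosages$a0,
           a1 = dosages$a1, beta = pooled, beta_se = sqrt(tot),
           n = rep(nrow(D), m), freq = dosages$freq, info = dosages$info,
           N = nrow(D))
}

#' Build a complete misspecification scenario
#'
#' Generates a full study design -- genotype panel(s), phenotype, GWAS
#' summary statistics and train/validation/test split -- under one of three
#' misspecification scenarios:
#'
#' * `"sample-size"`: per-variant GWAS subsampling at fractions (1.0, 0.8,
#'   0.6) assigned to exact proportions (1/2, 1/4, 1/4) of the variants.
#' * `"dosage"`: dosages with heterogeneous INFO are built first; the
#'   "true" panel is hard calls sampled from them, the phenotype comes from
#'   the true panel, the GWAS runs on the dosages (with recomputed INFO and
#'   dosage frequencies), and the LD reference uses the true genotypes.
#' * `"ld-mismatch"`: the LD panel comes from a founder pool whose alleles
#'   drifted (each founder allele flipped with probability `drift`);
#'   `drift = 0` makes the two panels exchangeable draws.
#'
#' Defaults (desk scale): 2,500 variants, 10,000 training / 2,000 validation
#' / 3,000 test individuals, h2 = 0.2 with 125 causal variants (5%
#' polygenicity, the proportion of the original design), founder pool of 10
#' haplotypes, 0.04 cM mean spacing.
#'
#' @param name scenario name.
#' @param params named list overriding any default listed above (fields
#'   `n_train`, `n_valid`, `n_test`, `n_variants`, `h2`, `n_causal`,
#'   `maf_range`, `ld_decay`, `n_founders`, `spacing_cm`, `fractions`,
#'   `proportions`, `info_range`, `drift`, `n_ld`).
#' @param seed integer seed; fully determines the scenario.
#' @return A list of class `"sim_scenario"`: `label`, `panel`, `dosages`
#'   (dosage scenario), `ld_panel` (ld-mismatch), `pheno`, `stats`,
#'   `fractions`, index vectors `train`, `valid`, `test`, `params`, `seed`.
#' @export
build_scenario <- function(name = c("sample-size", "dosage", "ld-mismatch"),
                           params = list(), seed = 1) {
  name <- match.arg(name)
  p <- utils::modifyList(list(
    n_train = 10000, n_valid = 2000, n_test = 3000,
    n_variants = 2500, h2 = 0.2, n_causal = 125,
    maf_range = c(0.05, 0.5), ld_decay = 1, n_founders = 8,
    spacing_cm = 0.03, hotspot_spacing_cm = 2, hotspot_jump_cm = 1,
    fractions = c(1, 0.8, 0.6),
    proportions = c(0.5, 0.25, 0.25), info_range = c(0.3, 1),
    drift = 0.01, n_ld = NULL), params)
  set.seed(seed)
  n_all <- p$n_train + p$n_valid + p$n_test
  idx_train <- seq_len(p$n_train)
  idx_valid <- p$n_train + seq_len(p$n_valid)
  idx_test <- p$n_train + p$n_valid + seq_len(p$n_test)

  panel <- simulate_genotypes(n_all, p$n_variants, p$maf_range, p$ld_decay,
                              p$n_founders, spacing_cm = p$spacing_cm,
                              hotspot_spacing_cm = p$hotspot_spacing_cm,
                              hotspot_jump_cm = p$hotspot_jump_cm)
  dosages <- NULL; ld_panel <- NULL; fractions <- rep(1, p$n_variants)

  if (name == "sample-size") {
    m <- p$n_variants
    counts <- c(round(m * p$proportions[1]), round(m * p$proportions[2]))
    counts <- c(counts, m - sum(counts))
    grp <- sample(rep.int(seq_along(p$fractions), counts))
    fractions <- p$fractions[grp]
    pheno <- simulate_phenotype(panel, p$h2, p$n_causal)
    stats <- run_gwas_linear(subset_panel(panel, idx_train),
                             pheno$y[idx_train], fractions)
  } else if (name == "dosage") {
    info <- runif(p$n_variants, p$info_range[1], p$info_range[2])
    dosages <- simulate_dosages(panel, info)
    panel <- hard_call_dosages(dosages)   # "true" genotypes
    pheno <- simulate_phenotype(panel, p$h2, p$n_causal)
    d_train <- subset_dosages(dosages, idx_train)
    stats <- run_gwas_linear(d_train, pheno$y[idx_train])
    stats$info <- as.numeric(recompute_info(d_train$D))
    stats$freq <- colMeans(d_train$D) / 2
  } else {  # ld-mismatch
    alleles <- panel$founder_alleles
    flip <- matrix(runif(length(alleles)) < p$drift, nrow(alleles))
    alleles_b <- ifelse(flip, 1L - alleles, alleles)
    n_ld <- p$n_ld %||% p$n_valid
    ld_panel <- simulate_genotypes(n_ld, p$n_variants, p$maf_range,
                                   p$ld_decay, p$n_founders,
                                   spacing_cm = p$spacing_cm,
                                   hotspot_spacing_cm = p$hotspot_spacing_cm,
                                   hotspot_jump_cm = p$hotspot_jump_cm,
                                   founder_alleles = alleles_b)
    # the drifted panel shares the variant map of the GWAS panel
    ld_panel$pos_cm <- panel$pos_cm; ld_panel$pos_bp <- panel$pos_bp
    ld_panel$a0 <- panel$a0; ld_panel$a1 <- panel$a1
    pheno <- simulate_phenotype(panel, p$h2, p$n_causal)
    stats <- run_gwas_linear(subset_panel(panel, idx_train),
                             pheno$y[idx_train])
  }

  structure(list(label = name, panel = panel, dosages = dosages,
                 ld_panel = ld_panel, pheno = pheno, stats = stats,
                 fractions = fractions, train = idx_train,
                 valid = idx_valid, test = idx_test,
                 params = p, seed = seed),
            class = "sim_scenario")
}

#' Subset a panel to a set of individuals
#'
#' Row-subsets a genotype or dosage panel (e.g. to its validation or test
#' individuals) and recomputes the allele frequencies.
#'
#' @param panel a genotype panel; `dos` a dosage panel.
#' @param idx individual (row) indices.
#' @return The subset panel.
#' @export
subset_panel <- function(panel, idx) {
  out <- panel
  out$G <- panel$G[idx, , drop = FALSE]
  out$freq <- colMeans(out$G) / 2
  out
}

#' @rdname subset_panel
#' @param dos a dosage panel.
#' @export
subset_dosages <- function(dos, idx) {
  out <- dos
  out$D <- dos$D[idx, , drop = FALSE]
  out$freq <- colMeans(out$D) / 2
  out
}

#' Write / read a genotype panel
#'
#' Simple on-disk container: a little-endian binary matrix of doubles
#' (`<prefix>.bin`, column-major, dimensions in `<prefix>.json`) plus a
#' variant-metadata TSV (`<prefix>.vars.tsv` with chr, pos, cM, a0, a1,
#' freq, info).  Phenotypes go to a two-column TSV via [pheno_write()].
#'
#' @param panel a genotype or dosage panel.
#' @param prefix path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
panel_write <- function(panel, prefix) {
  X <- if (inherits(panel, "dosage_panel")) panel$D else panel$G
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(X), con, size = 8, endian = "little")
  meta <- data.frame(chr = panel$chr, pos = panel$pos_bp, cm = panel$pos_cm,
                     a0 = panel$a0, a1 = panel$a1, freq = panel$freq,
                     info = if (!is.null(panel$info)) panel$info else NA)
  write.table(meta, paste0(prefix, ".vars.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = nrow(X), m = ncol(X),
                            type = class(panel)[1]),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname panel_write
#' @export
panel_read <- function(prefix) {
  dims <- jsonlite::read_json(paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  X <- matrix(readBin(con, "double", dims$n * dims$m, size = 8,
                      endian = "little"), dims$n, dims$m)
  meta <- read.delim(paste0(prefix, ".vars.tsv"),
                     colClasses = c(a0 = "character", a1 = "character"))
  out <- list(G = X, freq = meta$freq, pos_bp = meta$pos, pos_cm = meta$cm,
              chr = meta$chr, a0 = meta$a0, a1 = meta$a1,
              founder_alleles = NULL)
  if (identical(dims$type, "dosage_panel")) {
    out$D <- X; out$G <- NULL; out$info <- meta$info
    class(out) <- "dosage_panel"
  } else class(out) <- "geno_panel"
  out
}

#' @rdname panel_write
#' @param pheno a [simulate_phenotype()] model (or numeric vector).
#' @param path TSV path.
#' @export
pheno_write <- function(pheno, path) {
  y <- if (is.numeric(pheno)) pheno else pheno$y
  write.table(data.frame(sample_id = seq_along(y), y = y), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
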