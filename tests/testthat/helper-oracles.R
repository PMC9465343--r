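# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own solver code paths.

# proximal-gradient elastic net on 0.5 b'Rb - bh'b + sum(del_j/2 b_j^2)
# + sum(lam_j |b_j|); independent of the coordinate-descent implementation
prox_elastic_net <- function(bh, R, lam, del, iters = 2e5, tol = 1e-13) {
  m <- length(bh)
  lam <- rep_len(lam, m); del <- rep_len(del, m)
  A <- R + diag(del, m)
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(m)
  for (t in seq_len(iters)) {
    u <- b - (A %*% b - bh) / L
    b2 <- sign(u) * pmax(abs(u) - lam / L, 0)
    if (max(abs(b2 - b)) < tol) return(as.numeric(b2))
    b <- as.numeric(b2)
  }
  b
}

# exhaustive enumeration over all contiguous partitions of 1..m
brute_force_split <- function(R, weight, max_r2 = 1, max_block = NULL,
                              n_blocks_range = NULL) {
  m <- nrow(R)
  if (is.null(max_block)) max_block <- m
  R2 <- R^2
  best <- Inf; best_blocks <- NULL
  for (msk in 0:(2^(m - 1) - 1)) {
    cuts <- which(bitwAnd(msk, 2^(0:(m - 2))) > 0)
    blocks <- cumsum(c(1, as.integer(seq_len(m - 1) %in% cuts)))
    sizes <- table(blocks)
    if (any(sizes > max_block)) next
    k <- length(sizes)
    if (!is.null(n_blocks_range) &&
        (k < n_blocks_range[1] || k > n_blocks_range[2])) next
    C1 <- 0; ok <- TRUE
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (blocks[i] != blocks[j]) {
        if (R2[i, j] > max_r2) { ok <- FALSE; break }
        C1 <- C1 + R2[i, j]
      }
    }
    if (!ok) next
    cost <- weight * sum(sizes^2) + C1
    if (cost < best) { best <- cost; best_blocks <- blocks }
  }
  list(cost = best, blocks = best_blocks)
}

# wrap a dense symmetric matrix as an ld_matrix
dense_ld <- function(R, pos_cm = seq_len(nrow(R)), window_cm = Inf) {
  structure(list(R = methods::as(Matrix::Matrix(R, sparse = TRUE),
                                 "generalMatrix"),
                 pos_cm = pos_cm, window_cm = window_cm, blocks = NULL,
                 shrink = 1, monomorphic = NULL),
            class = "ld_matrix")
}

# small reusable panel + GWAS, cached per session
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulate_genotypes(2000, 200, c(0.1, 0.5), ld_decay = 1,
                              n_founder_haplotypes = 8, seed = 42,
                              spacing_cm = 0.05)
      ph <- simulate_phenotype(p, 0.4, 20, seed = 43)
      ss <- run_gwas_linear(p, ph$y, seed = 44)
      cache <<- list(panel = p, pheno = ph, stats = ss)
    }
    cache
  }
})

# bivariate normal density (for the 2-variant posterior oracle)
dmvn2 <- function(x, S) {
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  q <- (S[2, 2] * x[1]^2 - 2 * S[1, 2] * x[1] * x[2] + S[1, 1] * x[2]^2) / detS
  exp(-q / 2) / (2 * pi * sqrt(detS))
}

# analytic marginal posterior of beta_1 for the 2-variant spike-and-slab
# model beta_hat | beta ~ N(R beta, R/n), beta_j ~ p N(0, s2) + (1-p) d0:
# returns the mixture CDF (atom at 0 + two Gaussian components)
posterior2_cdf <- function(bh, r, n, p, s2) {
  R <- matrix(c(1, r, r, 1), 2)
  Sn <- R / n
  e1 <- c(1, 0); e2 <- c(0, 1)
  w <- numeric(4); comp <- list()
  # config 00
  w[1] <- (1 - p)^2 * dmvn2(bh, Sn)
  # config 10: beta1 in slab
  S10 <- Sn + s2 * (R %*% e1) %*% t(R %*% e1)
  w[2] <- p * (1 - p) * dmvn2(bh, S10)
  prec10 <- n + 1 / s2
  comp[[1]] <- c(mean = n * bh[1] / prec10, sd = sqrt(1 / prec10), w = NA)
  # config 01: beta1 = 0
  S01 <- Sn + s2 * (R %*% e2) %*% t(R %*% e2)
  w[3] <- (1 - p) * p * dmvn2(bh, S01)
  # config 11: joint slab; marginal of beta1
  S11 <- Sn + s2 * (R %*% R)
  w[4] <- p^2 * dmvn2(bh, S11)
  postP <- solve(n * R + diag(2) / s2)
  mu11 <- as.numeric(postP %*% (n * bh))
  comp[[2]] <- c(mean = mu11[1], sd = sqrt(postP[1, 1]), w = NA)
  w <- w / sum(w)
  function(x) {
    w[1] * (x >= 0) + w[3] * (x >= 0) +
      w[2] * pnorm(x, comp[[1]]["mean"], comp[[1]]["sd"]) +
      w[4] * pnorm(x, comp[[2]]["mean"], comp[[2]]["sd"])
  }
}
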