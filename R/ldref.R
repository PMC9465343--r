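#' Build a windowed sparse LD matrix
#'
#' Pearson correlations between all variant pairs closer than `window_cm`
#' centimorgans; exact zeros outside the window (variants further apart are
#' assumed uncorrelated), unit diagonal.  Monomorphic variants keep only
#' their diagonal entry and are flagged.
#'
#' @param x a genotype/dosage panel or a numeric matrix (>= 2 individuals).
#' @param pos_cm genetic positions (cM), non-decreasing; taken from the
#'   panel when `x` is one.
#' @param window_cm window width in cM (default 3); 0 gives the identity.
#' @return A list of class `"ld_matrix"`: `R` (symmetric `dgCMatrix` with
#'   stored diagonal), `pos_cm`, `window_cm`, `blocks` (NULL until
#'   [apply_blocks()]), `shrink` (1 until [shrink_offdiag()]),
#'   `monomorphic` flags.
#' @export
build_ld <- function(x, pos_cm = NULL, window_cm = 3) {
  X <- if (is.matrix(x)) x else if (inherits(x, "dosage_panel")) x$D else x$G
  if (is.null(pos_cm)) {
    if (is.matrix(x)) stop("pos_cm needed when x is a plain matrix")
    pos_cm <- x$pos_cm
  }
  n <- nrow(X); m <- ncol(X)
  if (n < 2) stop("need at least 2 individuals")
  if (is.unsorted(pos_cm)) stop("pos_cm must be non-decreasing")

  sds <- sqrt(matrixStats_colVars(X))
  mono <- sds == 0
  Xs <- sweep(X, 2, colMeans(X), "-")
  sds_safe <- ifelse(mono, 1, sds)
  Xs <- sweep(Xs, 2, sds_safe * sqrt(n - 1), "/")
  C <- crossprod(Xs)               # dense correlations (m kept moderate)
  diag(C) <- 1

  lo <- pmin(findInterval(pos_cm - window_cm, pos_cm) + 1L, seq_len(m))
  hi <- pmax(findInterval(pos_cm + window_cm, pos_cm), seq_len(m))
  ii <- jj <- vector("list", m)
  for (j in seq_len(m)) {
    rng <- if (mono[j]) j else setdiff2(lo[j], hi[j], mono, j)
    ii[[j]] <- rng
    jj[[j]] <- rep.int(j, length(rng))
  }
  i_all <- unlist(ii); j_all <- unlist(jj)
  R <- Matrix::sparseMatrix(i = i_all, j = j_all,
                            x = C[cbind(i_all, j_all)], dims = c(m, m))
  R <- methods::as(R, "generalMatrix")

  structure(list(R = R, pos_cm = pos_cm, window_cm = window_cm,
                 blocks = NULL, shrink = 1, monomorphic = mono),
            class = "ld_matrix")
}

# in-window row range for column j, dropping monomorphic partners
setdiff2 <- function(lo, hi, mono, j) {
  rng <- lo:hi
  rng[!mono[rng] | rng == j]
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf(
    "<ld_matrix> %d variants, window %.2g cM, %s stored entries%s%s\n",
    length(x$pos_cm), x$window_cm, format(length(x$R@x), big.mark = ","),
    if (!is.null(x$blocks)) sprintf(", %d blocks", max(x$blocks)) else "",
    if (x$shrink != 1) sprintf(", shrink %.2f", x$shrink) else ""))
  invisible(x)
}

upper_pairs <- function(ld) {
  Tm <- methods::as(ld$R, "TsparseMatrix")
  keep <- Tm@i < Tm@j
  list(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L, r2 = Tm@x[keep]^2)
}

#' Split an LD matrix into nearly independent blocks
#'
#' Exact dynamic program over contiguous split points minimizing
#' `weight * C2 + C1`, where `C1` is the sum of squared correlations outside
#' the blocks and `C2` the sum of squared block sizes (the printed default
#' weight is 5).  `max_r2` adds the constraint that no single squared
#' correlation outside blocks may exceed it: boundaries crossed by a
#' stronger pair are forbidden, which both guarantees split quality and
#' prunes the search.  Infeasible settings return `feasible = FALSE` with
#' the binding pair, not an error.
#'
#' @param ld an [build_ld()] matrix.
#' @param max_block_size maximum variants per block (default: no bound).
#' @param n_blocks_range optional `c(min, max)` number of blocks; `NULL`
#'   leaves the count free (faster).
#' @param max_r2 maximum squared correlation allowed outside blocks
#'   (default 1 = no constraint).
#' @param weight objective weight on `C2` (default 5).  The two components
#'   are always reported so users can re-weight.
#' @return A list of class `"block_split"`: `boundaries` (block end
#'   indices), `sizes`, `n_blocks`, `C1`, `C2`, `cost`, `weight`, `max_r2`,
#'   `feasible`, `binding_pair`.
#' @export
split_blocks <- function(ld, max_block_size = NULL, n_blocks_range = NULL,
                         max_r2 = 1, weight = 5) {
  m <- length(ld$pos_cm)
  if (is.null(max_block_size)) max_block_size <- m
  if (max_block_size < 1) stop("max_block_size must be >= 1")
  up <- upper_pairs(ld)

  # boundaries crossed by a pair with r2 > max_r2 are forbidden
  cross_cnt <- numeric(m)          # difference array over boundaries 1..m-1
  strong <- up$r2 > max_r2
  if (any(strong)) {
    for (k in which(strong)) {
      cross_cnt[up$i[k]] <- cross_cnt[up$i[k]] + 1
      cross_cnt[up$j[k]] <- cross_cnt[up$j[k]] - 1
    }
  }
  allowed <- c(cumsum(cross_cnt)[seq_len(max(m - 1, 0))] == 0, TRUE)

  # g[i] = sum_{j > b} r2_ij, maintained as the boundary b advances
  row_up <- numeric(m)             # initial: all j > i
  for (k in seq_along(up$i)) row_up[up$i[k]] <- row_up[up$i[k]] + up$r2[k]
  by_j <- split(seq_along(up$j), factor(up$j, levels = seq_len(m)))

  kconstr <- !is.null(n_blocks_range)
  kmax <- if (kconstr) min(n_blocks_range[2], m) else 1L
  INF <- Inf
  if (kconstr) {
    f <- matrix(INF, kmax + 1, m + 1); f[1, 1] <- 0
    prev <- array(0L, dim = c(kmax + 1, m + 1))
  } else {
    f <- rep(INF, m + 1); f[1] <- 0
    prev <- integer(m + 1)
  }

  g <- row_up
  for (b in seq_len(m)) {
    ids <- by_j[[b]]
    if (length(ids)) for (k in ids) g[up$i[k]] <- g[up$i[k]] - up$r2[k]
    # g[i] now equals sum_{j > b} r2_ij for every i <= b
    a_lo <- max(0L, b - max_block_size)
    if (b < m && !allowed[b]) next
    a_cand <- a_lo:(b - 1L)
    ok <- a_cand == 0L
    ok[!ok] <- allowed[a_cand[!ok]]
    a_cand <- a_cand[ok]
    if (!length(a_cand)) next
    sfx <- rev(cumsum(rev(g[(a_lo + 1L):b])))   # sum of g over (a, b]
    blk_cost <- weight * (b - a_cand)^2 + sfx[a_cand - a_lo + 1L]
    if (kconstr) {
      for (k in seq_len(kmax)) {
        tot <- f[k, a_cand + 1] + blk_cost
        best <- which.min(tot)
        if (length(best) && tot[best] < f[k + 1, b + 1]) {
          f[k + 1, b + 1] <- tot[best]
          prev[k + 1, b + 1] <- a_cand[best]
        }
      }
    } else {
      tot <- f[a_cand + 1] + blk_cost
      best <- which.min(tot)
      if (length(best) && tot[best] < f[b + 1]) {
        f[b + 1] <- tot[best]
        prev[b + 1] <- a_cand[best]
      }
    }
  }

  if (kconstr) {
    ks <- n_blocks_range[1]:min(n_blocks_range[2], m)
    vals <- f[ks + 1, m + 1]
    if (all(!is.finite(vals)))
      return(infeasible_split(up, max_r2, weight, m))
    kbest <- ks[which.min(vals)]
    boundaries <- integer(kbest); b <- m
    for (k in rev(seq_len(kbest))) {
      boundaries[k] <- b
      b <- prev[k + 1, b + 1]
    }
  } else {
    if (!is.finite(f[m + 1]))
      return(infeasible_split(up, max_r2, weight, m))
    boundaries <- integer(0); b <- m
    while (b > 0) { boundaries <- c(b, boundaries); b <- prev[b + 1] }
  }

  sizes <- diff(c(0L, boundaries))
  blocks <- rep.int(seq_along(sizes), sizes)
  C1 <- sum(up$r2[blocks[up$i] != blocks[up$j]])
  C2 <- sum(sizes^2)
  structure(list(boundaries = boundaries, sizes = sizes,
                 n_blocks = length(sizes), C1 = C1, C2 = C2,
                 cost = weight * C2 + C1, weight = weight, max_r2 = max_r2,
                 feasible = TRUE, binding_pair = NULL),
            class = "block_split")
}

infeasible_split <- function(up, max_r2, weight, m) {
  strong <- which(up$r2 > max_r2)
  binding <- if (length(strong)) {
    k <- strong[which.max(up$j[strong] - up$i[strong])]
    c(i = up$i[k], j = up$j[k], r2 = up$r2[k])
  } else NULL
  structure(list(boundaries = NULL, sizes = NULL, n_blocks = NA_integer_,
                 C1 = NA_real_, C2 = NA_real_, cost = NA_real_,
                 weight = weight, max_r2 = max_r2,
                 feasible = FALSE, binding_pair = binding),
            class = "block_split")
}

#' @export
print.block_split <- function(x, ...) {
  if (!x$feasible) {
    cat("<block_split> infeasible; binding pair:",
        paste(names(x$binding_pair), signif(x$binding_pair, 3),
              sep = "=", collapse = " "), "\n")
  } else {
    cat(sprintf("<block_split> %d blocks (sizes %s), C1 = %.4g, C2 = %g, cost = %.4g\n",
                x$n_blocks, paste(x$sizes, collapse = "/"), x$C1, x$C2, x$cost))
  }
  invisible(x)
}

#' Zero all LD entries crossing block boundaries
#'
#' Returns an LD matrix with independent blocks: entries between variants in
#' different blocks are removed, which prevents small errors in iterative
#' solvers from propagating across the genome.  Idempotent.
#'
#' @param ld an [build_ld()] matrix.
#' @param split a feasible [split_blocks()] result (or an integer vector of
#'   block ids, one per variant).
#' @return The blocked `"ld_matrix"`, with `blocks` set and the fraction of
#'   stored non-zeros kept in attribute-field `kept_fraction`.
#' @export
apply_blocks <- function(ld, split) {
  m <- length(ld$pos_cm)
  blocks <- if (inherits(split, "block_split")) {
    if (!split$feasible) stop("cannot apply an infeasible split")
    rep.int(seq_along(split$sizes), split$sizes)
  } else as.integer(split)
  if (length(blocks) != m) stop("split does not cover the matrix")

  Tm <- methods::as(ld$R, "TsparseMatrix")
  keep <- blocks[Tm@i + 1L] == blocks[Tm@j + 1L]
  nnz_before <- length(Tm@x)
  R2 <- Matrix::sparseMatrix(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L,
                             x = Tm@x[keep], dims = c(m, m))
  out <- ld
  out$R <- methods::as(R2, "generalMatrix")
  out$blocks <- blocks
  out$kept_fraction <- sum(keep) / nnz_before
  out
}

#' Shrink off-diagonal LD entries
#'
#' Multiplies every off-diagonal entry by `c`, leaving the unit diagonal
#' untouched -- i.e. replaces `R` by `c R + (1 - c) I`, raising the minimum
#' eigenvalue by `(1 - c)(1 - lambda_min(R))`.  `c = 1` is the identity
#' transformation and `c = 0` the identity matrix.  Used as sampler
#' regularization ("shrink_corr").
#'
#' @param ld an [build_ld()] matrix.
#' @param c shrink factor in \[0, 1\].
#' @return The shrunk `"ld_matrix"` (cumulative factor recorded in
#'   `$shrink`).
#' @export
shrink_offdiag <- function(ld, c) {
  if (c < 0 || c > 1) stop("shrink factor must be in [0, 1]")
  Tm <- methods::as(ld$R, "TsparseMatrix")
  x <- ifelse(Tm@i == Tm@j, Tm@x, Tm@x * c)
  R2 <- Matrix::sparseMatrix(i = Tm@i + 1L, j = Tm@j + 1L, x = x,
                             dims = dim(ld$R))
  R2 <- Matrix::drop0(R2)
  out <- ld
  out$R <- methods::as(R2, "generalMatrix")
  out$shrink <- ld$shrink * c
  out
}

#' LD scores
#'
#' `l_j = sum_k r2_jk` over stored entries, including the diagonal 1.
#'
#' @param ld an [build_ld()] matrix.
#' @return Numeric vector of LD scores.
#' @export
ld_scores <- function(ld) {
  as.numeric(Matrix::colSums(ld$R^2))
}

# ---- compact on-disk sparse format (.sfbm) ---------------------------------
#
# Little-endian layout:
#   bytes 0-3   magic "SFBM"
#   bytes 4-7   version (uint32, currently 1)
#   bytes 8-15  M, number of columns (uint64)
#   then M column records: i0 (uint64, 1-based first stored row, 0 = empty),
#        L (uint64, run length), L doubles (the contiguous values, interior
#        zeros stored explicitly)
#   then an offset table: M uint64 byte offsets (from file start) to each
#        column record, enabling random column access.

write_u64 <- function(con, v) {
  # values < 2^31 written as (lo, hi=0) uint32 pair = little-endian uint64
  writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
}

read_u64 <- function(con) {
  lo <- readBin(con, "integer", 1, size = 4, endian = "little")
  hi <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(lo) == 0) stop("sfbm: truncated file")
  lo + hi * 2^32
}

#' Write / read the compact sparse LD format
#'
#' On-disk sparse-matrix format that exploits the (near-)contiguity of
#' windowed LD columns: per column only the first stored row index and the
#' contiguous run of values up to the last non-zero are kept, plus a
#' trailing offset table for random column access.  On long runs this is
#' about twice as compact as a classic (index, value) sparse-column layout.
#' `sfbm_read(sfbm_write(x))` is bit-identical.  A sidecar JSON
#' (`<path>.json`) carries M, the window, genetic positions and a variant
#' checksum.
#'
#' @param ld an [build_ld()] matrix.
#' @param path file path (conventionally `.sfbm`).
#' @return `sfbm_write`: `path`, invisibly.  `sfbm_read`: the
#'   `"ld_matrix"`.  `sfbm_read_column`: one dense numeric column.
#' @export
sfbm_write <- function(ld, path) {
  R <- ld$R
  m <- ncol(R)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SFBM"), con)
  writeBin(1L, con, size = 4, endian = "little")
  write_u64(con, m)
  offsets <- numeric(m)
  p <- R@p; i <- R@i; x <- R@x
  pos <- 16
  for (j in seq_len(m)) {
    offsets[j] <- pos
    k <- if (p[j] < p[j + 1]) (p[j] + 1):p[j + 1] else integer(0)
    if (length(k) == 0) {
      write_u64(con, 0); write_u64(con, 0)
      pos <- pos + 16
    } else {
      rows <- i[k] + 1L
      i0 <- rows[1]; iL <- rows[length(rows)]
      run <- numeric(iL - i0 + 1)
      run[rows - i0 + 1] <- x[k]       # interior zeros explicit
      write_u64(con, i0); write_u64(con, length(run))
      writeBin(run, con, size = 8, endian = "little")
      pos <- pos + 16 + 8 * length(run)
    }
  }
  for (j in seq_len(m)) write_u64(con, offsets[j])

  meta <- list(M = m, window_cm = ld$window_cm, pos_cm = ld$pos_cm,
               shrink = ld$shrink, blocks = ld$blocks,
               checksum = sfbm_checksum(ld$pos_cm))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sfbm_checksum <- function(pos_cm) {
  sum(round(pos_cm * 1e6) %% 97003) %% 2147483647
}

sfbm_open <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "SFBM")) {
    close(con); stop("sfbm: bad magic at byte offset 0")
  }
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(ver, 1L)) {
    close(con); stop("sfbm: unsupported version at byte offset 4")
  }
  m <- read_u64(con)
  sz <- file.size(path)
  seek(con, sz - 8 * m)
  offsets <- vapply(seq_len(m), function(j) read_u64(con), numeric(1))
  list(con = con, m = m, offsets = offsets)
}

#' @rdname sfbm_write
#' @export
sfbm_read <- function(path) {
  h <- sfbm_open(path)
  on.exit(close(h$con))
  ii <- jj <- xx <- vector("list", h$m)
  for (j in seq_len(h$m)) {
    seek(h$con, h$offsets[j])
    i0 <- read_u64(h$con); L <- read_u64(h$con)
    if (L > 0) {
      run <- readBin(h$con, "double", L, size = 8, endian = "little")
      if (length(run) < L) stop("sfbm: truncated column at byte offset ",
                                h$offsets[j])
      ii[[j]] <- i0:(i0 + L - 1)
      jj[[j]] <- rep.int(j, L)
      xx[[j]] <- run
    }
  }
  R <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(h$m, h$m))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(R = methods::as(R, "generalMatrix"),
                 pos_cm = meta$pos_cm, window_cm = meta$window_cm,
                 blocks = meta$blocks, shrink = meta$shrink,
                 monomorphic = NULL),
            class = "ld_matrix")
}

#' @rdname sfbm_write
#' @param j column index (1-based) for random access.
#' @export
sfbm_read_column <- function(path, j) {
  h <- sfbm_open(path)
  on.exit(close(h$con))
  if (j < 1 || j > h$m) stop("column out of range")
  seek(h$con, h$offsets[j])
  i0 <- read_u64(h$con); L <- read_u64(h$con)
  col <- numeric(h$m)
  if (L > 0)
    col[i0:(i0 + L - 1)] <- readBin(h$con, "double", L, size = 8,
                                    endian = "little")
  col
}

#' Export / import an LD matrix as Matrix Market
#'
#' Interop with other tools: `.mtx` holds the sparse correlations; genetic
#' positions travel in a TSV alongside (`<path>.pos.tsv`).
#'
#' @param ld an [build_ld()] matrix.
#' @param path the `.mtx` path.
#' @export
ld_export_mtx <- function(ld, path) {
  Matrix::writeMM(methods::as(ld$R, "CsparseMatrix"), path)
  write.table(data.frame(pos_cm = ld$pos_cm, window_cm = ld$window_cm),
              paste0(path, ".pos.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname ld_export_mtx
#' @export
ld_import_mtx <- function(path) {
  R <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  meta <- read.delim(paste0(path, ".pos.tsv"))
  structure(list(R = methods::as(R, "generalMatrix"), pos_cm = meta$pos_cm,
                 window_cm = meta$window_cm[1], blocks = NULL, shrink = 1,
                 monomorphic = NULL),
            class = "ld_matrix")
}
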