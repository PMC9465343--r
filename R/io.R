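#' Read / write summary statistics as TSV
#'
#' The native dialect has columns `chr, pos, a0, a1, beta, beta_se` and
#' optionally `freq, info, n` (or `n_eff`), `n_cases, n_controls`.  A
#' column mapping translates external headers (e.g.
#' `c(beta = "b", beta_se = "se")` means the file calls them `b`/`se`).
#' Gzip is read transparently; missing values may be empty or `NA`.
#' Binary traits given per-variant `n_cases`/`n_controls` are converted to
#' the effective-sample-size scale at ingestion.
#'
#' @param path TSV path (optionally `.gz`).
#' @param mapping named character vector, standard name -> file header.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param N total (effective) sample size; inferred from `n` when absent.
#' @return A [sumstats] table.
#' @export
read_sumstats <- function(path, mapping = NULL,
                          trait_type = c("quantitative", "binary"),
                          N = NULL) {
  trait_type <- match.arg(trait_type)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = NA, na.strings = c("NA", ""))
  if (!is.null(mapping)) {
    missing_cols <- setdiff(unname(mapping), names(df))
    if (length(missing_cols))
      stop("cli_validation: mapped column(s) not in file: ",
           paste(missing_cols, collapse = ", "),
           "; available: ", paste(names(df), collapse = ", "),
           call. = FALSE)
    for (std in names(mapping)) names(df)[names(df) == mapping[[std]]] <- std
  }
  req <- c("chr", "pos", "a0", "a1", "beta", "beta_se")
  if (!all(req %in% names(df)))
    stop("cli_validation: missing required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "), call. = FALSE)
  n <- df$n %||% df$n_eff
  if (is.null(n) && !is.null(df$n_cases) && !is.null(df$n_controls))
    n <- ifelse(df$n_cases == 0 | df$n_controls == 0, 0,
                4 / (1 / df$n_cases + 1 / df$n_controls))
  sumstats(chr = df$chr, pos = df$pos, a0 = df$a0, a1 = df$a1,
           beta = df$beta, beta_se = df$beta_se, n = n,
           freq = df$freq, info = df$info,
           N = N %||% (if (!is.null(n)) max(n, na.rm = TRUE) else NULL),
           trait_type = trait_type)
}

#' @rdname read_sumstats
#' @param stats a [sumstats] table.
#' @export
write_sumstats <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Compute polygenic scores
#'
#' `score_i = sum_j effect_j x_ij` on the effect-allele dosage scale.
#'
#' @param x genotype/dosage panel or matrix (individuals x variants).
#' @param effects per-allele effect vector (or matrix, one score per
#'   column).
#' @return Numeric vector (or matrix) of individual scores.
#' @export
score_pgs <- function(x, effects) {
  X <- if (is.matrix(x)) x else if (inherits(x, "dosage_panel")) x$D else x$G
  if (NROW(effects) != ncol(X)) stop("effects length must match variants")
  unname(X %*% as.matrix(effects))
}
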