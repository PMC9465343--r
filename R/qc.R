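#' QC thresholds
#'
#' Threshold bundle for [qc_extended()].  Defaults: INFO >= 0.4, allele
#' frequency difference vs the reference <= 0.1, per-variant sample size
#' >= 70% of the maximum, no MAF floor, and two default excluded regions --
#' the long-range LD regions chr6:25-33.5 Mbp and chr8:8-12 Mbp
#' (coordinates 1-based, inclusive at both ends).
#'
#' @param info_min minimum INFO score.
#' @param maf_min minimum minor allele frequency (0 disables).
#' @param freq_diff_max maximum |f_stats - f_ref|.
#' @param n_frac_min minimum `n_j / max_k(n_k)`.
#' @param excluded_regions data.frame with columns `chr`, `start`, `end`
#'   (bp, 1-based inclusive); user-extensible.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(info_min = 0.4, maf_min = 0, freq_diff_max = 0.1,
                          n_frac_min = 0.7,
                          excluded_regions = default_excluded_regions()) {
  stopifnot(info_min >= 0, info_min <= 1, maf_min >= 0, maf_min <= 0.5,
            freq_diff_max >= 0, n_frac_min >= 0, n_frac_min <= 1)
  if (!is.null(excluded_regions)) {
    stopifnot(all(c("chr", "start", "end") %in% names(excluded_regions)),
              all(excluded_regions$start <= excluded_regions$end))
  }
  structure(list(info_min = info_min, maf_min = maf_min,
                 freq_diff_max = freq_diff_max, n_frac_min = n_frac_min,
                 excluded_regions = excluded_regions),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @export
default_excluded_regions <- function() {
  data.frame(chr = c(6L, 8L), start = c(25e6, 8e6), end = c(33.5e6, 12e6))
}

qc_report <- function(flags, extra = list()) {
  counts <- vapply(flags, sum, integer(1))
  structure(c(list(flags = as.data.frame(flags), counts = counts), extra),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", nrow(x$flags), "variants\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Match summary statistics to a reference variant table
#'
#' Joins on (chr, pos) -- not rsID, which drifts across builds -- and
#' reconciles alleles: exact (a0, a1) matches pass; swapped alleles are
#' flipped (`beta <- -beta`, `freq <- 1 - freq`) and flagged; palindromic
#' A/T and C/G variants are flagged strand-ambiguous and removed by default;
#' unmatched or allele-incompatible variants are dropped with counts.
#' Flipping twice restores the input (involution).
#'
#' @param stats a [sumstats] table.
#' @param reference data.frame with `chr`, `pos`, `a0`, `a1` and optionally
#'   `freq` (same 1-based coordinate convention).
#' @param keep_ambiguous keep palindromic variants (default drop).
#' @return A list: `stats` (aligned, in reference order) and `report`
#'   (a `"qc_report"` with flags matched / allele_flipped /
#'   strand_ambiguous / incompatible on the reference rows).
#' @export
match_alleles <- function(stats, reference, keep_ambiguous = FALSE) {
  key_s <- paste(stats$chr, stats$pos)
  key_r <- paste(reference$chr, reference$pos)
  if (anyDuplicated(key_s))
    stop("duplicated positions in stats: ",
         paste(head(key_s[duplicated(key_s)]), collapse = ", "))
  if (anyDuplicated(key_r))
    stop("duplicated positions in reference: ",
         paste(head(key_r[duplicated(key_r)]), collapse = ", "))

  idx <- match(key_r, key_s)
  hit <- !is.na(idx)
  s <- stats[idx[hit], , drop = FALSE]
  r <- reference[hit, , drop = FALSE]

  same <- s$a0 == r$a0 & s$a1 == r$a1
  swap <- s$a0 == r$a1 & s$a1 == r$a0
  ambiguous <- COMPLEMENT[s$a0] == s$a1
  compatible <- (same | swap) & !is.na(ambiguous)

  out <- s
  fl <- swap & compatible
  out$beta[fl] <- -out$beta[fl]
  if (!is.null(out$freq)) out$freq[fl] <- 1 - out$freq[fl]
  tmp <- out$a0[fl]; out$a0[fl] <- out$a1[fl]; out$a1[fl] <- tmp

  keep <- compatible & (keep_ambiguous | !ambiguous)
  flags <- list(matched = hit,
                allele_flipped = replace(logical(nrow(reference)),
                                         which(hit)[fl], TRUE),
                strand_ambiguous = replace(logical(nrow(reference)),
                                           which(hit)[ambiguous %in% TRUE],
                                           TRUE),
                incompatible = replace(logical(nrow(reference)),
                                       which(hit)[!compatible], TRUE))
  out <- out[keep, , drop = FALSE]
  attr(out, "N") <- attr(stats, "N")
  attr(out, "trait_type") <- attr(stats, "trait_type")
  class(out) <- class(stats)
  list(stats = out, report = qc_report(flags))
}

#' Standard-deviation outlier rule (default constants)
#'
#' The default sd-comparison rule, shipped as configuration (the constants
#' come from established prior practice): flag when
#' `sd_ss < 0.5 sd_af`, or `sd_ss > sd_af + 0.1`, or `sd_ss < 0.1`, or
#' `sd_af < 0.05` (this last arm effectively filters on MAF).
#'
#' @param ratio_min,diff_max,sd_ss_min,sd_af_min the four constants.
#' @return A list of class `"qc_sd_rule"`.
#' @export
qc_sd_rule <- function(ratio_min = 0.5, diff_max = 0.1,
                       sd_ss_min = 0.1, sd_af_min = 0.05) {
  structure(list(ratio_min = ratio_min, diff_max = diff_max,
                 sd_ss_min = sd_ss_min, sd_af_min = sd_af_min),
            class = "qc_sd_rule")
}

#' Standard-deviation comparison QC ("qc1")
#'
#' Compares genotype standard deviations inferred from the summary
#' statistics (`sd_ss`, INFO-adjusted upstream when INFO is available, i.e.
#' divided by sqrt(INFO)) with those expected from allele frequencies
#' (`sd_af`), flagging outliers under the pinned rule.  Underestimated
#' `sd_ss` typically indicates overestimated per-variant sample sizes or
#' uncorrected imputation; the `sd_af` floor removes very rare variants.
#'
#' @param sd_af,sd_ss aligned sd vectors.
#' @param rule a [qc_sd_rule()].
#' @return A `"qc_report"` with flag `sd_outlier` and the sd pairs used.
#' @export
qc_sd_filter <- function(sd_af, sd_ss, rule = qc_sd_rule()) {
  if (length(sd_af) != length(sd_ss)) stop("length mismatch")
  out <- sd_ss < rule$ratio_min * sd_af |
         sd_ss > sd_af + rule$diff_max |
         sd_ss < rule$sd_ss_min |
         sd_af < rule$sd_af_min
  out[is.na(out)] <- TRUE
  qc_report(list(sd_outlier = out),
            list(sd_af = sd_af, sd_ss = sd_ss, rule = rule))
}

#' Extended variant filters ("qc2")
#'
#' Applies, in order and each recorded separately: INFO >= `info_min`;
#' allele-frequency difference vs the reference <= `freq_diff_max`;
#' position outside the excluded (long-range LD) regions; per-variant
#' sample size >= `n_frac_min` of the maximum; MAF >= `maf_min`.
#' Idempotent: the kept set passes all filters again unchanged.
#'
#' @param stats a [sumstats] table.
#' @param ref_freq reference allele frequencies aligned with `stats` (for
#'   the frequency-difference filter; `NULL` skips it).
#' @param thresholds a [qc_thresholds()].
#' @return A `"qc_report"` with per-rule flags (`low_info`,
#'   `freq_mismatch`, `in_excluded_region`, `low_n`, `low_maf`) and the
#'   combined `keep` vector.
#' @export
qc_extended <- function(stats, ref_freq = NULL, thresholds = qc_thresholds()) {
  m <- nrow(stats)
  th <- thresholds

  low_info <- if (!is.null(stats$info)) {
    !is.na(stats$info) & stats$info < th$info_min
  } else logical(m)

  freq_mismatch <- if (!is.null(ref_freq) && !is.null(stats$freq)) {
    abs(stats$freq - ref_freq) > th$freq_diff_max
  } else logical(m)
  freq_mismatch[is.na(freq_mismatch)] <- FALSE

  in_region <- logical(m)
  if (!is.null(th$excluded_regions)) {
    for (k in seq_len(nrow(th$excluded_regions))) {
      rg <- th$excluded_regions[k, ]
      in_region <- in_region |
        (stats$chr == rg$chr & stats$pos >= rg$start & stats$pos <= rg$end)
    }
  }

  nmax <- max(stats$n, na.rm = TRUE)
  low_n <- !is.na(stats$n) & stats$n < th$n_frac_min * nmax

  low_maf <- if (!is.null(stats$freq)) {
    maf <- pmin(stats$freq, 1 - stats$freq)
    !is.na(maf) & maf < th$maf_min
  } else logical(m)

  flags <- list(low_info = low_info, freq_mismatch = freq_mismatch,
                in_excluded_region = in_region, low_n = low_n,
                low_maf = low_maf)
  keep <- !Reduce(`|`, flags)
  if (!any(keep)) warning("qc_extended removed every variant")
  qc_report(flags, list(keep = keep, thresholds = th))
}

#' Plot-ready sd-comparison table
#'
#' Emits one row per variant with `sd_af`, raw `sd_ss`, INFO-adjusted
#' `sd_ss / sqrt(info)`, and the sd-outlier flag, plus the two regression
#' slopes (raw and adjusted, through the origin) as attributes.  Rendering
#' is left to the caller.
#'
#' @param sd_af,sd_ss aligned sd vectors.
#' @param info INFO scores (default 1).
#' @param rule a [qc_sd_rule()] used for the flag.
#' @return A data.frame with attributes `slope_raw`, `slope_adjusted`.
#' @export
qc_plot_data <- function(sd_af, sd_ss, info = NULL, rule = qc_sd_rule()) {
  if (is.null(info)) info <- rep(1, length(sd_af))
  stopifnot(length(sd_af) == length(sd_ss), length(info) == length(sd_af))
  adj <- sd_ss / sqrt(info)
  flag <- if (length(sd_af)) qc_sd_filter(sd_af, adj, rule)$flags$sd_outlier
          else logical(0)
  out <- data.frame(sd_af = sd_af, sd_ss_raw = sd_ss,
                    sd_ss_info_adjusted = adj, flag = flag)
  slope <- function(yv) {
    ok <- is.finite(sd_af) & is.finite(yv)
    if (sum(ok) < 2) return(NA_real_)
    sum(sd_af[ok] * yv[ok]) / sum(sd_af[ok]^2)
  }
  attr(out, "slope_raw") <- slope(sd_ss)
  attr(out, "slope_adjusted") <- slope(adj)
  out
}

#' Serialize a QC report
#'
#' Writes one row per variant with one column per flag to TSV, plus a JSON
#' summary of the counts (and thresholds when present).
#'
#' @param report a `"qc_report"`.
#' @param prefix output path prefix (`.tsv` and `.json` appended).
#' @export
write_qc_report <- function(report, prefix) {
  write.table(report$flags, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(counts = as.list(report$counts),
                            thresholds = report$thresholds),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(prefix)
}
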