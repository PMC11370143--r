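#' Library sizes
#'
#' Total reads per sample, `R_i = sum_g r_gi`.
#'
#' @param cm A [count_matrix].
#' @return Named numeric vector of positive library sizes.
#' @export
library_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  R <- colSums(cm$counts)
  if (any(R == 0))
    stop("sample(s) with zero reads: ",
         paste(cm$sample_ids[R == 0], collapse = ", "))
  R
}

# Upper-quartile of CPM for one sample; used only to pick the TMM reference.
.uq_cpm <- function(counts, lib) {
  apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
}

# Weighted trimmed mean of M-values between one sample and the reference.
# M: gene-wise log2 ratio of library-size-scaled counts; A: average log2
# abundance. Genes with zero counts in either sample are dropped (the log
# ratio is undefined), the extremes of M and A are trimmed, and the
# remaining M values are averaged with inverse delta-method binomial
# variance weights.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  p_obs <- obs / lib_obs
  p_ref <- ref / lib_ref
  ok <- obs > 0 & ref > 0
  if (sum(ok) < 2L) {
    warning("fewer than 2 genes usable for TMM; factor set to 1")
    return(1)
  }
  M <- log2(p_obs[ok] / p_ref[ok])
  A <- (log2(p_obs[ok]) + log2(p_ref[ok])) / 2
  v <- (lib_obs - obs[ok]) / (lib_obs * obs[ok]) +
       (lib_ref - ref[ok]) / (lib_ref * ref[ok])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (sum(keep) < 2L) {
    warning("fewer than 2 genes survive TMM trimming; factor set to 1")
    return(1)
  }
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' TMM scale-normalization factors
#'
#' Weighted trimmed mean of M-values: per-sample scale factors computed from
#' gene-wise log ratios against a reference sample (the sample whose
#' upper-quartile CPM is closest to the mean upper quartile), trimming the
#' most extreme `trim_m` of log-ratios and `trim_a` of average abundances,
#' and weighting the surviving log-ratios by inverse asymptotic (binomial)
#' variances. Factors are rescaled so their geometric mean is 1, so the
#' effective library sizes `R_i * factor_i` preserve the total scale.
#'
#' @param cm A [count_matrix] with at least two samples.
#' @param trim_m Fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A values trimmed from each tail (default 0.05).
#' @param ref_column Optional reference sample index; default chooses by the
#'   upper-quartile rule.
#' @return Named numeric vector of normalization factors, geometric mean 1.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, ref_column = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2L) stop("TMM requires at least 2 samples")
  R <- library_sizes(cm)
  if (is.null(ref_column)) {
    uq <- .uq_cpm(cm$counts, R)
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_along(R), function(i) {
    if (i == ref_column) return(.tmm_pair(cm$counts[, i], cm$counts[, ref_column],
                                          R[i], R[ref_column], trim_m, trim_a))
    .tmm_pair(cm$counts[, i], cm$counts[, ref_column], R[i], R[ref_column],
              trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- cm$sample_ids
  f
}

# log2 counts-per-million with the 0.5 count and 1.0 library-size offsets.
logcpm_matrix <- function(counts, lib_sizes) {
  t(log2(t(counts + 0.5) / (lib_sizes + 1) * 1e6))
}

#' Log2 counts-per-million
#'
#' `logCPM_gi = log2((r_gi + 0.5) / (R_i + 1.0) * 1e6)`; the 0.5 count
#' offset avoids log of zero, the 1.0 library-size offset keeps the value
#' finite even at r = R. Library sizes are normally the effective
#' (TMM-scaled) sizes.
#'
#' @param cm A [count_matrix].
#' @param lib_sizes Positive library sizes, one per sample; defaults to the
#'   raw column sums.
#' @return G x n matrix of log2-CPM values.
#' @export
logcpm <- function(cm, lib_sizes = library_sizes(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(lib_sizes) != ncol(cm$counts) || any(lib_sizes <= 0))
    stop("lib_sizes must be positive, one per sample")
  logcpm_matrix(cm$counts, lib_sizes)
}

#' Normalize a count matrix
#'
#' Computes raw library sizes, TMM normalization factors, effective library
#' sizes and the log2-CPM matrix on the effective sizes — the normalized
#' expression object consumed by PCA and by the precision-weighted linear
#' modelling.
#'
#' @param cm A [count_matrix].
#' @inheritParams tmm_factors
#' @param tmm Logical; set `FALSE` to skip scale normalization (all factors
#'   1, effective sizes = raw sizes).
#' @return An object of class `normalized_expression`: list with `logcpm`,
#'   `lib_sizes`, `norm_factors`, `effective_lib_sizes`.
#' @export
normalize_counts <- function(cm, trim_m = 0.30, trim_a = 0.05, tmm = TRUE) {
  R <- library_sizes(cm)
  nf <- if (tmm && ncol(cm$counts) >= 2L) tmm_factors(cm, trim_m, trim_a)
        else stats::setNames(rep(1, length(R)), cm$sample_ids)
  eff <- R * nf
  structure(list(logcpm = logcpm_matrix(cm$counts, eff),
                 lib_sizes = R, norm_factors = nf,
                 effective_lib_sizes = eff),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d genes x %d samples; norm factors in [%.3f, %.3f]\n",
              nrow(x$logcpm), ncol(x$logcpm), min(x$norm_factors), max(x$norm_factors)))
  invisible(x)
}
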