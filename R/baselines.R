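#' Complete-case differential expression
#'
#' Drops every sample with at least one missing cell in the model
#' covariates, then runs the single-dataset analysis chain (voom weights,
#' weighted least squares, empirical-Bayes moderation) with BH adjustment.
#'
#' @param cm A filtered [count_matrix].
#' @param cov A [covariate_table], possibly with missing cells.
#' @param spec A [design_spec].
#' @param fdr Significance threshold (default 0.05).
#' @param span LOWESS span for the mean-variance trend.
#' @return data.frame per gene: `gene_id`, `logFC`, `se`, `df`, `t`, `p`,
#'   `p_adj`, `significant`; attribute `n_used` gives the retained sample
#'   count.
#' @export
cc_analysis <- function(cm, cov, spec, fdr = 0.05, span = 0.5) {
  stopifnot(inherits(cov, "covariate_table"))
  keep <- !apply(cov$miss[, spec$terms, drop = FALSE], 1, any)
  p_design <- length(spec$terms) + 3L
  if (sum(keep) < p_design)
    stop("too few complete samples (", sum(keep), ") for the design")
  cm_cc <- count_matrix(cm$counts[, keep, drop = FALSE],
                        gene_ids = cm$gene_ids,
                        sample_ids = cm$sample_ids[keep])
  cov_cc <- cov
  cov_cc$data <- cov$data[keep, , drop = FALSE]
  cov_cc$miss <- cov$miss[keep, , drop = FALSE]
  cov_cc$sample_ids <- cov$sample_ids[keep]
  res <- run_de_single_dataset(cm_cc, cov_cc, spec, span = span)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < fdr
  attr(res, "n_used") <- sum(keep)
  res
}

# Iterative random-forest single imputation of a covariate data.frame.
# Missing cells are initialized with marginal mean/mode, then each target
# is repeatedly re-predicted from the other covariates until the change
# between sweeps stops decreasing (or max_iter is hit). Expression data is
# deliberately excluded from the predictor set: with a single completed
# dataset there is no between-imputation variance to absorb the
# outcome-driven correlation, so including the outcome would bias the
# subsequent tests.
.rf_impute <- function(df, miss, num_trees = 100, max_iter = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- colnames(df)[colSums(miss) > 0]
  for (v in targets) {
    idx <- which(miss[, v])
    if (is.numeric(df[[v]])) {
      df[[v]][idx] <- mean(df[[v]][!miss[, v]])
    } else {
      tab <- table(df[[v]][!miss[, v]])
      df[[v]][idx] <- names(tab)[which.max(tab)]
    }
  }
  prev_err <- Inf
  prev <- df
  for (it in seq_len(max_iter)) {
    for (v in targets) {
      obs <- !miss[, v]
      dat <- data.frame(.y = df[[v]][obs], df[obs, setdiff(colnames(df), v),
                                              drop = FALSE])
      fit <- ranger::ranger(.y ~ ., data = dat, num.trees = num_trees,
                            respect.unordered.factors = "order")
      nd <- data.frame(df[!obs, setdiff(colnames(df), v), drop = FALSE])
      pred <- stats::predict(fit, data = nd)$predictions
      df[[v]][!obs] <- pred
    }
    # normalized change in the imputed cells between successive sweeps
    err <- 0
    for (v in targets) {
      idx <- which(miss[, v])
      if (is.numeric(df[[v]])) {
        denom <- stats::var(df[[v]][idx])
        err <- err + if (denom > 0)
          sum((df[[v]][idx] - prev[[v]][idx])^2) / (denom * length(idx)) else 0
      } else {
        err <- err + mean(df[[v]][idx] != prev[[v]][idx])
      }
    }
    if (err >= prev_err) break
    prev_err <- err
    prev <- df
  }
  prev
}

#' Single-imputation differential expression
#'
#' Imputes the covariates once with an iterative nonparametric
#' (random-forest) procedure — covariates only, never the expression data —
#' then runs the single-dataset analysis chain with BH adjustment. Masked
#' (MNAR) variables are excluded from the imputer's view.
#'
#' @inheritParams cc_analysis
#' @param seed Integer seed for the forest imputation.
#' @param num_trees Trees per forest (default 100).
#' @param max_iter Maximum imputation sweeps (default 10).
#' @return data.frame as in [cc_analysis()]; the completed covariate table
#'   is attached as attribute `imputed`.
#' @export
si_analysis <- function(cm, cov, spec, fdr = 0.05, seed = NULL,
                        num_trees = 100, max_iter = 10, span = 0.5) {
  stopifnot(inherits(cov, "covariate_table"))
  visible <- setdiff(cov$schema$variable, cov$masked)
  df <- cov$data[, visible, drop = FALSE]
  miss <- cov$miss[, visible, drop = FALSE]
  if (any(colSums(miss) > 0)) {
    df <- .rf_impute(df, miss, num_trees = num_trees, max_iter = max_iter,
                     seed = seed)
  }
  cov_si <- cov
  cov_si$data[, visible] <- df
  cov_si$miss <- is.na(cov_si$data)
  res <- run_de_single_dataset(cm, cov_si, spec, span = span)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < fdr
  attr(res, "imputed") <- cov_si
  res
}
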