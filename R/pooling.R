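# Vectorized Rubin's-rules pooling. B and S are G x m matrices of
# coefficients and (moderated) standard errors; df_bar is the per-gene mean
# of the m moderated dfs. Returns a data.frame of all pooled quantities.
.pool_matrix <- function(B, S, df_bar, lambda_floor = 1e-12) {
  m <- ncol(B)
  beta_bar <- rowMeans(B)
  V_W <- rowMeans(S^2)
  V_B <- rowSums((B - beta_bar)^2) / (m - 1)
  V_T <- V_W + (1 + 1 / m) * V_B
  SE <- sqrt(V_T)
  tstat <- beta_bar / SE
  lambda <- (V_B + V_B / m) / V_T
  lam <- pmax(lambda, lambda_floor)
  df_old <- (m - 1) / lam^2
  df_obs <- ifelse(is.finite(df_bar),
                   (df_bar + 1) / (df_bar + 3) * df_bar * (1 - lambda),
                   Inf)
  df_adj <- 1 / (1 / df_old + 1 / df_obs)
  p <- 2 * stats::pt(-abs(tstat), df_adj)
  data.frame(logFC = beta_bar, V_W = V_W, V_B = V_B, V_Total = V_T,
             se_pooled = SE, t = tstat, lambda = lambda,
             df_old = df_old, df_observed = df_obs, df_adjusted = df_adj,
             p = p)
}

#' Pool one gene's results across imputations with Rubin's rules
#'
#' Combines the m per-imputation coefficients and standard errors: pooled
#' coefficient = mean of the betas; within-imputation variance
#' `V_W = mean(SE^2)`; between-imputation variance
#' `V_B = sum((beta - mean)^2)/(m-1)`; total variance
#' `V_Total = V_W + (1 + 1/m) V_B`, whose square root is the pooled SE;
#' `t = pooled beta / pooled SE`. The fraction of variance due to
#' missingness is `lambda = (V_B + V_B/m)/V_Total`; the Barnard-Rubin
#' small-sample degrees of freedom combine `df_old = (m-1)/lambda^2` with
#' `df_observed = (df+1)/(df+3) * df * (1-lambda)` (df being the mean
#' moderated df) harmonically:
#' `df_adjusted = df_old * df_observed / (df_old + df_observed)`. The
#' two-sided p-value is `2 * pt(-|t|, df_adjusted)`. At `lambda = 0` the
#' limit `df_old -> Inf` is taken, so `df_adjusted = df_observed`.
#'
#' @param betas Numeric vector of m coefficients (m >= 2).
#' @param ses Positive numeric vector of m standard errors.
#' @param df_bar Mean of the m moderated degrees of freedom.
#' @return One-row data.frame: `logFC`, `V_W`, `V_B`, `V_Total`,
#'   `se_pooled`, `t`, `lambda`, `df_old`, `df_observed`, `df_adjusted`,
#'   `p`.
#' @examples
#' rubins_pool(c(1, 2, 3), c(1, 1, 1), df_bar = 10)
#' @export
rubins_pool <- function(betas, ses, df_bar) {
  m <- length(betas)
  if (m < 2) stop("pooling requires m >= 2 imputations")
  if (length(ses) != m) stop("betas and ses must have the same length")
  if (any(ses <= 0)) stop("standard errors must be positive")
  .pool_matrix(matrix(betas, 1), matrix(ses, 1), df_bar)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegates to [stats::p.adjust()] after validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pool a stack of per-imputation gene fits
#'
#' Applies Rubin's-rules pooling gene by gene across the m per-imputation
#' fit tables (from [run_de_single_dataset()]), then adjusts the pooled
#' p-values for false-discovery-rate control across all genes.
#'
#' @param fits List of m data.frames with identical `gene_id` columns (same
#'   genes, same order) and columns `logFC`, `se`, `df`.
#' @param fdr Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return data.frame with one row per gene: `gene_id`, all
#'   [rubins_pool()] quantities, `p_adj` and `significant`.
#' @export
pool_all <- function(fits, fdr = 0.05) {
  m <- length(fits)
  if (m < 2) stop("pooling requires m >= 2 fit tables")
  ids <- fits[[1]]$gene_id
  for (k in seq_len(m))
    if (!identical(fits[[k]]$gene_id, ids))
      stop("gene sets/order differ between imputation fits")
  B <- vapply(fits, `[[`, numeric(length(ids)), "logFC")
  S <- vapply(fits, `[[`, numeric(length(ids)), "se")
  Dg <- vapply(fits, `[[`, numeric(length(ids)), "df")
  if (length(ids) == 1L) {
    B <- matrix(B, 1); S <- matrix(S, 1); Dg <- matrix(Dg, 1)
  }
  out <- .pool_matrix(B, S, rowMeans(Dg))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr
  cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), out)
}
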