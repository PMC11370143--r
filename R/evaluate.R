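#' Score method results against the full-data truth
#'
#' The truth set is the genes significant (FDR-adjusted p < `fdr`) in the
#' full-data model. For each method: the true positive rate is the
#' proportion of true DEGs the method also calls significant; the false
#' positive rate is the proportion of the method's significant calls that
#' are not true DEGs; the mean absolute percentage error is
#' `mean(|beta_truth - beta| / |beta_truth|)` over the true DEGs, where
#' `beta_truth` is the full-data coefficient.
#'
#' @param results_by_method Named list of per-gene result data.frames (each
#'   with `gene_id`, `logFC`, `significant`), e.g. from
#'   [run_mi_pca_pipeline()]`$results`, [cc_analysis()], [si_analysis()].
#' @param full_data_results Per-gene results of the full-data model (same
#'   columns, same gene universe).
#' @param fdr Truth-set significance threshold (default 0.05).
#' @return data.frame with one row per method: `method`, `TPR`, `FPR`,
#'   `MAPE`, `n_true`, `n_significant`, `fpr_flag` (TRUE when the method
#'   called nothing significant, making the FPR denominator empty; FPR is
#'   then reported as 0), `tpr_flag` (TRUE when the truth set is empty; TPR
#'   and MAPE are then NA).
#' @export
evaluate_methods <- function(results_by_method, full_data_results, fdr = 0.05) {
  full <- full_data_results
  if (!"significant" %in% names(full)) {
    full$p_adj <- bh_adjust(full$p)
    full$significant <- full$p_adj < fdr
  }
  truth <- full$gene_id[full$significant]
  beta_truth <- stats::setNames(full$logFC, full$gene_id)
  rows <- lapply(names(results_by_method), function(meth) {
    res <- results_by_method[[meth]]
    if (!setequal(res$gene_id, full$gene_id))
      stop("method '", meth, "' has a different gene universe than the full-data model")
    sig <- res$gene_id[res$significant & !is.na(res$significant)]
    tp <- length(intersect(sig, truth))
    fp <- length(setdiff(sig, truth))
    tpr_flag <- length(truth) == 0
    fpr_flag <- length(sig) == 0
    tpr <- if (tpr_flag) NA_real_ else tp / length(truth)
    fpr <- if (fpr_flag) 0 else fp / length(sig)
    mape <- if (tpr_flag) NA_real_ else {
      b <- stats::setNames(res$logFC, res$gene_id)[truth]
      mean(abs(beta_truth[truth] - b) / abs(beta_truth[truth]), na.rm = TRUE)
    }
    data.frame(method = meth, TPR = tpr, FPR = fpr, MAPE = mape,
               n_true = length(truth), n_significant = length(sig),
               tpr_flag = tpr_flag, fpr_flag = fpr_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
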