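#' Run the PCA-augmented multiple-imputation DE pipeline
#'
#' The full workflow on one dataset: low-count filtering, TMM/logCPM
#' normalization, principal-component selection on the expression matrix,
#' chained-equations multiple imputation of the covariates with the
#' retained PC scores in every predictor model, per-imputation
#' precision-weighted linear modelling with empirical-Bayes moderation, and
#' Rubin's-rules pooling with BH adjustment. With a complete covariate
#' table the m analyses are identical and pooling reduces to the
#' single-dataset analysis (zero between-imputation variance).
#'
#' @param cm A [count_matrix] (unfiltered; filtering is applied here).
#' @param cov A [covariate_table]; its `masked` field (set by MNAR
#'   amputation) is honoured by the imputer.
#' @param spec A [design_spec]; defaults to predictor + adjustment
#'   covariates.
#' @param m Number of imputed datasets (default 10).
#' @param n_iterations Chained-equation sweeps (default 10).
#' @param pc_criterion PC retention criterion, see [select_pcs()].
#' @param n_permutations,percentile,cutoff Criterion parameters.
#' @param count_target Low-count filter target (default 10); `NA` skips
#'   filtering.
#' @param fdr Significance threshold (default 0.05).
#' @param seed Integer seed covering PC selection and imputation.
#' @param span LOWESS span.
#' @return An object of class `mi_pca_result`: list with `results` (pooled
#'   per-gene table), `h`, `m`, `pc_selection`, `stack` diagnostics,
#'   `manifest` (every seed and parameter needed to re-run identically).
#' @export
run_mi_pca_pipeline <- function(cm, cov, spec = design_from_covariates(cov),
                                m = 10, n_iterations = 10,
                                pc_criterion = "horn", n_permutations = 50,
                                percentile = 0.95, cutoff = 0.80,
                                count_target = 10, fdr = 0.05, seed = NULL,
                                span = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cov, "covariate_table"))
  if (!identical(cm$sample_ids, cov$sample_ids))
    stop("count matrix and covariate table sample ids do not align")
  if (!is.null(seed)) set.seed(seed)
  cmf <- if (is.na(count_target)) cm else filter_low_counts(cm, count_target)
  norm <- normalize_counts(cmf)
  sel <- select_pcs(norm$logcpm, criterion = pc_criterion,
                    n_permutations = n_permutations, percentile = percentile,
                    cutoff = cutoff)
  pm <- build_predictor_matrix(cov, pcs = sel)
  if (length(pm$targets)) {
    stack <- impute_chained(cov, pm, m = m, n_iterations = n_iterations)
    tables <- stack$tables
    diag <- convergence_diagnostics(stack)
  } else {
    stack <- NULL
    tables <- replicate(m, cov, simplify = FALSE)
    diag <- data.frame()
  }
  fits <- lapply(tables, function(tbl)
    run_de_single_dataset(cmf, tbl, spec, norm = norm, span = span))
  pooled <- pool_all(fits, fdr = fdr)
  manifest <- list(seed = seed, m = m, n_iterations = n_iterations,
                   pc_criterion = pc_criterion,
                   n_permutations = n_permutations, percentile = percentile,
                   cutoff = cutoff, h = sel$h, count_target = count_target,
                   fdr = fdr, span = span, genes_analysed = nrow(cmf$counts),
                   targets = pm$targets, masked = cov$masked,
                   package_version = as.character(utils::packageVersion("seqMI")))
  structure(list(results = pooled, h = sel$h, m = m, pc_selection = sel,
                 diagnostics = diag, manifest = manifest),
            class = "mi_pca_result")
}

#' @export
print.mi_pca_result <- function(x, ...) {
  cat(sprintf("mi_pca_result: %d genes, m = %d imputations, h = %d retained PCs, %d significant (FDR < %.2g)\n",
              nrow(x$results), x$m, x$h, sum(x$results$significant),
              x$manifest$fdr))
  invisible(x)
}

# Deterministic per-cell seed derivation: adding grid cells never perturbs
# existing cells because each cell's seed depends only on the master seed
# and its own coordinates.
.cell_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 2654435761 + counter * 104729) %% 2147483647L) + 1L
}

#' Run the simulation benchmark grid
#'
#' Full factorial benchmark: for each replicate a synthetic dataset is
#' generated ([simulate_dataset()]), the full-data model defines the truth
#' set, the covariates are amputed under each mechanism at each missingness
#' level, each method is run, and TPR/FPR/MAPE are scored against the truth
#' set. Per-cell seeds are derived deterministically from `master_seed`.
#'
#' @param props Missingness levels (fractions of samples with >= 1 missing
#'   cell; default 0.55).
#' @param mechanisms Subset of `c("MCAR", "MAR", "MNAR")`.
#' @param methods Subset of `c("mi_pca", "mi_gene_bin", "cc", "si")`.
#' @param n_replicates Replicates per cell (default 10).
#' @param G,n,null_fraction,shape Passed to [simulate_dataset()].
#' @param m Imputations for the MI methods (default 10).
#' @param master_seed Master seed (default 1).
#' @param pc_criterion PC retention criterion for `mi_pca`.
#' @param bin_size Bin size for `mi_gene_bin`.
#' @param fdr Significance threshold (default 0.05).
#' @param verbose Print per-cell progress.
#' @return data.frame: one row per method x mechanism x level x replicate
#'   with `TPR`, `FPR`, `MAPE`, truth-set size and flags.
#' @export
run_benchmark <- function(props = 0.55, mechanisms = c("MCAR", "MAR", "MNAR"),
                          methods = c("mi_pca", "cc", "si"),
                          n_replicates = 10, G = 500, n = 200,
                          null_fraction = 0.5, shape = 1, m = 10,
                          master_seed = 1, pc_criterion = "horn",
                          bin_size = 10, fdr = 0.05, verbose = FALSE) {
  methods <- match.arg(methods, c("mi_pca", "mi_gene_bin", "cc", "si"),
                       several.ok = TRUE)
  rows <- list()
  counter <- 0L
  for (rep_i in seq_len(n_replicates)) {
    counter <- counter + 1L
    ds <- simulate_dataset(G = G, n = n, null_fraction = null_fraction,
                           shape = shape,
                           seed = .cell_seed(master_seed, counter))
    cmf <- filter_low_counts(ds$counts)
    full <- run_de_single_dataset(cmf, ds$covariates, ds$design)
    full$p_adj <- bh_adjust(full$p)
    full$significant <- full$p_adj < fdr
    for (mech in mechanisms) {
      for (prop in props) {
        counter <- counter + 1L
        amp <- ampute_covariates(ds$covariates, prop = prop, mechanism = mech,
                                 seed = .cell_seed(master_seed, counter))
        res_list <- list()
        for (meth in methods) {
          counter <- counter + 1L
          sd_m <- .cell_seed(master_seed, counter)
          res <- tryCatch(switch(meth,
            mi_pca = run_mi_pca_pipeline(cmf, amp, ds$design, m = m,
                                         pc_criterion = pc_criterion,
                                         count_target = NA, fdr = fdr,
                                         seed = sd_m)$results,
            mi_gene_bin = mi_de_per_bin(cmf, amp, ds$design, m = m,
                                        bin_size = bin_size, fdr = fdr,
                                        seed = sd_m),
            cc = cc_analysis(cmf, amp, ds$design, fdr = fdr),
            si = si_analysis(cmf, amp, ds$design, fdr = fdr, seed = sd_m)),
            error = function(e) {
              warning("cell (", meth, ", ", mech, ", ", prop, ", rep ", rep_i,
                      ") failed: ", conditionMessage(e))
              NULL
            })
          if (!is.null(res)) res_list[[meth]] <- res
        }
        if (length(res_list)) {
          ev <- evaluate_methods(res_list, full, fdr = fdr)
          ev$mechanism <- mech
          ev$prop_missing <- prop
          ev$replicate <- rep_i
          rows[[length(rows) + 1L]] <- ev
        }
        if (verbose)
          message(sprintf("replicate %d, %s, prop %.2f done", rep_i, mech, prop))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a pooled top table
#'
#' @param results A pooled per-gene table ([pool_all()] or
#'   `run_mi_pca_pipeline()$results`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_top_table <- function(results, path) {
  cols <- intersect(c("gene_id", "logFC", "se_pooled", "se", "t",
                      "df_adjusted", "df", "lambda", "p", "p_adj",
                      "significant"), names(results))
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
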