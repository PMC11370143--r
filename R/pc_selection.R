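#' Principal component analysis of the log-CPM matrix
#'
#' Samples are the observations and genes the variables: each gene is
#' centered across samples (no unit-variance scaling by default) and the
#' sample scores, eigenvalues and variance-explained fractions are
#' returned. The decomposition is computed through the singular values of
#' the centered sample x gene matrix, so it stays cheap when the number of
#' genes greatly exceeds the number of samples.
#'
#' @param logcpm G x n numeric matrix (genes x samples).
#' @param center Center each gene (default `TRUE`).
#' @param scale. Scale each gene to unit variance (default `FALSE`).
#' @return An object of class `expr_pca`: list with `scores` (n x k sample
#'   coordinates, k = min(n-1, G) informative components), `eigenvalues`
#'   (descending), `variance_explained` (sums to 1), `sdev`.
#' @export
run_pca <- function(logcpm, center = TRUE, scale. = FALSE) {
  logcpm <- as.matrix(logcpm)
  n <- ncol(logcpm)
  if (n < 3L) stop("PCA requires at least 3 samples")
  if (nrow(logcpm) < 2L) stop("PCA requires at least 2 genes")
  X <- t(logcpm)                         # samples x genes
  X <- scale(X, center = center, scale = scale.)
  X[is.nan(X)] <- 0                      # constant genes under scaling
  if (all(abs(X) < 1e-12))
    stop("expression matrix has no variance; PCA undefined")
  k <- min(n - 1L, nrow(logcpm))
  sv <- svd(X, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  ev <- d^2 / (n - 1)
  scores <- sv$u %*% diag(d, k, k)
  rownames(scores) <- colnames(logcpm)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 sdev = sqrt(ev)),
            class = "expr_pca")
}

# Eigenvalues only (fast path used by the permutation loop): eigen of the
# n x n Gram matrix of the centered sample x gene data.
.pca_eigenvalues <- function(logcpm, k) {
  X <- t(logcpm)
  X <- X - rep(colMeans(X), each = nrow(X))
  ev <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev[seq_len(k)], 0) / (nrow(X) - 1)
}

#' Horn's parallel analysis for component retention
#'
#' Retains principal components whose eigenvalues exceed those of random
#' data: each gene's values are independently permuted across samples
#' `n_permutations` times, the eigen-spectrum recomputed each time, and a
#' component at rank j is retained when its observed eigenvalue exceeds the
#' `percentile` quantile of the permuted eigenvalues at the same rank.
#' Retention stops at the first failure so the retained set is always
#' PC1..PCh.
#'
#' @inheritParams run_pca
#' @param n_permutations Number of permutation replicates (default 50).
#' @param percentile Quantile of the permuted spectrum to beat
#'   (default 0.95).
#' @param seed Optional integer seed for the permutations.
#' @return Integer `h` (possibly 0) with attributes `observed` and
#'   `threshold` (the per-rank permutation quantiles).
#' @export
horn_parallel <- function(logcpm, n_permutations = 50, percentile = 0.95,
                          seed = NULL) {
  if (n_permutations < 2) stop("n_permutations must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  logcpm <- as.matrix(logcpm)
  n <- ncol(logcpm)
  k <- min(n - 1L, nrow(logcpm))
  obs <- .pca_eigenvalues(logcpm, k)
  perm <- matrix(0, n_permutations, k)
  G <- nrow(logcpm)
  for (b in seq_len(n_permutations)) {
    shuf <- logcpm
    for (g in seq_len(G)) shuf[g, ] <- shuf[g, sample.int(n)]
    perm[b, ] <- .pca_eigenvalues(shuf, k)
  }
  thr <- apply(perm, 2, stats::quantile, probs = percentile)
  pass <- obs > thr
  h <- if (pass[1]) which.min(c(pass, FALSE)) - 1L else 0L
  structure(as.integer(h), observed = obs, threshold = thr)
}

# Elbow point: index at maximum perpendicular distance from the
# variance-explained curve to the chord joining its endpoints.
.elbow_index <- function(ve) {
  k <- length(ve)
  if (k < 3L) return(1L)
  x <- seq_len(k)
  dx <- k - 1
  dy <- ve[k] - ve[1]
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (x - 1) - dx * (ve - ve[1])) / nrm
  which.max(d)
}

#' Select principal components for the imputation predictor matrix
#'
#' Runs [run_pca()] and applies one of three retention criteria: Horn's
#' parallel analysis (default), the smallest h whose cumulative variance
#' explained reaches `cutoff` (default 0.80), or the elbow of the
#' variance-explained curve (maximum distance to the chord joining its
#' endpoints).
#'
#' @inheritParams run_pca
#' @param criterion `"horn"`, `"variance_cutoff"` or `"elbow"`.
#' @param n_permutations,percentile,seed Passed to [horn_parallel()].
#' @param cutoff Cumulative variance-explained cutoff for
#'   `"variance_cutoff"`.
#' @return An object of class `pc_selection`: list with `scores` (n x h),
#'   `h`, `eigenvalues`, `variance_explained`, `criterion`,
#'   `criterion_params`.
#' @export
select_pcs <- function(logcpm, criterion = c("horn", "variance_cutoff", "elbow"),
                       n_permutations = 50, percentile = 0.95, cutoff = 0.80,
                       seed = NULL, center = TRUE, scale. = FALSE) {
  criterion <- match.arg(criterion)
  pca <- run_pca(logcpm, center = center, scale. = scale.)
  ve <- pca$variance_explained
  params <- switch(criterion,
    horn = list(n_permutations = n_permutations, percentile = percentile,
                seed = seed),
    variance_cutoff = list(cutoff = cutoff),
    elbow = list())
  h <- switch(criterion,
    horn = as.integer(horn_parallel(logcpm, n_permutations, percentile, seed)),
    variance_cutoff = {
      if (cutoff <= 0) 0L else which(cumsum(ve) >= cutoff - 1e-12)[1]
    },
    elbow = .elbow_index(ve))
  h <- as.integer(min(h, ncol(pca$scores)))
  structure(list(scores = pca$scores[, seq_len(h), drop = FALSE], h = h,
                 eigenvalues = pca$eigenvalues,
                 variance_explained = ve,
                 criterion = criterion, criterion_params = params),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf("pc_selection: h = %d (criterion: %s); top variance explained: %s\n",
              x$h, x$criterion,
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Scree / parallel-analysis table
#'
#' @param sel A [select_pcs()] result.
#' @return data.frame with one row per component: eigenvalue, variance
#'   explained, cumulative variance explained, retained flag.
#' @export
scree_table <- function(sel) {
  stopifnot(inherits(sel, "pc_selection"))
  k <- length(sel$eigenvalues)
  data.frame(component = seq_len(k),
             eigenvalue = sel$eigenvalues,
             variance_explained = sel$variance_explained,
             cumulative = cumsum(sel$variance_explained),
             retained = seq_len(k) <= sel$h)
}
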