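#' Design specification for the per-gene linear model
#'
#' The per-gene model regresses logCPM on an intercept plus the listed
#' covariates; the coefficient of the `contrast` term (the predictor of
#' interest) is the reported log2 fold change.
#'
#' @param terms Ordered character vector of covariate names entering the
#'   model (shadow variables are not allowed).
#' @param contrast Name of the term whose coefficient is reported; defaults
#'   to the first term.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(terms, contrast = terms[1]) {
  terms <- as.character(terms)
  if (!length(terms)) stop("at least one model term is required")
  if (!contrast %in% terms) stop("contrast '", contrast, "' is not among the terms")
  structure(list(terms = terms, contrast = contrast), class = "design_spec")
}

#' Default design from a covariate table
#'
#' Predictor of interest plus all adjustment covariates, in schema order.
#'
#' @param cov A [covariate_table].
#' @return A [design_spec].
#' @export
design_from_covariates <- function(cov) {
  sc <- cov$schema
  pred <- sc$variable[sc$role == "predictor"]
  adj <- sc$variable[sc$role == "adjustment"]
  design_spec(c(pred, adj), contrast = pred)
}

# Model matrix for a completed covariate table plus the index of the single
# contrast column. Factors use treatment coding; the contrast term must
# yield exactly one column.
build_design_matrix <- function(cov, spec) {
  stopifnot(inherits(spec, "design_spec"))
  df <- if (inherits(cov, "covariate_table")) cov$data else as.data.frame(cov)
  missing_terms <- setdiff(spec$terms, names(df))
  if (length(missing_terms))
    stop("design term(s) not found: ", paste(missing_terms, collapse = ", "))
  if (inherits(cov, "covariate_table")) {
    roles <- stats::setNames(cov$schema$role, cov$schema$variable)
    bad <- spec$terms[roles[spec$terms] == "shadow"]
    if (length(bad))
      stop("shadow variable(s) cannot enter the model: ",
           paste(bad, collapse = ", "))
  }
  df <- df[, spec$terms, drop = FALSE]
  if (anyNA(df))
    stop("design covariates contain missing values; impute or drop first")
  # ordered factors would get polynomial contrasts by default; use treatment
  # coding throughout so coefficients are level effects
  for (v in names(df)) if (is.ordered(df[[v]])) df[[v]] <- factor(df[[v]], ordered = FALSE)
  X <- stats::model.matrix(~ ., data = df)
  assign <- attr(X, "assign")
  term_idx <- match(spec$contrast, spec$terms)
  cols <- which(assign == term_idx)
  if (length(cols) != 1L)
    stop("contrast term '", spec$contrast, "' must contribute exactly one ",
         "coefficient (found ", length(cols), "); multi-level categorical ",
         "predictors of interest are not supported")
  attr(X, "contrast_col") <- cols
  X
}

#' Voom-style observation-level precision weights
#'
#' Models the mean-variance relationship of logCPM values. Each gene is fit
#' by OLS on the design; a LOWESS curve of the square-root residual
#' standard deviations against the average log-counts
#' `r_tilde_g = mean(logCPM_g) + log2(R_tilde) - log2(1e6)` (with `R_tilde`
#' the geometric mean of the effective library sizes plus one) is
#' interpolated piecewise-linearly (constant beyond its knots) to give the
#' function `lo()`; fitted logCPM values are converted to fitted log-counts
#' `lambda_hat_gi = mu_hat_gi + log2(R_i + 1) - log2(1e6)` and the precision
#' weight of each observation is `lo(lambda_hat_gi)^-4`, the predicted
#' inverse variance.
#'
#' @param cm A [count_matrix] (filtered).
#' @param design Design matrix from [build_design_matrix()], or a bare
#'   full-rank numeric matrix with an intercept.
#' @param norm A [normalize_counts()] result; computed if `NULL`.
#' @param span LOWESS span (default 0.5).
#' @return An object of class `voom_fit`: list with `weights` (G x n),
#'   `logcpm`, `r_tilde`, `lo_knots`, `design`, `norm`.
#' @export
voom_weights <- function(cm, design, norm = NULL, span = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(norm)) norm <- normalize_counts(cm)
  y <- norm$logcpm
  lib <- norm$effective_lib_sizes
  n <- ncol(y)
  p <- qr(design)$rank
  if (p < ncol(design)) stop("design matrix is not full rank")
  if (n - p <= 0) stop("no residual degrees of freedom (saturated design)")
  QR <- qr(design)
  beta <- t(qr.coef(QR, t(y)))
  fitted <- beta %*% t(design)
  res <- y - fitted
  sigma <- sqrt(rowSums(res^2) / (n - p))
  if (all(sigma < 1e-12))
    stop("all residual standard deviations are zero; ",
         "precision weights are undefined (is the data degenerate?)")
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- stats::lowess(sx, sy, f = span)
  lo_fun <- stats::approxfun(l, rule = 2, ties = list("ordered", mean))
  lambda_hat <- fitted + matrix(log2(lib + 1) - log2(1e6), nrow(y), n,
                                byrow = TRUE)
  w <- 1 / lo_fun(lambda_hat)^4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-finite or non-positive precision weight produced")
  structure(list(weights = w, logcpm = y, r_tilde = sx,
                 lo_knots = l, design = design, norm = norm),
            class = "voom_fit")
}

#' Weighted least squares for one gene
#'
#' @param y Numeric response (logCPM values for one gene).
#' @param X Full-rank design matrix.
#' @param w Positive observation weights.
#' @return List with `beta` (all coefficients), `sigma` (residual sd),
#'   `df_residual`, `se` (per-coefficient standard errors) and `unscaled`
#'   (per-coefficient sqrt of the diagonal of `(X'WX)^-1`, so that
#'   `se = sigma * unscaled`).
#' @export
wls_fit_per_gene <- function(y, X, w) {
  if (any(w <= 0)) stop("weights must be positive")
  XtW <- t(X * w)
  A <- XtW %*% X
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("design is rank deficient (collinear terms: ",
         paste(colnames(X), collapse = ", "), ")"))
  beta <- drop(Ainv %*% (XtW %*% y))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  unscaled <- sqrt(diag(Ainv))
  list(beta = beta, sigma = sqrt(sigma2), df_residual = df,
       se = sqrt(sigma2) * unscaled, unscaled = unscaled)
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
.trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Fits a scaled inverse-chi-square prior to the gene-wise residual
#' variances by moment matching on the log scale: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, the prior df `d0`
#' solves `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` and the prior
#' variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The
#' posterior (moderated) variance is the convex combination
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the moderated df is
#' `d0 + d_g`. A non-finite prior-df estimate (log-variances less dispersed
#' than chi-square sampling noise) is treated as an infinite prior: all
#' posterior variances equal `s0^2`.
#'
#' @param sigma2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @return List with `var_post`, `var_prior`, `df_prior`, `df_total`.
#' @export
ebayes_moderate <- function(sigma2, df) {
  G <- length(sigma2)
  if (G < 3) stop("at least 3 genes are required to fit the variance prior")
  if (G < 10)
    warning("fewer than 10 genes; the variance-prior fit may be unstable")
  df <- rep_len(df, G)
  s2 <- pmax(sigma2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # log-variances less dispersed than chi-square sampling noise: point
    # prior; no bias correction is appropriate for a point mass
    df_prior <- Inf
    var_prior <- exp(mean(log(s2)))
  }
  if (!is.finite(df_prior)) {
    var_post <- rep(var_prior, G)
    df_total <- rep(Inf, G)
  } else {
    var_post <- (df_prior * var_prior + df * sigma2) / (df_prior + df)
    df_total <- df_prior + df
  }
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior,
       df_total = df_total)
}

#' Differential expression on one completed dataset
#'
#' The single-dataset analysis chain: voom precision weights, per-gene
#' weighted least squares, empirical-Bayes variance moderation. Returns the
#' per-gene coefficient of the contrast term, its moderated standard error
#' and the moderated degrees of freedom — the quantities pooled across
#' imputations by Rubin's rules.
#'
#' @param cm A filtered [count_matrix].
#' @param cov A complete [covariate_table] (one imputed dataset), or a
#'   complete data.frame of covariates.
#' @param spec A [design_spec].
#' @param norm Optional precomputed [normalize_counts()] result.
#' @param span LOWESS span for the mean-variance trend.
#' @return data.frame with one row per gene: `gene_id`, `logFC`, `sigma`,
#'   `se`, `df` (moderated), `t`, `p`.
#' @export
run_de_single_dataset <- function(cm, cov, spec, norm = NULL, span = 0.5) {
  X <- build_design_matrix(cov, spec)
  jc <- attr(X, "contrast_col")
  vf <- voom_weights(cm, X, norm = norm, span = span)
  G <- nrow(vf$logcpm)
  beta <- sigma <- unscaled <- numeric(G)
  dfres <- integer(G)
  for (g in seq_len(G)) {
    f <- wls_fit_per_gene(vf$logcpm[g, ], X, vf$weights[g, ])
    beta[g] <- f$beta[jc]
    sigma[g] <- f$sigma
    dfres[g] <- f$df_residual
    unscaled[g] <- f$unscaled[jc]
  }
  mod <- ebayes_moderate(sigma^2, dfres)
  se_mod <- sqrt(mod$var_post) * unscaled
  tstat <- beta / se_mod
  p <- 2 * stats::pt(-abs(tstat), mod$df_total)
  data.frame(gene_id = cm$gene_ids, logFC = beta, sigma = sigma,
             se = se_mod, df = mod$df_total, t = tstat, p = p,
             stringsAsFactors = FALSE)
}
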