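#' Build the imputation predictor matrix
#'
#' Every covariate with at least one missing cell becomes an imputation
#' target; its predictors are all other (unmasked) covariates plus the
#' retained principal-component scores of the expression matrix. The
#' per-target model is keyed by the declared variable type: predictive mean
#' matching for continuous, logistic regression for binary, polytomous
#' regression for unordered categorical and proportional-odds modelling for
#' ordered categorical targets. PC scores are complete by construction
#' (expression is never imputed) and never appear as targets.
#'
#' @param cov A [covariate_table].
#' @param pcs A [select_pcs()] result, a bare n x h score matrix, or `NULL`
#'   for imputation without expression information.
#' @param exclude Character vector of variables to hide from the imputer
#'   entirely (neither targets nor predictors); defaults to `cov$masked`,
#'   the MNAR masking rule recorded by [ampute_covariates()].
#' @return An object of class `predictor_matrix`: list with `targets`,
#'   `methods` (named by target), `predictors` (named list), `pc_scores`.
#' @export
build_predictor_matrix <- function(cov, pcs = NULL, exclude = cov$masked) {
  stopifnot(inherits(cov, "covariate_table"))
  scores <- NULL
  if (inherits(pcs, "pc_selection")) scores <- pcs$scores
  else if (is.matrix(pcs)) scores <- pcs
  if (!is.null(scores) && nrow(scores) != nrow(cov$data))
    stop("PC scores are not aligned to the covariate table samples")
  vars <- setdiff(cov$schema$variable, exclude)
  miss <- cov$miss[, vars, drop = FALSE]
  all_missing <- colSums(!miss) == 0
  if (any(all_missing))
    stop("variable(s) with all cells missing cannot be imputed: ",
         paste(vars[all_missing], collapse = ", "))
  targets <- vars[colSums(miss) > 0]
  type_of <- stats::setNames(cov$schema$type, cov$schema$variable)
  methods <- stats::setNames(vapply(targets, function(v)
    switch(type_of[[v]],
           continuous = "pmm",
           binary = "logreg",
           categorical_unordered = "polyreg",
           categorical_ordered = "polr"), ""), targets)
  pc_names <- if (is.null(scores)) character(0) else colnames(scores)
  predictors <- stats::setNames(lapply(targets, function(v)
    c(setdiff(vars, v), pc_names)), targets)
  structure(list(targets = targets, methods = methods,
                 predictors = predictors, pc_scores = scores,
                 variables = vars),
            class = "predictor_matrix")
}

# Numeric design encoding of covariate predictors (no intercept column):
# continuous as-is, ordered factors as integer scores, other factors as
# full treatment-coded dummies.
.encode_predictors <- function(df, vars, schema, pc_scores = NULL) {
  cols <- list()
  type_of <- stats::setNames(schema$type, schema$variable)
  for (v in vars) {
    x <- df[[v]]
    if (is.null(x)) next
    if (type_of[[v]] == "continuous") {
      cols[[v]] <- matrix(as.numeric(x), ncol = 1,
                          dimnames = list(NULL, v))
    } else if (type_of[[v]] == "categorical_ordered") {
      cols[[v]] <- matrix(as.numeric(as.integer(x)), ncol = 1,
                          dimnames = list(NULL, v))
    } else {
      lv <- levels(x)
      m <- matrix(0, length(x), length(lv) - 1L,
                  dimnames = list(NULL, paste0(v, lv[-1])))
      for (j in seq_along(lv[-1])) m[, j] <- as.numeric(x == lv[j + 1L])
      cols[[v]] <- m
    }
  }
  X <- do.call(cbind, cols)
  if (!is.null(pc_scores)) X <- cbind(X, pc_scores)
  X
}

# Logistic regression by IRLS with an optional ridge penalty; used both for
# binary imputation models and as the separation-stabilized fallback.
.irls_logistic <- function(X, y, ridge = 0, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(ridge, p)
  pen[1, 1] <- 0                          # never penalize the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- t(X * w) %*% X + pen
  V <- tryCatch(solve(H), error = function(e) NULL)
  list(beta = beta, vcov = V, converged = max(abs(beta)) < 25)
}

.draw_mvn <- function(mean, V) {
  L <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8, nrow(V))))
  drop(mean + t(L) %*% stats::rnorm(length(mean)))
}

#' Predictive mean matching for one target variable
#'
#' The Bayesian-draw variant of PMM: the residual variance is drawn from its
#' scaled inverse-chi-square posterior and the regression coefficients from
#' their conditional normal posterior; predicted values for the observed
#' rows use the posterior mode and for the missing rows the drawn
#' coefficients, and each missing row is imputed with the observed value of
#' one of its `k_donors` nearest rows in predicted-value space, chosen
#' uniformly. Imputed values are therefore always observed donor values.
#'
#' @param y_obs Numeric observed responses.
#' @param X_obs,X_mis Numeric predictor matrices (no intercept column) for
#'   the observed and missing rows.
#' @param k_donors Number of candidate donors (default 5).
#' @param ridge Ridge added to the cross-product on singular designs.
#' @return Numeric vector of imputations, one per row of `X_mis`.
#' @export
pmm_impute_one <- function(y_obs, X_obs, X_mis, k_donors = 5, ridge = 1e-5) {
  n <- length(y_obs)
  if (n < k_donors) stop("need at least k_donors observed rows")
  X_obs <- cbind(1, as.matrix(X_obs))
  X_mis <- cbind(1, as.matrix(X_mis))
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs)
  sc <- mean(diag(XtX))
  XtXr <- XtX + diag(ridge * sc, p)
  betahat <- tryCatch(solve(XtXr, crossprod(X_obs, y_obs)),
                      error = function(e) solve(XtX + diag(0.01 * sc, p),
                                                crossprod(X_obs, y_obs)))
  betahat <- drop(betahat)
  resid <- y_obs - drop(X_obs %*% betahat)
  df <- max(n - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  V <- sigma2 * tryCatch(solve(XtXr), error = function(e) diag(1 / sc, p))
  beta_star <- .draw_mvn(betahat, V)
  yhat_obs <- drop(X_obs %*% betahat)
  yhat_mis <- drop(X_mis %*% beta_star)
  k <- min(k_donors, n)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    donors <- order(d, stats::runif(n))[seq_len(k)]
    y_obs[donors[sample.int(k, 1)]]
  }, numeric(1))
}

# One update of one target variable inside the chained-equations sweep.
# Returns the vector of imputed values for the missing rows.
.impute_target <- function(y, obs, X, method, k_donors) {
  X_obs <- X[obs, , drop = FALSE]
  X_mis <- X[!obs, , drop = FALSE]
  n_mis <- sum(!obs)
  if (method == "pmm")
    return(pmm_impute_one(y[obs], X_obs, X_mis, k_donors = k_donors))
  if (method == "logreg") {
    lv <- levels(y)
    yy <- as.numeric(y[obs] == lv[2])
    Xi <- cbind(1, X_obs)
    fit <- .irls_logistic(Xi, yy)
    if (is.null(fit) || is.null(fit$vcov) || !fit$converged) {
      warning("separation in logistic imputation model; ridge-stabilized fit used")
      fit <- .irls_logistic(Xi, yy, ridge = 0.1)
    }
    beta_star <- .draw_mvn(fit$beta, fit$vcov)
    p_mis <- stats::plogis(drop(cbind(1, X_mis) %*% beta_star))
    return(factor(lv[1 + stats::rbinom(n_mis, 1, p_mis)], levels = lv))
  }
  # polytomous / proportional odds: fit on observed rows, draw classes from
  # the predicted class probabilities of the missing rows
  dat <- data.frame(.y = y[obs], X_obs, check.names = FALSE)
  nd <- data.frame(X_mis, check.names = FALSE)
  probs <- NULL
  if (method == "polr" && nlevels(droplevels(y[obs])) >= 3L) {
    fit <- tryCatch(
      suppressWarnings(MASS::polr(.y ~ ., data = dat, method = "logistic")),
      error = function(e) NULL)
    if (!is.null(fit))
      probs <- tryCatch(stats::predict(fit, newdata = nd, type = "probs"),
                        error = function(e) NULL)
    if (is.null(probs))
      warning("proportional-odds fit failed; polytomous fallback used")
  }
  if (is.null(probs)) {
    fit <- tryCatch(
      nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 200),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("polytomous fit failed; ridge-stabilized (decay) fit used")
      fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 200,
                            decay = 1e-2)
    }
    probs <- stats::predict(fit, newdata = nd, type = "probs")
  }
  lv <- levels(y)
  if (is.null(dim(probs))) {
    # two observed classes collapse predict() to a vector of P(class 2)
    seen <- levels(droplevels(y[obs]))
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- seen
  }
  full <- matrix(0, n_mis, length(lv), dimnames = list(NULL, lv))
  full[, colnames(probs)] <- as.matrix(probs)
  idx <- apply(full, 1, function(pr) sample.int(length(lv), 1, prob = pr))
  factor(lv[idx], levels = lv, ordered = is.ordered(y))
}

#' Multiple imputation by chained equations
#'
#' Generates `m` completed covariate tables. Each imputation runs an
#' independent chain: missing cells are initialized by random draws from the
#' observed marginal of their variable, then the target variables are
#' cycled in declared column order for `n_iterations` sweeps, refitting the
#' per-target model on the currently completed data and redrawing the
#' imputations; the final sweep's values are returned. Observed cells are
#' never modified. Per-iteration means and variances of the imputed values
#' are recorded for convergence diagnostics.
#'
#' @param cov A [covariate_table] with missing cells.
#' @param pm A [build_predictor_matrix()] result.
#' @param m Number of imputed datasets (default 10).
#' @param n_iterations Chained-equation sweeps per chain (default 10).
#' @param k_donors PMM donor count (default 5).
#' @param seed Optional integer seed; fixing it makes the stack
#'   reproducible.
#' @return An object of class `imputed_stack`: list with `m`, `tables`
#'   (list of complete [covariate_table]s), `chain_stats`, `pm`, `seed`.
#' @export
impute_chained <- function(cov, pm, m = 10, n_iterations = 10, k_donors = 5,
                           seed = NULL) {
  stopifnot(inherits(cov, "covariate_table"), inherits(pm, "predictor_matrix"))
  if (m < 2) stop("m must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  targets <- pm$targets
  df0 <- cov$data
  miss <- cov$miss
  for (v in targets) {
    n_obs <- sum(!miss[, v])
    need <- max(10, length(pm$predictors[[v]]) + 2)
    if (n_obs < need)
      warning("target '", v, "' has only ", n_obs,
              " observed rows for ", length(pm$predictors[[v]]),
              " predictors; imputation model may be unstable")
  }
  chain_stats <- list()
  tables <- vector("list", m)
  for (chain in seq_len(m)) {
    df <- df0
    # marginal-draw initialization
    for (v in targets) {
      idx <- which(miss[, v])
      pool <- df0[[v]][!miss[, v]]
      df[[v]][idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
    iters <- max(n_iterations, 1L)
    for (it in seq_len(iters)) {
      for (v in targets) {
        pred_vars <- setdiff(pm$predictors[[v]], colnames(pm$pc_scores))
        X <- .encode_predictors(df, pred_vars, cov$schema, pm$pc_scores)
        obs <- !miss[, v]
        df[[v]][!obs] <- .impute_target(df[[v]], obs, X, pm$methods[[v]],
                                        k_donors)
        vals <- df[[v]][!obs]
        nv <- if (is.factor(vals)) as.numeric(as.integer(vals)) else as.numeric(vals)
        chain_stats[[length(chain_stats) + 1L]] <-
          data.frame(chain = chain, iteration = it, variable = v,
                     mean = mean(nv), var = stats::var(nv))
      }
    }
    tbl <- cov
    tbl$data <- df
    tbl$miss <- is.na(df)
    tables[[chain]] <- tbl
  }
  structure(list(m = m, tables = tables,
                 chain_stats = do.call(rbind, chain_stats),
                 n_iterations = n_iterations, pm = pm, seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("imputed_stack: m = %d completed tables, %d target variable(s), %d iterations\n",
              x$m, length(x$pm$targets), x$n_iterations))
  invisible(x)
}

#' Convergence diagnostics for an imputed stack
#'
#' Compares the between-chain spread of per-iteration chain means to the
#' within-chain spread over the second half of the iterations, in the style
#' of a potential-scale-reduction factor: for each target variable,
#' `ratio = sqrt((T-1)/T + var(chain means)/W)` where W is the mean
#' within-chain variance of the iteration means. Variables with ratio above
#' `flag_threshold` are flagged; runs with fewer than 2 recorded iterations
#' cannot be assessed and are flagged as such.
#'
#' @param stack An [impute_chained()] result.
#' @param flag_threshold Flag ratio (default 1.2).
#' @return data.frame with one row per target variable: `variable`,
#'   `ratio`, `flag`, `reason`; zero rows when nothing was imputed.
#' @export
convergence_diagnostics <- function(stack, flag_threshold = 1.2) {
  stopifnot(inherits(stack, "imputed_stack"))
  cs <- stack$chain_stats
  out <- data.frame(variable = character(0), ratio = numeric(0),
                    flag = logical(0), reason = character(0))
  if (is.null(cs) || !nrow(cs)) return(out)
  for (v in unique(cs$variable)) {
    sub <- cs[cs$variable == v, ]
    iters <- sort(unique(sub$iteration))
    keep <- iters[iters > max(iters) / 2]
    if (length(keep) < 2L) {
      out <- rbind(out, data.frame(variable = v, ratio = NA_real_, flag = TRUE,
                                   reason = "too few iterations to assess"))
      next
    }
    sub <- sub[sub$iteration %in% keep, ]
    Tn <- length(keep)
    chain_means <- tapply(sub$mean, sub$chain, mean)
    within <- tapply(sub$mean, sub$chain, stats::var)
    W <- mean(within)
    ratio <- if (W <= 0) 1 else sqrt((Tn - 1) / Tn + stats::var(chain_means) / W)
    out <- rbind(out, data.frame(variable = v, ratio = ratio,
                                 flag = ratio > flag_threshold,
                                 reason = ifelse(ratio > flag_threshold,
                                                 "between-chain spread high", "")))
  }
  rownames(out) <- NULL
  out
}
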