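#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Generates a base (null) count matrix emulating bulk RNA-seq structure:
#' gene-wise relative abundances from a log-normal, log-normal library-size
#' variation, and gene-wise negative-binomial dispersion with a biological
#' coefficient of variation typical of human bulk data (~0.25-0.3). The
#' matrix carries no covariate signal; signal is planted afterwards by
#' binomial thinning ([thin_counts()]).
#'
#' @param G Number of genes (default 500).
#' @param n Number of samples (default 200).
#' @param lib_size_mean Mean library size (default 3e5; the gene panel is a
#'   transcriptome subsample, so per-gene depth — here ~600 reads/gene —
#'   is what matters, not total depth).
#' @param lib_size_sdlog Log-scale sd of library sizes (default 0.35).
#' @param baseline_sdlog2 SD of gene log2 relative abundances (default 1.8).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise NB dispersion (defaults give BCV around 0.28).
#' @param seed Optional integer seed.
#' @return A [count_matrix].
#' @export
simulate_counts <- function(G = 500, n = 200, lib_size_mean = 3e5,
                            lib_size_sdlog = 0.35, baseline_sdlog2 = 1.8,
                            dispersion_meanlog = log(0.08),
                            dispersion_sdlog = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rel <- 2^stats::rnorm(G, 0, baseline_sdlog2)
  prop <- rel / sum(rel)
  L <- stats::rlnorm(n, log(lib_size_mean) - lib_size_sdlog^2 / 2, lib_size_sdlog)
  disp <- stats::rlnorm(G, dispersion_meanlog, dispersion_sdlog) + 0.01
  mu <- outer(prop, L)
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / disp, n)),
                   G, n)
  count_matrix(counts,
               gene_ids = sprintf("gene_%04d", seq_len(G)),
               sample_ids = sprintf("sample_%04d", seq_len(n)))
}

#' Simulate a mixed-type covariate table
#'
#' Draws correlated covariates from a latent Gaussian with exchangeable
#' correlation `rho`: a binary predictor of interest (`group`), a
#' continuous (`age`) and a 3-level unordered categorical (`batch`)
#' adjustment covariate, and two shadow variables (`alcohol`, binary;
#' `income`, continuous) that can drive simulated missingness.
#'
#' @param n Number of samples.
#' @param rho Latent exchangeable correlation (default 0.3).
#' @param seed Optional integer seed.
#' @return A complete [covariate_table].
#' @export
simulate_covariates <- function(n, rho = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- 5L
  S <- matrix(rho, V, V); diag(S) <- 1
  Z <- matrix(stats::rnorm(n * V), n, V) %*% chol(S)
  df <- data.frame(
    group = ifelse(Z[, 1] > 0, "b", "a"),
    age = 30 + 5 * Z[, 2],
    batch = cut(Z[, 3], breaks = stats::qnorm(c(0, 1 / 3, 2 / 3, 1)),
                labels = c("b1", "b2", "b3"), include.lowest = TRUE),
    alcohol = ifelse(Z[, 4] > stats::qnorm(0.7), "yes", "no"),
    income = 50 + 15 * Z[, 5])
  schema <- data.frame(
    variable = c("group", "age", "batch", "alcohol", "income"),
    type = c("binary", "continuous", "categorical_unordered", "binary",
             "continuous"),
    role = c("predictor", "adjustment", "adjustment", "shadow", "shadow"),
    stringsAsFactors = FALSE)
  covariate_table(df, schema,
                  sample_ids = sprintf("sample_%04d", seq_len(n)))
}

#' Draw per-gene signal coefficients
#'
#' A fraction `null_fraction` of genes (rounded up) get a zero coefficient;
#' the remainder get log2 fold-change magnitudes drawn from a gamma
#' distribution with the given shape (scale 1), with independent random
#' signs unless `random_sign = FALSE`.
#'
#' @param G Number of genes.
#' @param null_fraction Fraction of null genes in \[0, 1\] (benchmarked
#'   levels: 0.25, 0.50, 0.75, 0.99).
#' @param shape Gamma shape (default 1, i.e. exponential magnitudes).
#' @param random_sign Randomize effect signs (default `TRUE`).
#' @param seed Optional integer seed.
#' @return An object of class `signal_plan`: list with `beta` (length G),
#'   `is_null`, `null_fraction`.
#' @export
draw_effects <- function(G, null_fraction, shape = 1, random_sign = TRUE,
                         seed = NULL) {
  if (null_fraction < 0 || null_fraction > 1)
    stop("null_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_null <- min(G, ceiling(null_fraction * G))
  nulls <- sample.int(G, n_null)
  beta <- numeric(G)
  sig_idx <- setdiff(seq_len(G), nulls)
  if (length(sig_idx)) {
    mag <- stats::rgamma(length(sig_idx), shape = shape)
    if (random_sign) mag <- mag * sample(c(-1, 1), length(sig_idx), replace = TRUE)
    beta[sig_idx] <- mag
  }
  structure(list(beta = beta, is_null = seq_len(G) %in% nulls,
                 null_fraction = null_fraction),
            class = "signal_plan")
}

# Core binomial thinning against one predictor column: per-cell thinning
# probability q_gi with log2 q_gi = beta_g * x_i - max_i(beta_g * x_i), so
# q <= 1 and the expected log2 fold change of gene g per unit of x is
# beta_g.
.thin_one <- function(counts, x, beta) {
  L <- outer(beta, x)
  L <- L - apply(L, 1, max)
  q <- 2^L
  if (any(!is.finite(q))) stop("non-finite thinning probability")
  m <- matrix(stats::rbinom(length(counts), size = counts, prob = q),
              nrow(counts), ncol(counts))
  m
}

#' Plant known signal by binomial thinning
#'
#' Downsamples counts with per-cell binomial probabilities so that the log2
#' fold change of each gene with respect to the predictor equals the
#' planted coefficient in expectation; thinning preserves the count nature
#' and the inter-gene correlation of the base matrix. A binary predictor is
#' coded 0/1 (so coefficients are log2 fold changes between groups); a
#' continuous predictor is standardized (coefficients are per-SD).
#'
#' @param cm A [count_matrix].
#' @param x Predictor values per sample (numeric, or a 2-level factor).
#' @param plan A [draw_effects()] plan (its `beta` has one entry per gene).
#' @param seed Optional integer seed.
#' @return A [count_matrix] of thinned counts (cell-wise <= the input).
#' @export
thin_counts <- function(cm, x, plan, seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(plan, "signal_plan"))
  if (!is.null(seed)) set.seed(seed)
  if (is.factor(x)) x <- as.integer(x) - 1L
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("predictor values must be finite")
  if (length(x) != ncol(cm$counts)) stop("one predictor value per sample required")
  ux <- unique(x)
  if (length(ux) == 2L) {
    x <- as.numeric(x == max(ux))
  } else if (stats::sd(x) > 0) {
    x <- (x - mean(x)) / stats::sd(x)
  }
  if (length(plan$beta) != nrow(cm$counts))
    stop("signal plan has ", length(plan$beta), " coefficients for ",
         nrow(cm$counts), " genes")
  thinned <- .thin_one(cm$counts, x, plan$beta)
  count_matrix(thinned, gene_ids = cm$gene_ids, sample_ids = cm$sample_ids)
}

#' Induce missingness in a covariate table
#'
#' Converts a complete covariate table into one with controlled,
#' mechanism-specific missingness. A target fraction `prop` of samples
#' receive at least one missing cell; each selected sample gets a
#' missingness pattern drawn over the pattern variables (by default, each
#' pattern blanks a single adjustment covariate). Under MCAR, samples are
#' selected uniformly at random. Under MAR and MNAR, the per-sample
#' selection probability increases with a weighted sum of the scoring
#' variables through a logistic link whose intercept is calibrated by root
#' finding so the expected selected fraction equals `prop`. Under MNAR the
#' scoring variables are additionally recorded in the output's `masked`
#' field, so downstream imputers cannot use them; under MAR they remain
#' visible. The predictor of interest is never amputed.
#'
#' @param cov A complete [covariate_table].
#' @param prop Target fraction of samples with at least one missing cell
#'   (0 <= prop < 1).
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param patterns Logical matrix (patterns x variables, `TRUE` = missing),
#'   columns named by variable. Default: one single-variable pattern per
#'   adjustment covariate.
#' @param weights Named numeric vector of scoring-variable influences
#'   (MAR/MNAR). Default: weight 1 on every shadow variable.
#' @param seed Optional integer seed.
#' @return A [covariate_table] with `NA`s induced, plus fields `masked`
#'   (MNAR scoring variables) and attribute `mechanism`.
#' @export
ampute_covariates <- function(cov, prop, mechanism = c("MCAR", "MAR", "MNAR"),
                              patterns = NULL, weights = NULL, seed = NULL) {
  stopifnot(inherits(cov, "covariate_table"))
  mechanism <- match.arg(mechanism)
  if (prop < 0 || prop >= 1) stop("prop must be in [0, 1)")
  if (anyNA(cov$data)) stop("covariate table must be complete before amputation")
  if (!is.null(seed)) set.seed(seed)
  if (prop == 0) {
    out <- cov
    attr(out, "mechanism") <- mechanism
    return(out)
  }
  pred <- predictor_variable(cov)
  if (is.null(patterns)) {
    adj <- cov$schema$variable[cov$schema$role == "adjustment"]
    if (!length(adj)) stop("no adjustment covariates available to ampute")
    patterns <- diag(length(adj)) == 1
    colnames(patterns) <- adj
  }
  patterns <- as.matrix(patterns)
  if (!nrow(patterns) || !any(patterns))
    stop("prop > 0 requires at least one non-empty missingness pattern")
  if (pred %in% colnames(patterns)[colSums(patterns) > 0])
    stop("the predictor of interest ('", pred, "') must never be amputed")
  n <- nrow(cov$data)
  if (mechanism == "MCAR") {
    p_sel <- rep(prop, n)
  } else {
    if (is.null(weights)) {
      shadows <- cov$schema$variable[cov$schema$role == "shadow"]
      if (!length(shadows))
        stop("MAR/MNAR amputation needs scoring variables (weights or shadow role)")
      weights <- stats::setNames(rep(1, length(shadows)), shadows)
    }
    Xs <- .encode_predictors(cov$data, names(weights), cov$schema)
    # collapse each scoring variable's dummy block to one standardized score
    score <- rep(0, n)
    for (v in names(weights)) {
      cols <- grep(paste0("^", v), colnames(Xs))
      s <- rowSums(Xs[, cols, drop = FALSE])
      if (stats::sd(s) > 0) s <- (s - mean(s)) / stats::sd(s)
      score <- score + weights[[v]] * s
    }
    a <- stats::uniroot(function(a) mean(stats::plogis(a + score)) - prop,
                        c(-30, 30))$root
    p_sel <- stats::plogis(a + score)
  }
  sel <- which(stats::runif(n) < p_sel)
  out <- cov
  if (length(sel)) {
    pat_idx <- sample.int(nrow(patterns), length(sel), replace = TRUE)
    for (k in seq_along(sel)) {
      vs <- colnames(patterns)[patterns[pat_idx[k], ]]
      out$data[sel[k], vs] <- NA
    }
  }
  out$miss <- is.na(out$data)
  if (mechanism == "MNAR") out$masked <- union(out$masked, names(weights))
  attr(out, "mechanism") <- mechanism
  out
}

#' Simulate a complete benchmark dataset
#'
#' Composes the generators into one study: a base negative-binomial count
#' matrix, correlated mixed-type covariates, a signal plan with the given
#' null fraction, binomial thinning of the counts against the predictor of
#' interest, and (optionally) small additional thinning effects of the
#' adjustment covariates so that covariate adjustment matters.
#'
#' @param G,n Genes and samples (defaults 500, 200).
#' @param null_fraction Fraction of genes with no predictor effect
#'   (default 0.5).
#' @param shape Gamma shape of the effect magnitudes (default 1).
#' @param covariate_effect_sd SD of the small normal log2-FC effects of the
#'   adjustment covariates (default 0.2; 0 disables).
#' @param seed Integer seed driving the whole dataset.
#' @param ... Passed to [simulate_counts()].
#' @return List with `counts` (thinned [count_matrix]), `covariates`
#'   (complete [covariate_table]), `plan` (the [draw_effects()] plan for
#'   the predictor), `design` (default [design_spec]).
#' @export
simulate_dataset <- function(G = 500, n = 200, null_fraction = 0.5, shape = 1,
                             covariate_effect_sd = 0.2, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cm <- simulate_counts(G = G, n = n, ...)
  cov <- simulate_covariates(n)
  plan <- draw_effects(G, null_fraction = null_fraction, shape = shape)
  thinned <- thin_counts(cm, cov$data$group, plan)
  if (covariate_effect_sd > 0) {
    for (v in cov$schema$variable[cov$schema$role == "adjustment"]) {
      b <- stats::rnorm(G, 0, covariate_effect_sd)
      x <- cov$data[[v]]
      if (is.factor(x) && nlevels(x) > 2) x <- as.integer(x)
      cplan <- structure(list(beta = b, is_null = b == 0, null_fraction = 0),
                         class = "signal_plan")
      thinned <- thin_counts(thinned, x, cplan)
    }
  }
  list(counts = thinned, covariates = cov, plan = plan,
       design = design_from_covariates(cov))
}
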