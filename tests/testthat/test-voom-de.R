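test_that("precision weights are positive, finite and gene-order invariant", {
  cm <- make_counts(G = 60, n = 10, seed = 51, mu = 300)
  X <- cbind(1, rep(c(0, 1), each = 5))
  vf <- voom_weights(cm, X)
  expect_true(all(is.finite(vf$weights)) && all(vf$weights > 0))
  perm <- sample(nrow(cm$counts))
  cmp <- count_matrix(cm$counts[perm, ], sample_ids = cm$sample_ids)
  vfp <- voom_weights(cmp, X)
  expect_equal(vfp$weights, vf$weights[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a flat mean-variance trend yields near-constant weights", {
  # homoskedastic Gaussian logCPM surrogate: no trend for lowess to chase
  set.seed(52)
  G <- 80; n <- 20
  surrogate <- structure(list(
    logcpm = matrix(rnorm(G * n, mean = 5, sd = 0.5), G, n),
    lib_sizes = rep(1e6, n), norm_factors = rep(1, n),
    effective_lib_sizes = rep(1e6, n)), class = "normalized_expression")
  cm <- count_matrix(matrix(1, G, n))   # counts unused beyond validation
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  vf <- voom_weights(cm, X, norm = surrogate)
  expect_lt(max(abs(vf$weights / median(vf$weights) - 1)), 0.2)
})

test_that("weighted least squares reduces to OLS and handles exact fits", {
  set.seed(53)
  n <- 12
  x <- rnorm(n)
  X <- cbind(1, x)
  y <- 2 + 3 * x + rnorm(n)
  f <- wls_fit_per_gene(y, X, rep(1, n))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(f$beta[2]), slope, tolerance = 1e-12)
  expect_equal(f$df_residual, n - 2)

  exact <- drop(X %*% c(1, -2))
  fe <- wls_fit_per_gene(exact, X, rep(1, n))
  expect_equal(fe$beta, c(1, -2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fe$sigma, 0, tolerance = 1e-8)

  expect_error(wls_fit_per_gene(y, cbind(X, x), rep(1, n)), "rank deficient")
})

test_that("duplicating a sample at half weight reproduces the original fit", {
  set.seed(54)
  n <- 10
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  w <- runif(n, 0.5, 2)
  f1 <- wls_fit_per_gene(y, X, w)
  X2 <- rbind(X, X[n, ])
  y2 <- c(y, y[n])
  w2 <- c(w[-n], w[n] / 2, w[n] / 2)
  f2 <- wls_fit_per_gene(y2, X2, w2)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
})

test_that("variance moderation shrinks towards the prior as a convex mix", {
  s2 <- rep(0.5, 30)
  mod <- ebayes_moderate(s2, df = 8)
  expect_equal(mod$var_post, rep(0.5, 30), tolerance = 1e-9)

  set.seed(55)
  s2r <- rchisq(200, 10) / 10
  modr <- ebayes_moderate(s2r, df = 10)
  if (is.finite(modr$df_prior)) {
    lo <- pmin(s2r, modr$var_prior); hi <- pmax(s2r, modr$var_prior)
    inner <- abs(s2r - modr$var_prior) > 1e-10
    expect_true(all(modr$var_post[inner] > lo[inner] &
                    modr$var_post[inner] < hi[inner]))
  }
})

test_that("moderation recovers known prior df and scale", {
  set.seed(56)
  G <- 500; d0 <- 8; s02 <- 0.4; df <- 10
  true_var <- s02 * d0 / rchisq(G, d0)
  s2 <- true_var * rchisq(G, df) / df
  mod <- ebayes_moderate(s2, df = df)
  expect_lt(abs(mod$df_prior - d0) / d0, 0.2)
  expect_lt(abs(mod$var_prior - s02) / s02, 0.1)
})

test_that("frozen fixture weights match the reference-procedure oracle", {
  counts <- as.matrix(read.delim(test_path("fixtures", "voom_fixture_counts.tsv"),
                                 row.names = 1, check.names = FALSE))
  oracle <- as.matrix(read.delim(test_path("fixtures",
                                           "voom_fixture_weights_oracle.tsv"),
                                 row.names = 1, check.names = FALSE))
  grp <- scan(test_path("fixtures", "voom_fixture_group.tsv"), quiet = TRUE)
  cm <- count_matrix(counts)
  X <- cbind(1, grp)
  vf <- voom_weights(cm, X, norm = normalize_counts(cm, tmm = FALSE))
  expect_lt(max(abs(vf$weights - oracle) / oracle), 1e-3)
})

test_that("the single-dataset chain agrees with the established pipeline", {
  skip_if_not_installed("limma")
  set.seed(57)
  ds <- simulate_dataset(G = 80, n = 30, null_fraction = 0.5, seed = 57)
  cmf <- filter_low_counts(ds$counts)
  res <- run_de_single_dataset(cmf, ds$covariates, ds$design)
  norm <- normalize_counts(cmf)
  X <- seqMI:::build_design_matrix(ds$covariates, ds$design)
  v <- limma::voom(cmf$counts, design = X, lib.size = norm$effective_lib_sizes)
  fit <- limma::eBayes(limma::lmFit(v, X))
  jc <- attr(X, "contrast_col")
  expect_equal(res$logFC, unname(fit$coefficients[, jc]), tolerance = 1e-8)
  expect_equal(res$t, unname(fit$t[, jc]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, jc]), tolerance = 1e-6)
})

test_that("identical covariate tables give bitwise-identical fits", {
  ds <- simulate_dataset(G = 50, n = 24, seed = 58)
  cmf <- filter_low_counts(ds$counts)
  r1 <- run_de_single_dataset(cmf, ds$covariates, ds$design)
  r2 <- run_de_single_dataset(cmf, ds$covariates, ds$design)
  expect_identical(r1, r2)
})

test_that("planted signal is recovered and null p-values are uniform", {
  set.seed(59)
  base <- simulate_counts(G = 400, n = 100, seed = 59)
  grp <- rep(c(0, 1), 50)
  plan <- draw_effects(400, null_fraction = 0.9, seed = 60)
  thinned <- thin_counts(base, grp, plan, seed = 61)
  df <- data.frame(group = factor(ifelse(grp == 1, "b", "a")))
  schema <- data.frame(variable = "group", type = "binary", role = "predictor")
  ct <- covariate_table(df, schema, sample_ids = base$sample_ids)
  res <- run_de_single_dataset(filter_low_counts(thinned), ct,
                               design_spec("group"))
  plan_kept <- plan$beta[match(res$gene_id, base$gene_ids)]
  sig <- abs(plan_kept) > 0.5
  expect_gt(cor(res$logFC[sig], plan_kept[sig]), 0.95)
  ks <- ks.test(res$p[plan_kept == 0], "punif")
  expect_gt(ks$p.value, 0.01)
})
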