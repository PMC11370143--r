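make_impute_setup <- function(n = 60, seed = 41, miss = 10) {
  set.seed(seed)
  df <- data.frame(group = rep(c("a", "b"), length.out = n),
                   age = rnorm(n, 40, 8),
                   smoke = sample(c("no", "yes"), n, replace = TRUE),
                   site = sample(c("x", "y", "z"), n, replace = TRUE))
  schema <- data.frame(
    variable = c("group", "age", "smoke", "site"),
    type = c("binary", "continuous", "binary", "categorical_unordered"),
    role = c("predictor", "adjustment", "adjustment", "adjustment"),
    stringsAsFactors = FALSE)
  ct <- covariate_table(df, schema, sample_ids = sprintf("s%03d", seq_len(n)))
  if (miss > 0) {
    for (v in c("age", "smoke", "site"))
      ct$data[[v]][sample.int(n, miss)] <- NA
    ct$miss <- is.na(ct$data)
  }
  pcs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  list(ct = ct, pcs = pcs)
}

test_that("predictor matrix follows the construction rule", {
  s <- make_impute_setup()
  pm <- build_predictor_matrix(s$ct, s$pcs)
  expect_setequal(pm$targets, c("age", "smoke", "site"))
  expect_equal(unname(pm$methods[c("age", "smoke", "site")]),
               c("pmm", "logreg", "polyreg"))
  for (v in pm$targets) {
    expect_length(pm$predictors[[v]], 3 + 3)   # 3 other covariates + 3 PCs
    expect_false(v %in% pm$predictors[[v]])    # never predicts itself
    expect_true(all(paste0("PC", 1:3) %in% pm$predictors[[v]]))
  }
  # zero missing cells -> empty target set
  s0 <- make_impute_setup(miss = 0)
  expect_length(build_predictor_matrix(s0$ct, s0$pcs)$targets, 0)
})

test_that("masked (MNAR) variables are hidden from the imputer", {
  s <- make_impute_setup()
  s$ct$masked <- "site"
  pm <- build_predictor_matrix(s$ct, s$pcs)
  expect_false("site" %in% pm$targets)
  expect_false(any(vapply(pm$predictors, function(p) "site" %in% p, logical(1))))
  # visible again when masking is lifted (the MAR case)
  s$ct$masked <- character(0)
  pm2 <- build_predictor_matrix(s$ct, s$pcs)
  expect_true("site" %in% pm2$targets)
})

test_that("PMM respects the donor property and degenerate cases", {
  set.seed(42)
  X_obs <- matrix(rnorm(40), 20, 2)
  X_mis <- matrix(rnorm(10), 5, 2)
  y_const <- rep(3.5, 20)
  expect_equal(pmm_impute_one(y_const, X_obs, X_mis), rep(3.5, 5))
  y <- rnorm(20)
  imp <- pmm_impute_one(y, X_obs, X_mis)
  expect_true(all(imp %in% y))
})

test_that("noiseless PMM with one donor matches the brute-force nearest row", {
  set.seed(43)
  X_obs <- matrix(rnorm(60), 30, 2)
  X_mis <- matrix(rnorm(8), 4, 2)
  beta <- c(2, -1)
  y <- drop(X_obs %*% beta) + 5
  imp <- pmm_impute_one(y, X_obs, X_mis, k_donors = 1)
  yhat_mis <- drop(X_mis %*% beta) + 5
  expected <- vapply(yhat_mis, function(yh) y[which.min(abs(y - yh))], numeric(1))
  expect_equal(imp, expected, tolerance = 1e-6)
})

test_that("chained imputation preserves observed cells and is reproducible", {
  s <- make_impute_setup(n = 80, seed = 44, miss = 15)
  pm <- build_predictor_matrix(s$ct, s$pcs)
  st1 <- impute_chained(s$ct, pm, m = 3, n_iterations = 3, seed = 7)
  st2 <- impute_chained(s$ct, pm, m = 3, n_iterations = 3, seed = 7)
  expect_identical(st1$tables[[2]]$data, st2$tables[[2]]$data)
  obs <- !s$ct$miss
  for (tbl in st1$tables) {
    expect_false(anyNA(tbl$data))
    for (v in colnames(obs))
      expect_identical(tbl$data[[v]][obs[, v]], s$ct$data[[v]][obs[, v]])
  }
  expect_error(impute_chained(s$ct, pm, m = 1), "at least 2")
})

test_that("a complete table imputes to m identical copies", {
  s <- make_impute_setup(miss = 0)
  pm <- build_predictor_matrix(s$ct, s$pcs)
  st <- impute_chained(s$ct, pm, m = 3, n_iterations = 2, seed = 1)
  for (tbl in st$tables) expect_identical(tbl$data, s$ct$data)
  expect_equal(nrow(convergence_diagnostics(st)), 0)
})

test_that("imputed categorical draws stay inside the observed level sets", {
  s <- make_impute_setup(n = 90, seed = 45, miss = 20)
  pm <- build_predictor_matrix(s$ct, s$pcs)
  st <- impute_chained(s$ct, pm, m = 2, n_iterations = 3, seed = 2)
  for (tbl in st$tables) {
    expect_true(all(tbl$data$smoke %in% c("no", "yes")))
    expect_true(all(tbl$data$site %in% c("x", "y", "z")))
    expect_true(all(tbl$data$age[s$ct$miss[, "age"]] %in%
                      s$ct$data$age[!s$ct$miss[, "age"]]))  # PMM donors
  }
})

test_that("pooled regression after MCAR imputation is unbiased", {
  # linear-model recovery: y depends on the (complete) predictor x and a
  # covariate z that loses 20% of its values completely at random; the
  # pooled x-coefficient over replicates must sit within 2 MC-SE of truth
  set.seed(46)
  n <- 120; reps <- 40; beta_x <- 0.7
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n); z <- 0.5 * x + rnorm(n)
    y <- beta_x * x + 0.6 * z + rnorm(n)
    df <- data.frame(x = x, z = z, y = y)
    schema <- data.frame(variable = c("x", "z", "y"),
                         type = "continuous",
                         role = c("predictor", "adjustment", "adjustment"))
    ct <- covariate_table(df, schema)
    ct$data$z[sample.int(n, round(0.2 * n))] <- NA
    ct$miss <- is.na(ct$data)
    pm <- build_predictor_matrix(ct, pcs = NULL)
    st <- impute_chained(ct, pm, m = 5, n_iterations = 5)
    fits <- vapply(st$tables, function(tbl) {
      f <- summary(lm(y ~ x + z, data = tbl$data))
      c(f$coefficients["x", 1:2])
    }, numeric(2))
    est[r] <- rubins_pool(fits[1, ], fits[2, ], df_bar = n - 3)$logFC
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - beta_x), 2 * mc_se + 0.02)
})

test_that("convergence diagnostics flag unassessable and settled chains", {
  s <- make_impute_setup(n = 100, seed = 47, miss = 25)
  pm <- build_predictor_matrix(s$ct, s$pcs)
  st <- impute_chained(s$ct, pm, m = 4, n_iterations = 8, seed = 3)
  dg <- convergence_diagnostics(st)
  expect_setequal(dg$variable, c("age", "smoke", "site"))
  expect_true(all(is.finite(dg$ratio)))
  expect_true(all(dg$ratio < 1.5))          # unstructured data: near 1
  st1 <- impute_chained(s$ct, pm, m = 4, n_iterations = 1, seed = 3)
  dg1 <- convergence_diagnostics(st1)
  expect_true(all(dg1$flag))                # one sweep cannot be assessed
})
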