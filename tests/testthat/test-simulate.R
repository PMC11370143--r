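test_that("effect plans honour the null fraction and gamma magnitudes", {
  all_null <- draw_effects(100, null_fraction = 1, seed = 1)
  expect_true(all(all_null$beta == 0))

  set.seed(2)
  plan <- draw_effects(4000, null_fraction = 0, shape = 1, seed = 2)
  expect_true(all(plan$beta != 0))
  expect_lt(abs(mean(abs(plan$beta)) - 1), 3 / sqrt(4000))

  half <- draw_effects(101, null_fraction = 0.5, seed = 3)
  expect_equal(sum(half$beta == 0), ceiling(0.5 * 101))

  p1 <- draw_effects(50, 0.25, seed = 7)
  p2 <- draw_effects(50, 0.25, seed = 7)
  expect_identical(p1$beta, p2$beta)
})

test_that("binomial thinning is a no-op at beta = 0 and never adds counts", {
  cm <- make_counts(G = 50, n = 10, seed = 11)
  x <- rep(c(0, 1), 5)
  null_plan <- draw_effects(50, null_fraction = 1)
  expect_identical(thin_counts(cm, x, null_plan, seed = 1)$counts, cm$counts)

  plan <- draw_effects(50, null_fraction = 0.5, seed = 12)
  thinned <- thin_counts(cm, x, plan, seed = 13)
  expect_true(all(thinned$counts <= cm$counts))
  expect_identical(thinned$counts[plan$beta == 0, ], cm$counts[plan$beta == 0, ])
})

test_that("amputation calibrates the missing fraction and honours MCAR", {
  cov <- simulate_covariates(600, seed = 21)
  none <- ampute_covariates(cov, 0, "MCAR")
  expect_identical(none$data, cov$data)

  amp <- ampute_covariates(cov, 0.4, "MCAR", seed = 22)
  frac <- mean(apply(amp$miss, 1, any))
  expect_lt(abs(frac - 0.4), 0.07)
  expect_false(any(amp$miss[, "group"]))       # predictor never amputed
  expect_length(amp$masked, 0)

  # MCAR: missingness independent of the covariates
  miss_row <- apply(amp$miss, 1, any)
  expect_gt(chisq.test(table(miss_row, cov$data$alcohol))$p.value, 0.01)
})

test_that("MAR scoring raises missingness in the high-score stratum", {
  cov <- simulate_covariates(800, seed = 23)
  amp <- ampute_covariates(cov, 0.5, "MAR",
                           weights = c(alcohol = 2), seed = 24)
  miss_row <- apply(amp$miss, 1, any)
  rate_yes <- mean(miss_row[cov$data$alcohol == "yes"])
  rate_no <- mean(miss_row[cov$data$alcohol == "no"])
  expect_gt(rate_yes, rate_no + 0.1)
  expect_length(amp$masked, 0)                 # shadows visible under MAR

  mnar <- ampute_covariates(cov, 0.5, "MNAR",
                            weights = c(alcohol = 2), seed = 25)
  expect_true("alcohol" %in% mnar$masked)      # hidden from imputers
  expect_error(ampute_covariates(cov, 0.5, "MCAR",
                                 patterns = matrix(FALSE, 1, 1,
                                                   dimnames = list(NULL, "age"))),
               "non-empty")
})

test_that("complete-case analysis drops rows and matches full data when complete", {
  ds <- simulate_dataset(G = 60, n = 50, seed = 31)
  cmf <- filter_low_counts(ds$counts)
  full <- run_de_single_dataset(cmf, ds$covariates, ds$design)
  cc <- cc_analysis(cmf, ds$covariates, ds$design)
  expect_equal(cc$logFC, full$logFC)
  expect_equal(cc$p, full$p)
  expect_equal(attr(cc, "n_used"), 50)

  amp <- ampute_covariates(ds$covariates, 0.3, "MCAR", seed = 32)
  cc2 <- cc_analysis(cmf, amp, ds$design)
  expect_equal(attr(cc2, "n_used"), sum(!apply(amp$miss[, ds$design$terms], 1, any)))
  expect_true(all(c("gene_id", "logFC", "se", "t", "p", "p_adj", "significant")
                  %in% names(cc2)))
})

test_that("single imputation is an identity without missing data and stays in range", {
  ds <- simulate_dataset(G = 60, n = 50, seed = 33)
  cmf <- filter_low_counts(ds$counts)
  full <- run_de_single_dataset(cmf, ds$covariates, ds$design)
  si <- si_analysis(cmf, ds$covariates, ds$design, seed = 1)
  expect_equal(si$logFC, full$logFC)

  amp <- ampute_covariates(ds$covariates, 0.4, "MCAR", seed = 34)
  si2 <- si_analysis(cmf, amp, ds$design, seed = 2)
  imp <- attr(si2, "imputed")
  expect_false(anyNA(imp$data))
  expect_true(all(imp$data$batch %in% c("b1", "b2", "b3")))
})

test_that("forest imputation beats marginal draws on MCAR continuous data", {
  cov <- simulate_covariates(400, seed = 35)
  amp <- ampute_covariates(cov, 0.2, "MCAR",
                           patterns = matrix(TRUE, 1, 1,
                                             dimnames = list(NULL, "age")),
                           seed = 36)
  idx <- which(amp$miss[, "age"])
  visible <- setdiff(colnames(amp$data), amp$masked)
  filled <- seqMI:::.rf_impute(amp$data[, visible], amp$miss[, visible],
                               seed = 37)
  rf_err <- sqrt(mean((filled$age[idx] - cov$data$age[idx])^2))
  set.seed(38)
  marg <- sample(cov$data$age[-idx], length(idx), replace = TRUE)
  marg_err <- sqrt(mean((marg - cov$data$age[idx])^2))
  expect_lt(rf_err, marg_err)
})

test_that("evaluation reproduces its formulas on hand-built inputs", {
  full <- data.frame(gene_id = c("g1", "g2", "g3"),
                     logFC = c(1, 2, 0.1),
                     significant = c(TRUE, TRUE, FALSE))
  ident <- evaluate_methods(list(self = full), full)
  expect_equal(ident$TPR, 1)
  expect_equal(ident$FPR, 0)
  expect_equal(ident$MAPE, 0)

  meth <- data.frame(gene_id = c("g1", "g2", "g3"),
                     logFC = c(1.1, 1.8, 0.1),
                     significant = c(TRUE, TRUE, TRUE))
  ev <- evaluate_methods(list(m = meth), full)
  expect_equal(ev$MAPE, (0.1 / 1 + 0.2 / 2) / 2)       # = 0.10
  expect_equal(ev$FPR, 1 / 3)

  none_true <- full
  none_true$significant <- FALSE
  ev2 <- evaluate_methods(list(m = meth), none_true)
  expect_true(is.na(ev2$TPR) && ev2$tpr_flag)

  silent <- meth
  silent$significant <- FALSE
  ev3 <- evaluate_methods(list(m = silent), full)
  expect_equal(ev3$FPR, 0)
  expect_true(ev3$fpr_flag)
})

test_that("simulated datasets look like bulk RNA-seq", {
  ds <- simulate_dataset(G = 200, n = 60, seed = 41)
  expect_s3_class(ds$counts, "count_matrix")
  expect_equal(dim(ds$counts), c(200L, 60L))
  expect_false(anyNA(ds$covariates$data))
  libs <- colSums(ds$counts$counts)
  expect_gt(sd(log(libs)), 0.1)                  # real library-size spread
  expect_equal(ds$design$contrast, "group")
})
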