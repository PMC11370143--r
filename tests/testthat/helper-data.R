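# Shared generators for small in-code fixtures.

make_counts <- function(G = 30, n = 6, seed = 1, mu = 200, size = 5) {
  set.seed(seed)
  m <- matrix(rnbinom(G * n, mu = mu, size = size), G, n)
  m[rowSums(m) == 0, 1] <- 1L
  count_matrix(m, gene_ids = sprintf("g%03d", seq_len(G)),
               sample_ids = sprintf("s%03d", seq_len(n)))
}

basic_schema <- function() {
  data.frame(
    variable = c("group", "age", "smoke"),
    type = c("binary", "continuous", "binary"),
    role = c("predictor", "adjustment", "adjustment"),
    stringsAsFactors = FALSE)
}

make_covariates <- function(n = 6, seed = 1, miss_age = 0) {
  set.seed(seed)
  df <- data.frame(group = rep(c("a", "b"), length.out = n),
                   age = round(rnorm(n, 40, 8), 1),
                   smoke = sample(c("no", "yes"), n, replace = TRUE))
  if (miss_age > 0) df$age[sample.int(n, miss_age)] <- NA
  covariate_table(df, basic_schema(),
                  sample_ids = sprintf("s%03d", seq_len(n)))
}
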