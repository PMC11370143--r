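---
title: "seqMI: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqMI: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The statistical problem

`seqMI` targets bulk RNA-seq association studies in which some model
covariates are missing for some samples. The per-gene model is an ordinary
linear model on the log-CPM scale,

$$\mathrm{logCPM}_g = \beta_0 + \sum_n \beta_n C_n,$$

with one predictor of interest whose coefficient (a log2 fold change) is
reported. Complete-case analysis discards incomplete samples; single
imputation fills them once and ignores imputation uncertainty. Multiple
imputation is the principled alternative, but validity requires the
imputation model to see the outcome — and here the outcome is a whole
transcriptome. The package's central device is to compress the expression
matrix into a few principal-component scores and place those scores in
every covariate-imputation model: outcome information informs the
imputations without fitting one imputation model per gene, and the
expression data themselves are never imputed.

# The pipeline, step by step

**Filtering.** Genes are kept when their average CPM (raw library sizes —
filtering precedes scale normalization) strictly exceeds
`count_target / (min_i R_i / 1e6)`, translating the conventional ~10-read
cutoff onto the CPM scale so deep samples get no preference. A mean-logCPM
alternative (`method = "mean_logcpm"`, cutoff 0) is exposed because both
conventions are common; the count-target rule is the default.

**Normalization.** TMM scale factors are computed from gene-wise log ratios
against the sample whose upper-quartile CPM is closest to the mean upper
quartile, trimming 30% of M values and 5% of A values from each tail and
weighting by inverse delta-method binomial variances. Genes with a zero
count in either sample of a pair are excluded (undefined log ratio), and
factors are rescaled to geometric mean 1 so effective library sizes
preserve the total scale. The logCPM offsets (0.5 counts, 1.0 library
size) are applied to the *effective* sizes, so the matrix consumed by PCA
and by the precision-weight machinery is the same one the weighted models
analyse.

**PC selection.** PCA treats samples as observations and genes as centered
variables (no unit-variance scaling by default; both are switchable). The
default retention rule is Horn's parallel analysis: each gene's values are
permuted independently across samples (50 permutations), and a component
is kept while its eigenvalue exceeds the 95th percentile of the permuted
eigenvalues at the same rank; retention stops at the first failure so the
kept set is always PC1..PCh. The permutation scheme, percentile and count
follow common parallel-analysis practice and are all arguments. The
variance-cutoff criterion keeps the smallest h reaching 80% cumulative
variance; the elbow criterion keeps up to the point of maximum
perpendicular distance between the variance-explained curve and the chord
joining its endpoints — the standard operationalization of "the elbow".
`h = 0` is possible on structureless data and is honoured downstream
(imputation then runs without expression predictors).

**Imputation.** Chained equations with, per target: Bayesian-draw
("type-2") predictive mean matching for continuous targets (coefficients
drawn from their normal posterior, residual variance from its scaled
inverse-chi-square posterior, 5 donors, uniform pick — so imputed values
are always observed donor values); logistic regression with a posterior
coefficient draw for binary targets; polytomous and proportional-odds
models (class draws from predicted probabilities) for unordered/ordered
categorical targets. Defaults `m = 10` imputed datasets and 10 sweeps per
chain in declared column order; chains are fully independent so
between-imputation variance is honest. Categorical predictors enter other
variables' models as treatment-coded dummies, ordered categoricals as
integer scores. Perfect separation falls back to a ridge-stabilized fit
with a warning. Proper posterior draws make results sign-invariant to PC
score orientation *in distribution* (the model fits are exactly
invariant; the draws consume the same random numbers differently).

**Convergence diagnostics.** Per target variable, a PSRF-style ratio
compares the between-chain spread of per-sweep imputed-value means to the
within-chain spread over the second half of the sweeps; ratios above 1.2
are flagged, and runs with fewer than two recorded sweeps are flagged as
unassessable rather than silently passed.

**Per-dataset analysis.** For each completed covariate table: OLS per gene
on the design, a LOWESS curve (span 0.5, the customary robustness
iterations) of sqrt residual standard deviations against average
log-counts, a piecewise-linear interpolant `lo()` clamped to its terminal
values beyond the knot range (preventing explosive weights at extreme
fitted counts), observation weights `lo(lambda_hat)^-4`, per-gene weighted
least squares, then empirical-Bayes moderation: a scaled
inverse-chi-square prior fitted to the gene-wise variances by moment
matching on log variances (Newton inversion of the trigamma function,
relative tolerance 1e-8). When the log-variances are less dispersed than
chi-square sampling noise the prior df is infinite and all posterior
variances equal the geometric-mean prior scale. Moderated standard errors
and moderated dfs (residual + prior) are what pooling consumes — the only
reading under which the pooled t-statistics use the moderation at all.

**Pooling.** Rubin's rules per gene, with the Barnard-Rubin adjusted df
combining `df_old = (m-1)/lambda^2` and
`df_obs = (df+1)/(df+3)·df·(1-lambda)` harmonically; `df` is the mean
moderated df across imputations, unweighted. `lambda` is floored at 1e-12
before `df_old` so the no-missingness limit (`df_adjusted = df_obs` at
`lambda = 0`) is reached smoothly; infinite moderated dfs propagate
through the harmonic form without NaNs. Two-sided p-values from the
t-distribution, BH-FDR across genes, significance at FDR < 0.05 — all
thresholds are arguments.

With a complete covariate table every imputed dataset is identical, so the
pipeline collapses exactly to the single-dataset analysis with the
`lambda = 0` df adjustment; the test suite asserts this identity to
machine precision.

**Gene-bin variant.** `mi_de_per_bin()` randomly permutes the genes,
slices them into bins of `bin_size` (default 10 — small enough to keep
per-bin imputation models identifiable at typical cohort sizes; the final
bin holds the remainder), uses each bin's logCPM values directly as
imputation predictors, analyses the bin's genes alone and concatenates,
applying a single global BH adjustment at the end. Failed bins are
reported as NA rows, not fatal. Per-bin LOWESS trends on ~10 genes are
noisier than the global trend; that is inherent to the variant.

# The simulation framework

**Counts.** Negative-binomial with log-normal gene abundances, log-normal
library sizes (sdlog 0.35) and log-normal gene-wise dispersions (BCV
around 0.28) — typical of human bulk data. Default library sizes centre on
3e5 for the default 500-gene panel: the panel is treated as a
transcriptome subsample, so per-gene depth (~600 reads), not total depth,
is matched to practice.

**Covariates.** Five variables from a latent Gaussian with exchangeable
correlation 0.3: a binary predictor (`group`), continuous `age` and
3-level categorical `batch` as adjustment covariates, binary `alcohol`
(30% prevalence) and continuous `income` as shadow variables that drive
simulated missingness but never enter the expression model.

**Signal.** A fraction of genes (benchmark levels 25/50/75/99% null) get
log2 fold changes with gamma(shape = 1) magnitudes. Gamma magnitudes are
positive, so signs are randomized by default (a flag disables this) —
two-sided testing should be exercised. Signal is planted by binomial
thinning: per-cell probabilities `2^(beta_g x_i - max_i beta_g x_i)` so
probabilities stay in (0, 1] and the induced coefficient equals the
planted one in expectation, while inter-gene correlation and count
character survive. Binary predictors are coded 0/1 (coefficients are
between-group log2 fold changes); continuous predictors are standardized
(per-SD coefficients). Small normal effects (sd 0.2) of the adjustment
covariates are thinned in on top by default so adjustment actually
matters; thinning composes, so this is exact.

**Amputation.** A target fraction of samples gets at least one missing
cell, each receiving a pattern drawn over the adjustment covariates (one
single-variable pattern per covariate by default). MCAR selects uniformly;
MAR/MNAR select through a logistic link on a standardized weighted sum of
the scoring variables, the intercept calibrated by root finding so the
expected selected fraction equals the target. Under MNAR the scoring
variables are recorded as masked and every imputer in the package honours
the mask; under MAR they stay visible. The predictor of interest is never
amputed.

**Evaluation.** Truth = genes at FDR < 0.05 in the full-data model. TPR is
the proportion of true DEGs recovered; FPR the proportion of a method's
significant calls that are not true DEGs (reported as 0 with a flag when
nothing is called); MAPE the mean of `|beta_truth - beta|/|beta_truth|`
over true DEGs (NA with a flag when the truth set is empty).

**Baselines.** CC drops incomplete rows before the standard chain. SI is
an iterative random-forest imputation (100 trees, up to 10 sweeps,
stopping when the normalized change in imputed cells stops decreasing)
over the covariates only — with one completed dataset there is no
between-imputation variance to absorb outcome-driven correlation, so the
outcome must stay out of the SI predictor set.

# What the tests do and do not show

The simulation suite exercises the pipeline at deliberately desk-sized
problems — pooling oracles at 10^4 random inputs, calibration checks at
n = 1000 samples, and end-to-end benchmarks at G = 500 genes, n = 200
samples, 10 replicates (smaller for unit tests). The generator emulates
library-size spread, overdispersion, correlated mixed-type covariates and
mechanism-specific missingness, but not batch structure, gene-gene
correlation beyond what thinning preserves from the NB draw,
heavy-tailed outliers, or the scale of a real transcriptome (tens of
thousands of genes, where PC estimation and FDR behave somewhat
differently). Passing tests therefore demonstrate correctness of the
machinery and the method's operating characteristics under these
conditions, not performance guarantees on any particular cohort.

# Known limitations

- Only a single-coefficient contrast is supported; multi-level categorical
  predictors of interest and F-type contrasts are out of scope.
- Imputation models are main-effects GLMs (plus PC scores); no
  interactions, multilevel structure or random-forest MI.
- Variance moderation has no trend or robust variants.
- Horn's analysis permutes genes independently, which ignores gene-gene
  correlation under the null; with strongly correlated null data it can
  retain an extra component.
- The chained-equations sampler is a Gibbs-style approximation; with
  badly incompatible conditionals (rare with these model families) the
  stationary distribution is not a joint model.
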