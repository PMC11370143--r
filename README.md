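# seqMI

Differential expression analysis for RNA-seq studies with **missing
covariate data**, by PCA-augmented multiple imputation.

## The problem

Bulk RNA-seq association studies model each gene's expression on a
predictor of interest while adjusting for covariates (batch, age, exposure
variables, ...). In real cohorts those covariates are often incomplete.
The common fixes are both unsatisfying: complete-case (CC) analysis throws
away every sample with any missing cell — losing power and risking bias
when missingness is not completely random — while single imputation (SI)
fills the gaps once and then pretends the filled values were observed,
understating uncertainty. Proper multiple imputation (MI) should use the
outcome when imputing, but with tens of thousands of genes there are tens
of thousands of outcomes, and per-gene imputation models are impractical.

`seqMI` implements the MI-PCA approach: compress the expression matrix
into a handful of principal-component scores, add those scores to every
covariate-imputation model, and let the completed datasets flow through a
standard precision-weighted differential-expression analysis whose results
are pooled with Rubin's rules. The expression data themselves are never
imputed.

## The method

For counts *r<sub>gi</sub>* (gene *g*, sample *i*) with library sizes
*R<sub>i</sub>* = Σ<sub>g</sub> *r<sub>gi</sub>* (TMM scale-normalized):

1. **Filter & normalize.** Keep genes whose average CPM exceeds
   `count_target / (min Rᵢ / 10⁶)`; compute
   logCPM<sub>gi</sub> = log₂((r<sub>gi</sub>+0.5)/(R<sub>i</sub>+1)·10⁶)
   on the effective (TMM-scaled) library sizes.
2. **PC selection.** PCA of the logCPM matrix (samples as observations);
   retain *h* PCs by Horn's parallel analysis (default), an 80%
   cumulative-variance cutoff, or the elbow criterion.
3. **Impute.** Chained-equations multiple imputation of the covariates,
   *m* times, with all covariates **plus PC1..PCh** in every predictor
   model: predictive mean matching (continuous), logistic (binary),
   polytomous (unordered categorical), proportional odds (ordered).
4. **Analyse each completed dataset.** Voom-style observation weights
   lo(λ̂<sub>gi</sub>)⁻⁴ from a LOWESS mean-variance trend, per-gene
   weighted least squares, empirical-Bayes variance moderation.
5. **Pool.** Rubin's rules per gene — β̄, V_W, V_B,
   V_Total = V_W + (1+1/m)V_B, t = β̄/√V_Total, λ = (V_B+V_B/m)/V_Total —
   with Barnard-Rubin adjusted degrees of freedom and BH-FDR across genes.

A gene-binning variant (`mi_de_per_bin()`) imputes per small bin of genes
with the bin's own logCPM values as predictors. CC (`cc_analysis()`) and
iterative random-forest SI (`si_analysis()`) baselines, plus a simulation
framework (negative-binomial counts, binomial-thinning signal injection,
MCAR/MAR/MNAR covariate amputation, TPR/FPR/MAPE scoring) support
benchmarking all of them against the full-data model.

## Worked example

```r
library(seqMI)
ds  <- simulate_dataset(G = 500, n = 120, null_fraction = 0.75, seed = 11)
amp <- ampute_covariates(ds$covariates, prop = 0.40, mechanism = "MAR", seed = 12)
amp
#> covariate_table: 120 samples x 5 variables (46 missing cells)
#>  variable                  type       role
#>     group                binary  predictor
#>       age            continuous adjustment
#>     batch categorical_unordered adjustment
#>   alcohol                binary     shadow
#>    income            continuous     shadow

fit <- run_mi_pca_pipeline(ds$counts, amp, ds$design, m = 10, seed = 13)
fit
#> mi_pca_result: 465 genes, m = 10 imputations, h = 3 retained PCs,
#>   87 significant (FDR < 0.05)

head(fit$results[order(fit$results$p_adj),
     c("gene_id", "logFC", "se_pooled", "t", "lambda", "p_adj")], 3)
#>       gene_id logFC se_pooled     t   lambda    p_adj
#> 262 gene_0279 -3.21    0.0689 -46.6 1.40e-03 3.89e-78
#> 433 gene_0464 -4.81    0.1164 -41.3 2.01e-05 2.28e-72
#> 143 gene_0153 -5.15    0.1254 -41.0 4.76e-04 3.32e-72
```

`logFC` is the pooled log₂ fold change of the `group` predictor,
`se_pooled` its total-variance standard error, and `lambda` the fraction
of that variance attributable to missing data (tiny here: the retained PCs
carry most of the information the missing covariates held). The top gene's
planted effect was |log₂FC| = 3.32, recovered as 3.21. 40% of samples had
a missing covariate, yet no sample was discarded.

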