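# bbcluster

Phenotype clustering and treatment-effect heterogeneity for beta-blocker
trials in heart failure with reduced ejection fraction (HFrEF).

## The problem

Beta blockers reduce all-cause mortality in HFrEF patients in sinus rhythm
(SR) but show no average benefit in patients with atrial fibrillation (AF),
and single baseline characteristics fail to explain who responds. This
package implements an unsupervised pipeline for discovering patient
phenotypes in pooled individual patient data from randomised
placebo-controlled trials, and for estimating the randomised treatment
effect within each discovered phenotype:

1. **Cohort preparation** — exclusion of LVEF ≥ 50% and paced/other/missing
   rhythm (atrial flutter pooled with AF), complete-case filtering on a
   prespecified baseline variable set (age, sex, BMI, heart rate, systolic
   blood pressure, LVEF, previous MI, NYHA class III/IV, creatinine, and
   drug therapy: ACEi/ARB, diuretic, anticoagulant, digoxin), stratification
   by baseline ECG rhythm, and standardisation into a typed feature matrix
   (13 columns: 6 continuous, 7 binary).
2. **Embedding** — a mixed-likelihood variational autoencoder (gaussian
   likelihood with learned per-column variance for continuous variables,
   bernoulli for binary ones) trained by maximising the evidence lower bound
   `ELBO = E_q[Σ_j log p(x_j | z)] − KL(q(z|x) ‖ N(0, I))`,
   with a linear PCA baseline for comparison.
3. **Clustering and objective model selection** — Ward hierarchical
   clustering and k-means++ on the latent posterior means; the latent
   dimension d and the number of clusters k are selected by maximising the
   gap statistic
   `Gap(k) = (1/B) Σ_b log W*_kb − log W_k`,
   where `W_k = Σ_r (1/2n_r) Σ_{i,i'∈C_r} ‖x_i − x_i'‖²` and the reference
   datasets are uniform over the data's principal-axis-aligned bounding box.
   Mean silhouette, Calinski–Harabasz and Davies–Bouldin are reported
   alongside.
4. **Robustness** — repeated re-clustering of random subsets (bootstrap),
   scored by the cluster-size-weighted best-match Jaccard overlap against
   the reference partition and compared with a proportion-preserving
   random-assignment null via the two-sample Kolmogorov–Smirnov test.
5. **External validation** — leave-one-trial-out: refit on the remaining
   trials, predict membership for the held-out trial by nearest latent
   centroid, and score agreement with the Adjusted Rand Index against a
   label-permutation null.
6. **Treatment effects** — per-cluster intention-to-treat 2×2 mortality
   tables: odds ratio with Woolf (log-OR) 95% CI and chi-square p, risk
   ratio, absolute risk reduction with Wald CI, number needed to treat
   (NNT = 1/ARR, reported only when the ARR interval excludes 0), and
   annualised mortality per 100 person-years.

Because the original trial data cannot be shared, the package ships a
calibrated **synthetic cohort generator** (`default_cohort_spec()`,
`generate_cohort()`): nine trials, ~15 659 patients with marginals matched
to the published pooled cohort, planted latent phenotypes expressed as
covariate shifts, and cluster-specific treatment log odds ratios on
mortality. Every pipeline stage is exercised end-to-end against this
generator, with the planted structure as ground truth.

## Worked example

```r
library(bbcluster)

spec   <- default_cohort_spec(separation = 4, n_scale = 0.312, seed = 1)
cohort <- generate_cohort(spec)
prep   <- prepare_cohort(cohort)

fit <- phenomap(prep$strata$SR$table, d_grid = 2, k_grid = 2:8,
                method = "kmeanspp", B = 20, seed = 2,
                vae_args = list(epochs = 40, hidden = c(32, 32), batch_size = 256))
fit
#> phenomap (vae embedding, kmeanspp clustering): d* = 2, k* = 6
#>   3996 patients; cluster sizes 231/307/813/473/985/1187; gap 1.3291 (se 0.0078)

adjusted_rand_index(fit$solution$labels, prep$strata$SR$table$true_cluster)
#> [1] 0.922

cluster_effect_table(prep$strata$SR$table, fit$solution$labels, prefix = "SR")
#>   cluster   or or_low or_high   nnt annualised_mortality
#> 1   SRall 0.69   0.58    0.82 20.96                 7.79
#> 2     SR1 1.18   0.42    3.29    NA                 3.59
#> 3     SR2 0.41   0.17    1.03 16.77                 3.73
#> 4     SR3 0.71   0.46    1.11    NA                 5.90
#> 5     SR4 0.44   0.24    0.79 11.72                 6.60
#> 6     SR5 0.71   0.49    1.02    NA                 7.18
#> 7     SR6 0.71   0.54    0.93 16.35                12.02
```

The gap statistic selects six clusters (the number planted by the
generator), the recovered labels agree with the planted phenotypes at
ARI 0.92, and the per-cluster odds ratios scatter around the planted
treatment effects with the pooled SR effect at OR 0.69. Clusters are
numbered in ascending order of observed mortality; `NA` in the NNT column
means the absolute risk reduction was not statistically significant in that
(small) cluster.

Effect measures can also be computed directly from published per-cluster
counts:

```r
effect_table_from_counts(published_counts())
#>   cluster   or or_low or_high   nnt
#>     SRall 0.74   0.67    0.81 24.96
#>     ...
#>       AF2 0.57   0.35    0.93 17.37
```

which reproduces the published pooled-trial odds ratios (SR all 0.74,
95% CI 0.67–0.81; AF2 0.57, 0.35–0.93) and NNTs (SR all 25, AF2 17.4).

Stability and external validation:

```r
st <- bootstrap_stability(fit, n_boot = 100, frac = 0.8, seed = 3)
lt <- leave_one_trial_out(prep$strata$SR$table, d = 2, k = 6, seed = 4)
```

`run_pipeline(run_config(...))` chains every stage for one or both rhythm
strata and serialises labels, gap matrices, effect tables, profiles and
radar figures to an output directory.

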