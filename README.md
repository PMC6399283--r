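# rfclust

Risk-factor-based clustering (RFC) of type 2 diabetes susceptibility.

## The problem

Type 2 diabetes develops heterogeneously: subpopulations defined by
combinations of ordinary risk factors differ several-fold in how often
they have, and will develop, the disease. `rfclust` implements a
data-driven way to find those subpopulations from five routinely
collected risk factors — sex, age, body mass index (BMI), hypertension
(HTN), and family history of diabetes (FHDM) — and to characterise and
reuse them:

1. **Dissimilarity.** Participants are compared with the Gower
   coefficient for mixed data,

   d(i, j) = Σ_v w_v δ_v(i,j) d_v(i,j) / Σ_v w_v δ_v(i,j),

   where numeric variables contribute |x_iv − x_jv| / range_v and
   binary risk factors are *asymmetric*: a pair that merely shares the
   absence of a risk factor (0–0) is dropped from the average
   (δ_v = 0), so only shared presence counts as similarity.
2. **Clustering.** Complete-linkage agglomeration of the dissimilarity
   matrix gives a dendrogram; cutting it at k yields k clusters.
3. **Choosing k.** For each candidate k, a 2 × k table of
   nondiabetic/diabetic counts per cluster is tested with a Pearson
   chi-square (df = k − 1, p-values kept in log space). The selected k
   maximises the heterogeneity significance over the scan range
   (a sequential first-drop variant is available).
4. **Transfer.** An RBF-kernel SVM trained on (risk factors → cluster)
   assigns new cohorts to the discovery clusters without re-clustering.
5. **Characterisation.** Kaplan–Meier disease-free curves, log-rank
   tests and cumulative incidence on follow-up data; two-way ANOVA
   (cluster × diabetes status, with interaction) for biomarkers;
   cluster-specific logistic risk scores with ROC/AUC, DeLong
   comparisons, and fasting-glucose threshold sweeps.

The cohorts the method was developed on are access-restricted, so the
package ships a synthetic-cohort generator (`default_discovery_spec()`,
`generate_cohort()`, `generate_followup()`, `generate_biomarkers()`)
parameterised by the published per-cluster composition (n = 10,023 in
six clusters), which makes every stage of the pipeline testable.

## Worked example

```r
library(rfclust)

## a synthetic cohort with the published six-cluster composition
cfg <- simulation_config(seed = 1)
cohort <- generate_cohort(cfg)

## Gower distance -> complete linkage -> heterogeneity-selected k
res <- run_discover(cohort)
print(res$k_selection)
#> Selected k = 7 (heterogeneity maximum)
#>   k statistic df log10_p
#>   2     323.3  1  -71.56
#>   3     329.0  2  -71.44
#>   4     331.2  3  -70.75
#>   5     336.3  4  -70.79
#>   6     450.2  5  -94.34
#>   7     460.2  6  -95.51
#>   8     460.3  7  -94.56
#>   ...
print(res$table)
#> Diabetes status by cluster (2 x 7)
#>        1    2   3    4   5    6   7
#> ndm 1162 2923 459 1010 688 2019 146
#> dm   126  318  70  171 174  626 131
#> prevalence: 1=0.10  2=0.10  3=0.13  4=0.14  5=0.20  6=0.24  7=0.47
```

The trace shows the chi-square heterogeneity of diabetes prevalence at
each cut: significance jumps when the six planted clusters are resolved
(the 6-cut statistic, 450.2, is essentially the published 450.9) and
decays in df beyond the peak, and the selected cut orders clusters from
~0.10 to ~0.47 prevalence — the published spread is 0.09–0.44, or
4.9-fold. On sampled cohorts the peak lands on 6 or 7 depending on the
seed: splitting one planted cluster in two costs almost nothing in the
statistic, so the peak position is noisy around the true value.

The printed discovery table itself is available as a fixture:

```r
het <- chi_square_heterogeneity(published_cluster_counts("discovery"))
print(het)
#> Chi-square heterogeneity: X2 = 450.9, df = 5, log10(p) = -94.50
signif(het$p_value, 3)
#> [1] 3.16e-95
```

Transfer to an independent cohort and downstream characterisation:

```r
model <- train_cluster_classifier(cohort, res$assignment, seed = 1)
validation <- generate_cohort(simulation_config(seed = 2))
val <- run_validate(model, validation)

fu <- generate_followup(cohort, cfg)
km <- km_curves(fu, res$assignment)
logrank_test(fu, res$assignment)

bio <- generate_biomarkers(cohort, cfg)
keep <- bio$prior_dx == 0      # never previously diagnosed
two_way_anova(bio$fg[keep], res$assignment[keep], bio$dm[keep])
```

## Limitations

See the methods vignette (`vignettes/rfclust.Rmd`) for the model
assumptions, the free parameters of the synthetic generator, and an
analysis of when the cluster-count selection is unstable on sampled
cohorts.
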