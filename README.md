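# fuzzyfda

Fuzzy k-medoids clustering of longitudinal mobile-health symptom curves,
with penalized B-spline smoothing, fuzzy-silhouette model selection, and a
permutation-based index relating patient curves to pollen exposure.

## The problem

Patients with seasonal allergic rhinoconjunctivitis can grade their
symptoms and medication use daily in an mHealth app. Each patient-day
yields a Combined Symptom and Medication Score,

    CSMS = ARTSS + RMS ∈ [0, 6],

where ARTSS is the mean of six symptom grades (sneezing, rhinorrhea,
pruritus, nasal congestion, ocular pruritus, lacrimation; each 0–3) and
RMS is the strongest medication category taken that day (0 = none,
1 = antihistamine, 2 = nasal corticosteroid, 3 = oral corticosteroid).
Such diaries are noisy, irregularly missing, and short (a 30–40 day pollen
season). The clinical question is whether the cohort splits into groups
with distinct severity trajectories — and whether any group's trajectory
tracks a specific pollen.

## The method

1. **Score, filter, impute.** Daily records become per-patient CSMS
   series. Patients missing more than a cut-off fraction of days (default
   37.5%) or recording constant values are excluded; remaining gaps are
   filled by edge carry and linear interpolation. Scores are divided by 6
   and pollen counts by their seasonal maximum, so all curves live on
   [0, 1].
2. **Smooth.** Each series y_ij is represented as a functional
   x_i(t) = Σ_p c_ip φ_p(t) on a shared B-spline basis (order m, q
   equally spaced interior knots, dimension s = q + m), fitted by
   penalized least squares SSE + λ∫[D²x_i(t)]²dt. A grid search picks
   (q, m) and a single shared λ = 10^g by minimizing the total
   generalized cross-validation score TGCV(q, m) = Σ_i GCV_i, with
   GCV_i = v·SSE_i/(v − df(λ))².
3. **Cluster.** Fuzzy k-medoids on the coefficient rows c_i: minimize
   Σ_i Σ_l u_il^f d²(c_i, h_l) subject to row-stochastic memberships
   u_il and prototypes h_l constrained to observed units, by alternating
   the weighted-medoid and closed-form membership updates from multiple
   random starts (fuzziness f = 1.5 by default; a fuzzy k-means variant
   `fkm()` drops the medoid constraint). The number of clusters is chosen
   by the fuzzy silhouette FS(k), a membership-gap-weighted mean of the
   silhouette values.
4. **Associate.** For each patient and pollen taxon, the Spearman
   correlation between their curve coefficients is tested one-sidedly by
   a 10,000-permutation test; each patient's significant positive
   correlations are normalized into the ARp index (0 where
   non-significant, summing to 1 over significant taxa), then summarized
   per cluster with membership weights.

A synthetic-cohort generator (`generate_cohort()`) plants known cluster
templates, noise, MCAR missingness and matched pollen curves so the whole
chain is testable without patient data.

## Worked example

```r
library(fuzzyfda)

cohort <- generate_cohort(cohort_design(n_per_cluster = 20L, seed = 11))
cfg <- pipeline_config(q_options = c(10L, 20L), m_options = 4L,
                       g_min = -8, g_max = 8, g_step = 0.25,
                       k_range = 2:5, n_starts = 10L, n_perm = 999L,
                       seed = 11)
res <- run_pipeline(cohort$records, pollen = cohort$pollen, config = cfg)
print(res$selection$table)
#>  k        FS         S objective
#>  2 0.7978894 0.7595806 38.798414
#>  3 0.9228315 0.9219562  6.387932
#>  4 0.8540563 0.8122879  4.461183
#>  5 0.8213327 0.7315596  4.165260
print(res)
#> Pipeline: 60 patients retained, basis m = 4 / q = 20, k = 3
#> Fuzzy medoid partition: n = 60, k = 3, f = 1.5, objective = 6.38793 (converged in 4 iterations)
#> Cluster sizes (max membership): 20, 20, 20
#> Cluster mean ARp:
#>           grass olive nettle
#> Cluster 1 0.651 0.349      0
#> Cluster 2 0.720 0.180      0
#> Cluster 3 1.000 0.000      0
#> Total     0.790 0.177      0
```

The fuzzy silhouette peaks at k = 3 (FS = 0.92), the three planted
clusters of 20 patients are recovered exactly (ARI = 1 against the
generator's labels), and the cluster built around the pollen-tracking
template carries a mean ARp of 1.00 for the matched grass taxon — every
one of its patients is significantly, and exclusively, associated with
that pollen curve — while the flat-profile clusters show no such
concentration.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fuzzyfda.R simulate --out sim --seed 3
Rscript inst/cli/fuzzyfda.R pipeline --records sim/records.tsv \
    --pollen sim/pollen.tsv --out run --seed 3
```

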