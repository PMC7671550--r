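---
title: "Fuzzy k-medoids clustering of functional symptom curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy k-medoids clustering of functional symptom curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyfda)
```

This vignette explains the statistical model behind `fuzzyfda`, the
assumptions it makes, the parameters a user may want to change, and the
design decisions taken where more than one reasonable implementation
existed.

## From diaries to curves

A patient's daily diary yields the combined symptom and medication score
CSMS = ARTSS + RMS, where ARTSS averages six 0–3 symptom grades and RMS
is the 0–3 category of the strongest drug taken. Three conventions govern
missing entries:

* a day with all six symptoms but no medication entry counts as "no
  medication" (RMS = 0) — patients rarely log the absence of a drug;
* a day with *any* symptom grade missing has no defined ARTSS and is a
  missing day (we never part-fill the average);
* a day with no entry at all is missing.

Patients whose missing fraction exceeds a cut-off (default 0.375,
inclusive: a patient exactly at the boundary is retained) are excluded,
as are zero-variance recorders — a diary that never changes, including
the all-zero diary of a patient who logged nothing day after day, carries
no trajectory information and would otherwise anchor a degenerate
cluster. Remaining gaps are imputed: leading/trailing gaps carry the
nearest observation, interior gaps are linear between their flanking
observations. The imputation is idempotent and never touches observed
values. The cut-off is evaluated *after* the RMS = 0 convention, since
that convention turns symptom-only days into complete days.

CSMS values are divided by 6 and each pollen series by its seasonal
maximum, so all curves are comparable on [0, 1].

## Penalized B-spline smoothing

Each series is modelled as noisy evaluations of a smooth function,
`y_ij = x_i(t_ij) + ε_ij`, with `x_i(t) = Σ_p c_ip φ_p(t)` on a B-spline
basis of order `m` (degree + 1) with `q` equally spaced interior knots on
the observation window. The basis dimension is `s = q + m` — the standard
count for a knot sequence whose boundary knots are repeated to order `m`.
(Counting conventions that add one more function correspond to a
different treatment of the boundary knots and do not match the q = 15,
m = 4 bases of daily-diary windows; we flag this because off-by-one
conventions are a recurring source of confusion with spline software.)

Coefficients minimize the penalized criterion

    PENSSE_λ = ‖y_i − Φ c_i‖² + λ c_iᵀ R c_i,
    R_pp' = ∫ D²φ_p(t) D²φ_p'(t) dt,

with identity error weights. `R` is computed *exactly* by Gauss–Legendre
quadrature with `m` nodes per inter-knot interval (the integrand is a
piecewise polynomial of degree `2(m − 3)`, so this quadrature has no
truncation error); its nullspace is the straight lines, which are never
penalized.

**Numerical route.** The fit is solved through the QR factorization of
the augmented design `rbind(Φ, √λ L)` with `LᵀL = R`, not through the
normal equations `ΦᵀΦ + λR`: when λ is extreme (the GCV grid spans
`10^-30` to `10^20`), forming the normal-equations matrix rounds the
`ΦᵀΦ` contribution away entirely and with it the information that
determines the fit inside the penalty's nullspace. The augmented QR keeps
the large-λ limit accurate — at `λ = 10^20` the fitted curve matches the
ordinary least-squares straight line to ~1e−7 and `df(λ)` reaches 2 —
while behaving identically to the usual solve at moderate λ. `df(λ)` is
the trace of the hat matrix `Φ(ΦᵀΦ + λR)⁻¹Φᵀ`, computed from the
triangular factor. A rank-deficient system (e.g. λ = 0 with more basis
functions than observations) is flagged and assigned infinite GCV rather
than a pseudo-inverse fit, since such a fit's GCV denominator is
meaningless.

**Model selection.** GCV_i = v·SSE_i/(v − df(λ))² uses the per-unit
number of observations `v`; the cohort criterion TGCV(q, m) = Σ_i GCV_i
is minimized over a shared λ = 10^g grid (defaults g ∈ [−30, 20] step
0.05) for each candidate (q, m) (defaults q ∈ {5, 10, 15, 20},
m ∈ {4, 6}). All units share (q, m, λ) so their coefficient vectors are
directly comparable in the clustering step. Ties in λ go to the larger
smoothing (the grid is scanned from small to large λ and only strict
improvements are kept — at equal GCV the smoother fit wins). Because one
λ-grid QR factorization serves the whole cohort at once, the full default
grid costs seconds, not minutes. A `parsimony_tol` argument lets the user
select a simpler (q, m) whose TGCV is within a stated slack of the
minimum; the override is recorded in the result.

## Fuzzy k-medoids on the coefficients

The clustering minimizes

    Σ_i Σ_l u_il^f d²(c_i, h_l)

over row-stochastic memberships `U` and prototypes `h_l` constrained to
be observed coefficient rows (medoids), with `d²` squared Euclidean
distance. Alternating updates are closed-form: the medoid of cluster `l`
is the unit minimizing the `u^f`-weighted sum of squared distances, and
`u_il ∝ d²(c_i, h_l)^{−1/(f−1)}` with a unit at zero distance from a
medoid taking membership 1 there (medoid rows are exactly one-hot).
Convergence is declared when the Frobenius norm of successive membership
matrices falls below `tol` (default 1e−6); the objective is
non-increasing throughout.

Design decisions in this module:

* **Initialization.** Each restart draws `k` distinct random units as
  provisional medoids and starts from the memberships they induce. We
  first tried rows drawn uniformly on the simplex; those starts
  concentrate near the uniform-membership configuration, from which the
  weighted-medoid update almost always steps to the same central units —
  on weakly separated two-cluster instances only 44/50 runs reached the
  exhaustive-enumeration optimum, versus 50/50 for medoid-seeded starts.
  The package exposes `global_oracle_fkmed()` (full enumeration of medoid
  subsets, `n ≤ 15`) precisely so this kind of claim can be checked.
* **Medoid collisions.** The per-cluster argmin can name the same unit
  for two clusters; distinctness is restored by letting the cluster with
  the lower weighted cost keep the unit while the other takes its
  next-best candidate (clusters resolved in order of best achievable
  cost), and an update that would raise the objective under the current
  memberships is rejected in favour of the previous medoids — this guard
  is what makes the monotonicity guarantee unconditional.
* **Ties** in the medoid argmin break toward the smallest unit index, so
  runs are reproducible under a seed.
* **Defaults** `f = 1.5`, `n_starts = 30`, `max_iter = 1000`,
  `tol = 1e−6`. Fuzziness beyond ~1.5 is not recommended for medoid-based
  algorithms; as `f → 1` the partition hardens, and for large `f`
  memberships approach `1/k`. That large-`f` limit is exact only where
  units' distance ratios to the medoids are moderate (at `f = 20` the
  membership exponent is 1/19, so a unit ten times closer to one medoid
  still deviates from `1/k` by ~0.03); our tests therefore check the
  limit on a near-equidistant configuration and check monotone shrinkage
  of the deviation elsewhere.

`fkm()` is the centroid variant: prototypes become the `u^f`-weighted
means of the units, everything else unchanged. Both functions accept raw
observed series as rows just as well as spline coefficients, which is how
raw-data comparators are run.

## Choosing k, and comparing partitions

For a hard partition, the silhouette of unit `i` is
`s(i) = (b(i) − a(i))/max(a(i), b(i))` with `a(i)` the mean distance to
its own cluster's other members and `b(i)` the smallest mean distance to
another cluster; a unit alone in its cluster takes the neutral value 0.
The fuzzy silhouette weights each `s(i)` by `(u_ig − u_ig')^γ`, the gap
between the unit's two largest memberships (default γ = 1), after
hardening by maximum membership (ties to the lowest cluster index). With
one-hot memberships, or γ = 0, it reduces exactly to the mean silhouette.
`select_k()` maximizes FS(k) over a k range but also reports every k
within a tolerance of the maximum — a mechanical argmax can hide a
slightly-lower-FS solution with more clinical structure, so near-ties are
surfaced rather than suppressed. Silhouette distances default to squared
Euclidean (matching the clustering objective); plain Euclidean is a flag.

Partition agreement is measured by the adjusted Rand index on hardened
labels (computed via `mclust`).

## Pollen association: the ARp index

For patient `i` and pollen `u`, the Spearman correlation `r_iu` between
their curve *coefficients* is tested against `r ≤ 0` by a permutation
test (default 10,000 permutations; the pollen curve is smoothed with the
same basis and λ as the patients, so both coefficient vectors index the
same basis functions). Spline coefficients are serially dependent, which
invalidates the parametric correlation test; permutation only requires
exchangeability under the null. The p-value uses the add-one estimator
`(1 + #{r_perm ≥ r_obs})/(n_perm + 1)`, which cannot return 0. Then

    ARp_iu = 0                        if p_iu > α,
    ARp_iu = r_iu / Σ_{u': p_iu' ≤ α} r_iu'   otherwise,

so a patient's significant entries sum to 1 and each lies in [0, 1]
(the one-sided test makes significant correlations positive, so the
ratio's denominator is a sum of positive terms). Cluster summaries
average ARp within each maximum-membership cluster, weighted by the
membership degrees, and report the share of patients with ARp = 1;
cluster-level means need not sum to 1 across pollens. No multiplicity
correction is applied across the patient × pollen table — the index is
descriptive, not confirmatory.

## The synthetic cohort generator

`generate_cohort()` plants known structure so every stage is testable:
per-cluster template curves on [0, 1] (`flat-low`, `flat-high`,
`peak-then-decline`, `pollen-tracking`), patient-level multiplicative
amplitude jitter (sd 0.1) and time-shift jitter (sd 1.5 days), additive
Gaussian noise (default sd 0.05 on the [0, 1] scale), MCAR missingness
(default rate 0.1), and pollen curves whose first taxon is the seasonal
bump the tracking template follows (peak 400 grains/m³, matching a
prolific olive/grass season; two further taxa peak off-season or
late-season). Defaults emulate a 40-day seasonal study with three
clusters of 30 patients. Template levels were set so the three canonical
shapes are mutually comparably separated in L2 over the window — the
bump only spans part of the season, so its amplitude (0.80) must exceed
the flat-level gap (0.45) for the three planted clusters to be equally
distinguishable; with unequal separations the fuzzy silhouette correctly
prefers the merged two-cluster solution, which would test the index, not
the pipeline.

Each daily value is decomposed back into a valid app record: the
medication category absorbs the part of the raw CSMS target above the
symptom scale, and the remaining ARTSS target is spread over six integer
0–3 grades as evenly as possible. Since the ARTSS of integer grades has
granularity 1/6, the recovered CSMS matches the target within 1/12 on the
raw scale (1/72 normalized); finer decompositions are impossible with
integer grades.

What the generator does *not* emulate: informative (MNAR) missingness,
weekday/reporting-fatigue patterns, measurement error in pollen counts,
within-season regime changes, or heavy-tailed noise. Tests passing on
these cohorts demonstrate that the chain recovers structure of the
planted kind at realistic noise and missingness — not that real diaries
contain such structure.

## Problem sizes used by the test suite

The suite and the acceptance script run at sizes chosen to exercise every
claim while remaining desk-scale: 50 two-cluster enumeration-oracle
instances (n = 12, s = 3), 20 planted three-cluster cohorts (90 patients,
40 days) for recovery and k selection, 2000 null replicates at 999
permutations for the test's type-I error, and a coarse λ grid
(g ∈ [−8, 8] step 0.25, q ∈ {10, 20}, m = 4) for cohort-level searches —
the full default grid is exercised where a single cohort is smoothed.

## Known limitations

* The medoid constraint makes the objective combinatorial; multi-start
  alternation carries no global guarantee (the enumeration oracle bounds
  this empirically at small n).
* A single shared λ across patients trades per-patient adaptivity for
  comparability of coefficients; strongly heterogeneous smoothness across
  patients would be misfit.
* The ARp index ignores time lags between exposure and symptoms and
  applies no multiplicity control.
* Hardening by maximum membership discards the very fuzziness the method
  estimates; summaries weighted by membership degrees mitigate but do not
  remove this.
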