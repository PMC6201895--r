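---
title: "Methods: from response sequences to attention-quality levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from response sequences to attention-quality levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnquality)
```

## The measurement model

The package analyzes selective-attention test sessions in which a
participant works through a stream of non-semantic symbols for two
12-minute tasks, producing an ordered *response sequence*: at each event a
symbolic decision $y_i \in \{Y, N, I\}$ (yes / no / ignore), a correctness
flag, and a reaction time $\tau_i > 0$ in milliseconds. Three intrinsic
qualities are extracted per participant:

* **Attention span — $W$** (normalized number of decisions). With the
  session length fixed, the number of decisions $I$ measures processing
  speed. It is min-max normalized, $W = (I - I_{\min})/(I_{\max} -
  I_{\min}) \in [0,1]$, either against the cohort's own range (default) or
  against the test's design range $[200, 800]$.
* **Attention stability — $H$** (Hurst exponent). The reaction-time series
  is analyzed by rescaled-range (R/S) analysis; the scaling exponent $H$
  of $(R/S)_n \sim c\,n^H$ summarizes the long-range correlation of the
  series. $H \approx 0.5$ is a near-random response process, $H > 0.5$
  persistent (stable), $H < 0.5$ anti-persistent. $H$ is used raw: it
  already lives in $(0,1)$ for these series.
* **Distribution-shift of attention — $E$** (error rate of decisions):
  the fraction of incorrect decisions over *all* decisions, including
  ignores. Lower is better (rapid and exact switching).

Feature vectors are $[W, H]^\top$ (2-dim) or $[W, H, E]^\top$ (3-dim),
in the unit square/cube. The component order is fixed as $W$ first: all
published centroid tables and every qualitative interpretation read the
first coordinate as the workload, and this package follows that
convention throughout.

## R/S analysis and the small-sample correction

For a window size $n$ the series is cut into $d = \lfloor \ell/n \rfloor$
consecutive blocks (remainder discarded). Per block: the mean is removed,
deviations are cumulated, $R$ is the range of the cumulative sums, and
$S$ the unbiased standard deviation (divisor $n-1$). $(R/S)_n$ averages
$R/S$ over the non-degenerate blocks; constant blocks (possible after
reaction-time rounding) are excluded rather than contributing 0 or NaN,
and a window where every block is constant is skipped with a warning.

The default window schedule is dyadic: $n = \lfloor \ell/2^j \rfloor$
down to a minimum window of 8, deduplicated and ascending —
logarithmically spaced points weight the log-log regression evenly.
$H$ is the least-squares slope of $\log (R/S)_n$ on $\log n$ (natural
logarithms; the slope is base-invariant).

**Finite-sample correction.** The plain R/S statistic is biased upward on
short series: for independent data $\mathrm{E}[(R/S)_n]$ does not follow
the asymptotic $n^{1/2}$ power law at small $n$, so the raw regression
slope on a series of a few hundred to a few thousand points
overestimates $H$ — enough to push an i.i.d. Gaussian series visibly
above 0.5, contradicting the defining characterization of a random
process. The default estimator therefore applies the Anis–Lloyd expected
value (with the $(n - \tfrac12)/n$ small-sample front factor), regressing
$\log (R/S)_n - \log \mathrm{E}[(R/S)_n]$ on $\log n$ and recentering the
slope at $0.5$. This is the standard corrected R/S of the long-memory
literature. `rs_config(correction = "none")` gives the uncorrected
regression for comparison with analyses that used it. The test suite
verifies that the corrected estimator is calibrated (mean estimate on
seeded i.i.d. Gaussian sequences of length 1024 inside $[0.45, 0.55]$)
and recovers generator values $H \in \{0.3, 0.5, 0.7\}$ within $\pm 0.1$;
the uncorrected estimator recovers strongly persistent series
($H = 0.8$, length 2048, median within $[0.7, 0.9]$).

Estimates are never clipped: a value outside $(0,1)$ (e.g. on a trending
series) is reported with an `out_of_range` flag so the anomaly stays
visible.

## Clustering

K-means (Lloyd's algorithm) with k-means++ seeding partitions the feature
matrix, best of 50 restarts by total SSE, deterministic given one integer
seed. $K = 4$ by default, matching the four quality levels the assessment
targets; `k_selection_report()` gives the SSE-versus-K curve for
inspection. Numerical policies, all chosen for reproducibility:

* nearest-centroid ties go to the lowest cluster index;
* an emptied cluster is repaired by moving in the farthest point;
* convergence when assignments stop changing or the centroid shift falls
  below $10^{-10}$ (at most 300 iterations); every Lloyd iteration is
  asserted never to increase the SSE;
* final clusters are relabeled by ascending centroid $W$, so "cluster 1"
  is always the slowest-responding group and results are comparable
  across runs and seeds.

When reading the SSE-versus-K curve, the elbow is best judged on the log
scale: on the raw scale the drop from $K=1$ to $K=2$ dominates any
four-group geometry, while the largest second difference of $\log$ SSE
lands at the planted $K$ in the package's recovery experiments.

## Cluster statistics

Per cluster $S_k$ with $N_k$ members and centroid $\mu_k$: the dispersion
$\sigma_k = \sqrt{\sum_{x \in S_k} \lVert x - \mu_k \rVert^2 / (N_k - 1)}$
(unbiased divisor — clusters can be small) and its per-dimension version
$\sigma_k/\sqrt{n}$; the unbiased covariance $\Sigma_k$; the Pearson
correlation matrix; and the eigen-decomposition with eigenvalues in
decreasing order and orthonormal eigen-features whose sign is fixed
(largest-magnitude component positive).

Across clusters: Euclidean centroid distances, and the trace-log-det
(TLD) divergence
$\mathrm{div}_T(S_k, S_i) = \tfrac1n [\mathrm{tr}(\Sigma_k \Sigma_i^{-1})
- \ln\det(\Sigma_k \Sigma_i^{-1}) - n]$, symmetrized into the TLD
distance by averaging the two directions. Natural logarithms throughout.
A singular covariance is a domain error — no silent ridging, since a
hidden regularization would corrupt every downstream number; callers who
want a ridge must add it explicitly.

The *information-theoretic metric* (ITM) of a single cluster is its TLD
divergence from the identity ("ideal") covariance. Two conventions are
computed and labeled everywhere: `per_dimension` (with the $1/n$ factor,
exactly $\mathrm{div}_T(\Sigma, I)$) and `unnormalized`
($\mathrm{tr}\,\Sigma - \ln\det\Sigma - n$). The unnormalized form is the
reporting default because the published metric tables this package
reproduces are consistent only with that form (the acceptance tests
recompute them from the published covariance matrices to within the
printed rounding); the per-dimension form is what the defining formula
with the $1/n$ factor gives. Exposing both, labeled, avoids baking either
reading in silently.

**A note on the triangle inequality.** The symmetrized TLD distance is
non-negative, symmetric and zero exactly at equal covariances — all
verified on random SPD pairs — but it is *not* a metric: the triangle
inequality fails on a substantial fraction of random SPD triples (the
suite freezes a seeded 1000-triple experiment counting the violations).
Claims that rely on metric axioms for this quantity should be read as
heuristic.

Cluster contours in the 2-dim feature plane are convex hulls from
Graham's scan: vertices in counter-clockwise order from the lowest-y
point, collinear boundary points excluded, degenerate inputs (fewer than
3 points, or all collinear) returning the extreme points with a flag.

## The qualitative assessment

For $K = 4$ and 3-dim centroids, each intrinsic factor is ranked across
clusters — span by descending centroid $W$, stability by descending
centroid $H$, distribution-shift by ascending centroid $E$ — and ranks
1..4 map to High / Moderate / Low / Bottom. This rank-by-centroid rule is
adopted as the *definition* of the published qualitative grid: applied to
the published centroids it reproduces that grid cell for cell (an
acceptance test), and no other generating rule is stated in the source
material. Ties are broken by cluster index and flagged.

The overall level of a cluster is its rank-sum across the three factors
(1 = High … 4 = Bottom), ascending score mapping to Level 1..4 =
Excellent / Good / Moderate / Unqualified, with ties broken by ascending
centroid $E$ (the error rate is the most consequential factor for
operational risk). On the published centroids this identifies the
moderate-workload / low-error cluster as the unique best (score 6 against
7, 8, 9), matching the published reading; the full ordering of the weaker
clusters is this package's choice, since the source text does not totally
order them.

The expert-style bands (`expert_threshold_labels()`) implement only the
three-band structure of a 1–9 point expert grading — Narrow/Medium/Wide
for $W$, Bad/Medium/Good for $H$, and the inverted
Slow & Inaccurate/Medium/Rapid & Exact for $E$ — with cohort terciles as
default cut points. The human grading procedure itself is out of scope.

## The synthetic cohort generator

Real study data cannot ship with the package, so every downstream stage
is exercised on synthetic cohorts whose *measured* properties are
controlled:

* **Reaction times** are an affine transform of exact fractional Gaussian
  noise — circulant embedding (Davies–Harte) of the fGn autocovariance,
  so the prescribed Hurst exponent holds in distribution, not by
  approximate aggregation — scaled by `rt_mean_ms` and `rt_sd_ms` and
  truncated below at 50 ms. Truncation perturbs the realized $H$
  slightly; the $\pm 0.1$ calibration tolerance absorbs it.
* **NoD**: exactly `target_NoD` by default; an optional `nod_sd` draws a
  rounded-normal NoD clamped to $[200, 800]$, giving the within-group
  workload variability real cohorts show (without it, a recovered
  cluster's $W$ column is constant and its covariance singular).
* **Correctness**: i.i.d. Bernoulli$(1 - \text{ERD})$. **Decisions**:
  i.i.d. over $\{Y, N, I\}$ with a 0.45/0.45/0.10 mix (no published mix
  exists; the mix does not enter any downstream statistic).
* **Determinism**: the cohort is a pure function of its spec, including
  the seed; per-participant seeds are derived with disjoint strides.

`default_cohort_spec()` encodes the default study conditions: four latent
groups at the published 3-dim centroid positions $(W, H, E)$, with
`target_NoD` $= 200 + 600W$ rounded, `nod_sd = 30` (group $W$ spread
$\approx 0.05$), and sizes 75/51/11/6 — 143 participants, the retained
cohort size, with sizes derived once from the published per-cluster SSE
ratios. `rt_mean_ms` defaults to $1{,}440{,}000 / \text{NoD}$ ms so the
reaction times fill the 24-minute session.

What the generator does **not** emulate: reaction-time marginals (real
response-time distributions are right-skewed, not Gaussian), any
dependence of correctness on reaction time or on time-on-task, stimulus
semantics, and fatigue or learning drift. Passing tests therefore show
that the *pipeline* measures what it claims on data with known $H$, NoD
and ERD structure — not that real cohorts satisfy the model.

## Data handling choices

The interchange format is a six-column CSV (participant, task, event,
decision, correctness, reaction time in ms); XLSX is accepted read-only
for ingesting deposited sheets. Units are part of the format contract:
reaction times are milliseconds. The two tasks are concatenated for
analysis (the test is treated as one 24-minute session); per-task series
are available via `reaction_times(x, per_task = TRUE)`. Malformed rows
are dropped and logged (or abort in strict mode). The shipped cleaning
rule — at least 2 tasks and NoD ≥ 100 — is a documented stand-in: the
rule behind the original study's 168 → 143 participant reduction is not
published, so that count is not asserted anywhere in the suite.

## Problem sizes

The suite and the acceptance script run at desk scale by choice: Hurst
calibration uses 20 replicates of length 1024, generator recovery 10–50
replicates of lengths 512–2048, clustering experiments cohorts of
60–143 points, and the SPD-triple experiment 1000 draws. These sizes put
every stochastic check several standard errors inside its tolerance
while keeping a full run in seconds.
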