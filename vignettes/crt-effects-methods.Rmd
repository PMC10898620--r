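---
title: "Estimating cluster-level and individual-level effects in cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cluster-level and individual-level effects in cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crteffects)
```

## The problem

In a cluster randomized trial (CRT) an intervention is assigned to groups —
health facilities, communities, schools — while outcomes are measured on the
individuals inside them. Two estimands are then on the table for the same
trial. Writing $Y^c_j = \sum_i \alpha_{ij} Y_{ij}$ for the aggregated outcome
of cluster $j$ (with $\alpha_{ij} = 1/N_j$ by default, so $Y^c_j$ is the
cluster's event proportion), the *cluster-level* effect contrasts the
expected cluster outcome under each arm, giving every cluster equal weight:

$$\Psi^c(1)/\Psi^c(0), \qquad \Psi^c(a) = E\big[E(Y^c \mid A=a, E, W^c)\big],$$

while the *individual-level* effect gives every participant equal weight:

$$\Psi(1)/\Psi(0), \qquad \Psi(a) = E\big[E(Y \mid A=a, E, W)\big].$$

With constant cluster sizes the two coincide numerically; once sizes vary
they differ, and under *informative cluster size* — size modifying the
treatment effect — they can diverge sharply. The toy dataset built by the
tests (four clusters of 10 and one of 10 000, with event counts 2, 2, 2, 2
and 7 500) makes the point: the equally-weighted cluster mean is 0.31 while
the pooled individual mean is 0.748. Neither is wrong; they answer
different questions. The package therefore makes the estimand an explicit
object (`estimand_spec()`: level, scale, handling of matched pairs) and
every estimator declares which estimands it can target.

## Estimators

**Unadjusted contrast** (`unadjusted_contrast()`). Arm-specific means of
the cluster-level outcomes, weighted by the analysis weights
$J/N_T \times 1/\alpha_{ij}$ (all ones for the cluster-level target,
$J N_j / N_T$ for the individual-level target). Ratio contrasts get
delta-method inference on the log scale using the influence function (IF)
of the arm means; the reference distribution is $t$ with $J-2$ degrees of
freedom throughout.

**Geometric-mean t-test** (`geometric_ttest()`) applies Welch's t-test to
arm means of $\log Y^c_j$. Exponentiation targets the *ratio of geometric
means* — a genuinely different estimand, further from 1 than the
arithmetic ratio whenever outcomes vary, by the AM–GM inequality.

**TMLE family.** All three targeted maximum likelihood estimators share
one template: an initial logistic outcome regression, a logit-scale
fluctuation with the two clever covariates
$H(a) = \mathbf{1}(A=a)/\hat\pi(a \mid \cdot)$ fitted by a single weighted
MLE with the initial fit as offset (no iteration is needed in this
parameterization), targeted predictions averaged to the point estimate,
and IF-based variance over the $J$ independent clusters.

* `cluster_tmle()` works entirely on cluster-level aggregates; adjustment
  covariates are cluster-level ($E$-variables, cluster means $W^{*}c$ of
  individual covariates, or $N$).
* `hierarchical_tmle()` fits the outcome regression, propensity and
  fluctuation on pooled individual rows, then aggregates: the cluster IF
  is $\sum_i (J/N_T) D_{ij}$ for the individual-level target or
  $\sum_i \alpha_{ij} D_{ij}$ for the cluster-level target.
* `hybrid_tmle()` aggregates an individual-level outcome regression to an
  initial cluster-level estimator
  ($\hat\mu^c_j = \sum_i \alpha_{ij}\hat\mu(A_j,E_j,W_{ij})$) and then
  proceeds exactly as the cluster-level TMLE.

When the propensity adjustment set is empty the known design value 0.5 is
used — nothing needs estimating in a balanced CRT — and with an empty
outcome adjustment set the TMLE collapses *exactly* to the unadjusted
contrast, which the tests verify to $10^{-10}$.

A design point worth flagging: when the hierarchical TMLE targets the
*cluster-level* effect, the $\alpha_{ij}$ weights enter every step —
initial fit, fluctuation, and aggregation — not just the aggregation. The
individual-level fluctuation solves an individual-weighted score; only the
$\alpha$-weighted score makes the equally-weighted cluster mean consistent
when the outcome model is misspecified. Weighting only the aggregation
leaves a bias under informative cluster size that weighting throughout
removes; the test suite checks the weighted estimator's bias against the
counterfactual truth over replicated trials.

**Adaptive Prespecification** (`adaptive_prespec()`). With 20 clusters one
cannot afford to guess the adjustment set, nor to adjust blindly. The
procedure prespecifies candidate generalized linear adjustment sets
(by default the empty set plus each covariate singly) and selects, by
leave-one-cluster-out cross-validation with the squared IF of the target
contrast as loss, first the outcome regression (propensity fixed at the
known 0.5), then the propensity regression given that choice. The
unadjusted candidate is always present, so selection can only help; ties
break toward the smaller set, then lexicographic covariate name — both
choices ours, made for parsimony and determinism. For ratio estimands the
loss is the squared IF of the log ratio, matching the log-scale standard
errors reported everywhere else. When matched pairs are kept, folds are
pairs (the independent unit), and the pair-level IF is the *average* of
its two clusters' contributions: with pair contribution defined as the raw
sum, the variance of independent pairs would come out four times the
break-matches variance instead of reproducing it.

**Comparators.** `care()` implements the covariate-adjusted residuals
estimator: a pooled logistic regression of the outcome on baseline
covariates (never the arm) yields expected event counts $e_j$; the ratio
residuals $R_j = d_j/e_j$ are log-transformed and t-tested between arms,
targeting a geometric-mean-type estimand. `crt_gee()` solves the log-link
GEE with Poisson variance function (relative-risk regression — chosen for
its reliable convergence with binary outcomes where the log-binomial MLE
often fails), independence or exchangeable working correlation, robust
sandwich variance and the Fay–Graubard small-sample inflation of each
cluster's score (the $(1-\min(0.75, h_{jj}))^{-1/2}$ form); no GEE
dependency is used, the estimating equation is solved directly.
`aug_gee()` adds the augmentation term
$\sum_a [\mathbf{1}(A_j=a) - \pi^c(a)]\gamma_a$ restoring the marginal
interpretation of $e^{\beta_A}$ under covariate adjustment, with the
propensity fixed at the known 0.5 and conditional predictions from a
pooled logistic regression including the arm.

## The benchmark data-generating processes

`simulate_crt()` implements two study designs, both with $J = 20$ clusters
pair-matched on the cluster covariate $E_2$ and randomized within pairs.
"Norm$(a, b)$" is mean $a$, SD $b$ throughout.

**Study 1** (`sim1`): cluster covariates $E_1 \sim N(2,1)$,
$E_2 \sim N(0,1)$, sizes $N_j \sim N(150, 80)$ truncated below at 30 and
rounded; latent cluster factors $U_{E1} \sim U(-0.2, 1.5)$,
$U_{E2} \sim U(-0.5, 0.5)$ drive four individual covariates
($W_1 \sim N(2U_{E1}, 0.35)$, $W_2 \sim N(4U_{E1}, 0.9)$, $W_3, W_4 \sim
N(U_{E2}, 0.5)$); outcomes are Bernoulli with
$\text{logit}^{-1}(-0.75 - 0.35A + 0.8W_1 + 0.4W_2 - 0.3E_1 - 0.2AW_2)$.
The shared factor $U_{E1}$ creates strong between-cluster heterogeneity
that $W_1^c$ or $W_2^c$ can absorb — which is exactly what Adaptive
Prespecification discovers.

**Study 2** (`sim2`): $E_1, E_2 \sim N(0,1)$, $N_j \sim N(400, 250)$
truncated at 30; three noise-plus-latent covariates; outcome probability
$\text{logit}^{-1}(0.5 + W_1/6 + W_2/2 + W_3/4 + E_1/5 + E_2/5 -
\tilde N/8 - A\tilde N/5)$ with $\tilde N = N/150$. Size lowers risk and
interacts with treatment, so the cluster-level and individual-level true
ratios separate (about 0.77 vs 0.69 on a population of 1000 clusters).

The null variants set every treatment term to zero *after coupling*: the
same uniform draws generate both counterfactuals, so $Y(1) = Y(0)$
individual by individual and the true null ratios are exactly 1, not just
1 up to Monte-Carlo error.

`compute_truth()` evaluates the finite-population true effects on large
counterfactual populations (2500 clusters for study 1, 1000 for study 2 by
default — the sizes at which the quantities are stable to well under
0.01). Clusters with a zero counterfactual mean are excluded from the
geometric ratio, with a warning, since their log outcome is undefined;
with sizes of 30+ this is a sub-0.1% event.

Distributional choices the studies leave open were fixed once: sizes are
*clamped* at 30 (not resampled) and rounded to the nearest integer; truth
populations are generated without pair-matching, which cannot affect a
counterfactual mean; within each pair the intervention is assigned by an
independent fair coin. Pair matching minimizes the total within-pair
$|\Delta E_2|$; because the matching variable is scalar, sorting and
pairing adjacent values *is* the exact minimum-cost perfect matching (the
tests check this against exhaustive enumeration), so no general
nonbipartite matching code is carried.

## Numerical choices

* Cluster-level outcomes exactly 0 or 1 are nudged into
  $[10^{-6}, 1-10^{-6}]$ before the logit offset; the raw outcomes are
  kept in the score and IF, so the empty-adjustment identities stay exact.
* Estimated propensities are truncated to $[0.05, 0.95]$ (positivity
  guard) with a warning.
* All logistic fits run on prebuilt design matrices through a small
  damped Newton solver; a fit that fails (separation, singularity) makes
  the estimator fall back to its unadjusted candidate with a warning, and
  inside cross-validation it removes that candidate.
* Sample variances use the $n-1$ denominator; two-sided tests at
  $\alpha = 0.05$ by default.
* A zero-variance contrast at exactly the null returns $p = 1$ (no
  evidence); a zero-variance contrast away from the null returns `NaN`
  with a warning.

## What the simulations do and do not show

`run_study()` regenerates a trial per replicate (seed `base + r`, so runs
are bit-reproducible), applies each declared estimator, and summarizes
`pt` (mean estimate), `bias`, `sigma` (SD of log estimates), `sigma_hat`
(mean log-scale SE), `coverage` and `reject` against each estimator's own
target effect. Replicates where an estimator fails — e.g. a zero-event
cluster for a log-scale method, roughly 0.5% of study-1 replicates — are
excluded and counted.

At the problem sizes used by the tests and the acceptance script (200
replicates of study 1, 150–200 of study 2; population truths at 2500 and
1000 clusters) the Monte-Carlo error of a rejection rate is 1.5–3.5
percentage points, which is the resolution at which the operating
characteristics should be read. The generators emulate the hierarchy,
size variability, pair-matching and informative cluster size of a real
facility-based CRT; they do not emulate missing outcomes, time-varying
covariates, non-binary endpoints, more than two arms, or unequal
allocation — all estimators here assume a balanced two-arm design with
complete binary outcomes, and passing tests say nothing beyond that
envelope.

## Known limitations

* The GEE variance-function and working-correlation conventions differ
  across implementations; ours (Poisson variance, independence default)
  is internally consistent but need not numerically match other software
  beyond the no-covariate identities.
* Matched-pair inference treats the pair as the unit with $J/2 - 1$
  degrees of freedom; a full pair-matched efficiency theory (how matching
  interacts with adaptive selection) is outside the package's scope.
* Heterogeneous within-cluster weights $\alpha_{ij}$ are accepted by the
  aggregation operations, but the cluster-level analysis weights require
  $\alpha$ constant within cluster, and no worked reference exists for
  inference under within-cluster heterogeneous weights.
* Candidate libraries are meant to stay small (singletons); nothing stops
  larger sets, but with $J = 20$ clusters the cross-validated variance
  estimates behind the selection become noisy as candidates grow.

## A worked example

```{r example, eval = FALSE}
cfg <- dgp_config("sim2", J = 20, seed = 7)
trial <- simulate_crt(cfg)

# the two estimands diverge under informative cluster size
unadjusted_contrast(trial, estimand_spec("cluster"))
unadjusted_contrast(trial, estimand_spec("individual"))

# adaptive TMLE for the individual-level effect
adaptive_prespec(trial, estimand_spec("individual"), "hierarchical_tmle",
                 outcome_candidates = list(character(), "W1", "W2"))
```
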