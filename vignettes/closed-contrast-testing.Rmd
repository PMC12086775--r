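---
title: "Closed model-based contrast testing for dose-control comparisons"
author: "cmcpmod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed model-based contrast testing for dose-control comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcpmod)
```

## The testing problem

A parallel-group trial randomizes patients to a control arm and $k$ active
doses $d_1 < \dots < d_k$. Responses are modeled as
$Y_{ij} = \mu_i + \varepsilon_{ij}$ with
$\varepsilon_{ij} \sim N(0, \sigma^2)$. Two questions must be answered with
familywise error control at a one-sided level $\alpha$ (0.025 by default):
is there any dose-related drug effect at all, and which individual doses
are superior to control? The elementary hypotheses are
$H_i : \mu_i \le \mu_0$, tested for superiority ($\mu_i > \mu_0$); the
package is one-sided for an *increase*, so endpoints where lower is better
must be negated by the caller.

Plain many-to-one procedures (Dunnett and its step-down version, Hochberg,
fixed sequence) answer the second question without using the expected
*shape* of the dose-response relationship. Model-based contrast tests
exploit that shape: a candidate set of standardized dose-response curves,
fixed at the design stage, is translated into contrast vectors that
maximize power against each anticipated shape.

## Candidate shapes and contrasts

`candidate_model()` supports Emax $d/(ED_{50}+d)$, sigmoid Emax
$d^h/(ED_{50}^h+d^h)$, beta $(d/S)^{\delta_1}(1-d/S)^{\delta_2}$,
exponential $e^{d/\theta}-1$ and linear shapes. Standardized shapes are
meaningful only up to an affine transformation; `scaled_profile()` anchors
them to effect 0 at control and a chosen maximum effect at the design dose
of maximum efficacy, and every contrast is invariant to that scaling. The
exponential shape is written with the $-1$ offset so all shapes vanish at
dose 0; after placebo anchoring this is the same curve. The packaged
default set (`default_candidate_set()`) holds three Emax shapes
($ED_{50} = 0.05, 0.2, 0.7$) and two sigmoid Emax shapes
($h=3, ED_{50}=0.25$; $h=2, ED_{50}=0.6$) for a dose range rescaled to
$[0, 1]$ — five monotone curves spanning steep early saturation to nearly
linear behavior.

For a profile $\mu^0$ and arm variances proportional to $A = diag(1/n_i)$,
the optimal contrast maximizes the noncentrality
$c'\mu^0 / \sqrt{c'Ac}$ subject to $\sum_i c_i = 0$; the solution is
proportional to $n_i(\mu^0_i - \bar\mu^0)$ and is normalized to unit norm
with the orientation $c'\mu^0 > 0$ (`optimal_contrast()`). A general
positive-definite $A$ is accepted, but covariate-adjusted design matrices
are out of scope.

### Why constrain the weights

An optimal contrast may give an active dose a *negative* coefficient. The
test statistic then grows when that dose performs badly, so a sufficiently
harmful dose drives the test to reject with probability approaching one
even though no dose is better than control. `constrained_contrast()`
therefore maximizes the same objective under nonnegative dose-vs-control
weights, yielding a genuinely one-sided test. The solver enumerates all
$2^{|I|}-1$ supports, solves the unconstrained problem on each, discards
any solution with a negative dose weight (tolerance $-10^{-12}$), and
returns the feasible maximizer — an exact, reproducible KKT-consistent
solution, practical for $k \le 15$. When no dose beats control the
optimum degenerates to the least-unfavorable single comparison, which the
solver returns explicitly. The constrained optimum equals the
unconstrained one whenever the latter is already feasible, and its
objective can never exceed it; both facts are asserted in the test suite
against a smooth independent optimizer.

## The closed procedure

`closed_mcpmod()` tests all $2^k - 1$ intersections
$H_I = \cap_{i\in I} H_i$. For each $I$ the per-model contrasts are
re-optimized on the control arm plus the doses in $I$ (coefficients
elsewhere are exactly zero), and the statistics
$T_{m,I}$ use the pooled variance from *all* arms — never re-estimated on
the subset — with $N - k - 1$ degrees of freedom. Under $H_I$ the vector
of statistics is central multivariate t with the correlation matrix
implied by the contrasts and allocations, so
$q_{m,I} = 1 - P(T_1 \le t_{m,I}, \dots)$ are maxT-adjusted p-values and
$H_I$ is rejected when $\min_m q_{m,I} < \alpha$, equivalently when
$\max_m T_{m,I}$ exceeds the equicoordinate critical value. An elementary
$H_i$ is rejected iff every $I \ni i$ is rejected; its closed-test
adjusted p-value is the maximum intersection p-value over those $I$
(standard closure algebra). The procedure is **not consonant**: rejecting
the global intersection does not guarantee an elementary rejection, so the
closure is evaluated exhaustively, never by shortcut. One consequence,
visible in the flat-null simulations below, is that the probability of any
elementary rejection sits *below* $\alpha$ (strictly so for the
unconstrained variant) while the global test itself is exact.

Strong FWER control holds for the constrained variant by the closed test
principle. For unconstrained contrasts control is established for
$k = 2$; for $k \ge 3$ it is supported by simulation only, so
`closed_mcpmod(constrained = FALSE)` emits a warning. Candidate models
whose profile is constant on an intersection are dropped for that
intersection with a warning rather than failing the procedure; the
remaining models still give a valid level-$\alpha$ test.

## Numerical choices

Multivariate-t probabilities use randomized quasi-Monte-Carlo integration
(`mvtnorm`, Genz-Bretz; 50 000 points, absolute tolerance $5\times10^{-5}$)
under a fixed internal seed (option `cmcpmod.mvt.seed`) so all results are
reproducible; the attained integration error is attached to every p-value
vector. Critical values are found by root-finding on the integrated
probability inside the exact bracket formed by the univariate and
Bonferroni quantiles. Numerically identical contrasts (pairwise correlation
1 within $10^{-12}$) are collapsed before integration — on singleton
intersections every model yields the same $\pm1/\sqrt 2$ pairwise contrast
and the test reduces to the two-sample t-test exactly. Tie-breaks: the dose
of maximum efficacy takes the smallest maximizing design dose; contrast
orientation always makes the profile inner product positive.

## What the simulator emulates

`scenario()` + `simulate_trial()` draw per-patient normal responses around
a profile obtained by anchoring a true shape at effect 0 under control and
a maximum effect (0.3, 0.4 or 0.5 in the packaged study grid) at the dose
of maximum efficacy, with residual SD 1 — the case-study conditions: doses
0/0.1/0.4/1 and 100 patients per arm. Replicates are derived from a master
seed through independent substreams, and `run_study()` applies every
requested procedure to the *same* replicate data (common random numbers)
before summarizing RAO (probability of at least one rejection), per-dose
power and AVE/k with binomial standard errors. Because design, candidate
set and level fix all contrasts, correlations and critical values,
`closed_mcpmod_plan()` precomputes them once and `plan_decisions()`
reduces each replicate to matrix arithmetic; the plan path is asserted
against the full per-dataset procedure.

The generator draws i.i.d. normal errors with known common variance
structure and no covariates, dropouts, or endpoint correlation; passing
tests therefore validate the procedure's mathematics and calibration under
the stated model, not robustness to non-normality or heteroscedasticity.
Misspecification of the *shape* is exercised: beta and exponential truths
outside the candidate set probe the power cost of a wrong candidate set.

Problem sizes used by the shipped tests were chosen to keep Monte-Carlo
error meaningfully below the quantities compared: 10 000 replicates for the
flat-null error rates (3 binomial SEs $\approx 0.0047$), 2 000 for power
orderings and the harmful-dose configuration, 100 random instances for the
optimizer and duality checks.

## Two endpoints

For a primary and a secondary endpoint on the same arms,
`two_endpoint_graph()` encodes the successive testing strategy: the level
is split equally across the primary hypotheses; rejection of a primary
hypothesis passes its level to the same-dose secondary hypothesis (edge
weight $x = 1$; a generalized $x \in [0,1]$ splits the remainder across
the other primaries), and a rejected secondary hypothesis passes its level
on to the other doses' primaries. `local_levels()` implements the node
removal algebra, which is invariant to removal order. Each of the
$2^{2k}-1$ intersections is tested by splitting its local levels between
the endpoint groups (Bonferroni — the endpoint correlation is deliberately
never estimated) and testing the positive-level hypotheses of each
endpoint jointly with the constrained contrast test on their doses at the
group's summed level (`closed_graphical_mcpmod()`). With the default graph
no secondary hypothesis carries positive level while every primary is
present, so "secondary only after its own primary" emerges from the graph
rather than being hard-coded; the suite asserts it on simulated data. The
candidate set is shared across endpoints; per-endpoint sets are accepted
through the API but are not part of the validated surface. Within an
endpoint group the intersection test uses the group's own doses at the
summed level — levels inside a group are equal for every intersection of
the default graph, so no weighted-maxT refinement is needed.

## Known limitations

* Normal, homoscedastic endpoints only; no generalized parametric, binary
  or time-to-event extensions.
* The Mod step — dose-response model fitting, model averaging, target-dose
  estimation — is intentionally absent: this package covers the
  confirmatory testing layer.
* No consonant modification of the closure and no adaptive two-stage
  designs.
* Support enumeration is exponential in the intersection size; fine for
  the intended $k \le 15$, and the two-endpoint closure is limited to
  $2k \le 16$ hypotheses.
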