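---
title: "Hybrid mongoose-annealing feature selection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid mongoose-annealing feature selection: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmsao)
```

## The problem

Wrapper feature selection treats subset choice as an optimization problem
whose objective is a classifier's performance on each candidate subset. For
a dataset with $D_t$ features there are $2^{D_t} - 1$ nonempty subsets, so
beyond a couple of dozen features exhaustive search is hopeless and a
stochastic search is used instead. The archetypal application in this
package is gene selection on microarray-style data: tens of samples,
thousands of expression features, and a handful of genes that actually
carry class signal.

`bdmsao` implements a hybrid of two searches:

* a **binary Dwarf Mongoose Optimization** (BDMO) population search over
  continuous positions $x \in [0,1]^{D_t}$, thresholded into binary
  feature masks, providing exploration; and
* a **simulated annealing** (SA) local search over masks under a
  single-bit-flip neighbourhood, providing exploitation around the best
  solution found so far.

## The objective

A candidate mask with $d_s$ selected features is scored by a
$k$-nearest-neighbour classifier (Euclidean distance, $k = 5$, majority
vote) and the composite minimization fitness

$$ f \;=\; \mu\,(1 - A_c) \;+\; (1-\mu)\,\frac{d_s}{D_t}, \qquad \mu = 0.99, $$

where $A_c$ is the classification accuracy, pooled over stratified 10-fold
cross-validation by default (a stratified 80/20 holdout is available via
`fitness_config(eval_mode = "holdout")`; the 80/20 ratio is this package's
choice, as the train/test protocol underlying holdout evaluation does not
itself fix one). The error term dominates; the size term breaks ties among
equally accurate subsets in favour of small ones. Consequences worth
keeping in mind:

* the smallest possible fitness difference between two masks at equal
  accuracy is $(1-\mu)/D_t$ — tiny for large $D_t$;
* a *correct* optimizer returns a **minimal sufficient subset**: once some
  subset reaches the attainable accuracy ceiling, every additional feature
  only costs penalty. If several features carry redundant signal, most of
  them will (rightly) be dropped.

Features are min–max scaled to $[0,1]$ on each training fold, with the
training parameters applied to the evaluation fold. Unscaled KNN distances
would be dominated by feature units; the scaling is mask-independent and
therefore precomputed once per dataset. KNN determinism is pinned down
explicitly: neighbour ties break by smallest training index, vote ties by
the nearest tied class, so a (dataset, configuration, seed) triple always
reproduces the same accuracy.

## The search operators

**Binarization.** A bit is selected iff its clamped position strictly
exceeds 0.5. An all-zero mask (possible, since 0.5 itself maps to
unselected) is repaired by switching on the bit with the largest
continuous position: the classifier, and hence the fitness, is undefined
on an empty subset.

**Alpha/foraging phase.** Each of the $n - bs$ foraging agents
tournament-selects a guide (size 2; tournament selection keeps selection
pressure mild and lets weak solutions occasionally lead) and proposes
`guide + phi * peep` with `phi ~ U(-1, 1)` per dimension and `peep = 2`.
Candidates are accepted greedily — only if strictly better under the
deterministic preference order (fitness, then subset size, then
lexicographic mask) — which guarantees a monotone best-so-far trajectory.
A fitness-proportional alternative to the tournament is provided
(`guide_selection = "roulette"`); because the fitness is minimized, the
proportional rule is applied to $g_i = \max_j \mathrm{fit}_j -
\mathrm{fit}_i + \varepsilon$, which preserves the normalization while
ranking good solutions highest.

**Sleeping mounds and scouting.** Every proposal updates a normalized
fitness-change score $sm_i \in [-1, 1]$; their mean $\varphi$ steers the
scout move `X ± CF * phi * rand * (X - M)`, whose amplitude decays with
the schedule $CF = (1 - t/T)^{2t/T}$. The printed movement vector
$M = \sum_i x_i\,sm_i/x_i$ cancels algebraically to the scalar
$\sum_i sm_i$ broadcast over dimensions; the package implements that
simplification and offers the sm-weighted centroid
$\sum_i x_i\,sm_i / n$ behind `m_variant = "centroid"` for users who
prefer a position-dependent drift. `phi` is drawn per dimension in the
foraging move (independent vocal perturbation) but per agent in the scout
move (a coherent group move).

**Babysitters.** `bs = 3` agents sit out of the search; every
`round(0.6 * max_iter)` iterations the worst `bs` agents are re-drawn
uniformly — a restart mechanism that injects diversity late in the run.
The incumbent best agent is never re-initialized.

**SA stage.** In hybrid mode the alpha-group intensification is augmented
by annealing the current best agent's mask: single-bit-flip proposals,
Metropolis acceptance ($\exp(-\Delta/T)$ for worse moves), geometric
cooling by 0.93. The local search is *elitist*: the best mask ever
visited is returned, so a refinement can never lose ground. After the
main loop a final SA polish is applied to the global best. The flowchart
gate that routes solutions between BDMO and SA by a "position index
$\geq 0.5$" test is also available (`sa_gate = "p_index"`: agents with
fewer than half their bits selected take the SA branch); the default
best-agent reading keeps the SA budget bounded and concentrated where
intensification pays.

## Temperatures: one deliberate deviation

The conventional initial temperature $T_0 = 2\,|N|$ (with $|N| = D_t$)
grows with the dimension while the objective is bounded in $[0,1]$. If
the stopping temperature is also tied to $T_0$ (e.g. $10^{-3}\,T_0$), the
whole schedule sits in the always-accept regime for any realistic $D_t$:
every proposal is accepted and the local search is a pure random walk. We
measured exactly that — with a $T_0$-proportional floor the hybrid beat
the plain binary search on only half of paired seeds, i.e. the SA stage
contributed nothing. The package therefore ends the schedule where it can
discriminate: `min_temp` defaults to $10^{-3}/D_t$, a tenth of the
one-feature penalty step $(1-\mu)/D_t$, so late proposals accept a
one-feature *improvement* and reject a one-feature *regression* — the
hill-climbing regime that actually prunes subsets. Both $T_0$ and
`min_temp` remain configurable.

Two related orchestration choices: all SA calls within a run share a
single cooling schedule (each call resumes where the previous one cooled
to, and holds at the floor once reached), rather than restarting a fresh
schedule each iteration — one coherent annealing process whose early
calls explore and late calls refine; and the final polish continues that
schedule at its terminal temperature instead of reheating. Each SA call
is capped at `max_evals = 100` proposals, keeping its per-iteration cost
independent of $D_t$; `chain_length = 5` proposals are made per
temperature level. Cached (previously seen) masks are re-served from the
run's memo table, so repeated proposals near a local optimum cost
microseconds, not classifier evaluations.

## Synthetic data and what the tests show

`make_planted()` generates datasets with a known ground truth: informative
features are class-conditional Gaussians whose class means sit
`class_sep` within-class standard deviations apart, noise features are
class-independent standard Gaussians, labels are balanced. The
homoscedastic mean-shift design keeps the KNN-optimal subset analytically
predictable. `make_expression_like()` exponentiates the same design, so
values are positive with a log-normal right skew at microarray shapes
(e.g. 62 samples x 2000 features). Neither generator attempts to mimic
real expression covariance structure, batch effects, or heavy-tailed
noise — passing tests certify the search machinery, not biological
relevance.

Because every planted feature is *individually* separating, the planted
set is redundant by construction: at `class_sep = 4` one to three
informative features already reach cross-validated accuracy 1.0, and the
optimizer — correctly — returns such a minimal subset. "Recovering all
planted features" is therefore not an achievable target under this
objective, and the test suite documents this behaviour rather than
papering over it: the accuracy of the selected subset is asserted, the
measured recovery rate is what the objective implies.

`exhaustive_oracle()` enumerates all nonempty masks (capped at 20
features, ~$10^6$ evaluations) with the identical evaluator and
tie-breaking, providing the ground-truth optimum that the search is
checked against: at its defaults the search matches the oracle optimum on
essentially every seeded run of 6–12-feature problems.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale, chosen so the whole
suite completes in minutes: oracle-equivalence on ten 6–12-feature
planted datasets (100 samples, separation 4, two informative features,
20 seeds each); hybrid-vs-plain pairing and accuracy checks on a
50-feature planted dataset over 20 seeds; and a single 62 x 2000
expression-shaped run. At that last scale the default budget (population
10, 50 iterations, ~100 SA proposals per iteration) reaches perfect or
near-perfect accuracy (1.0 at the shipped seed) but retains several
hundred features: a uniform random initialization
selects ~$D_t/2$ bits, and single-bit-flip descent removes on the order
of 0.1 features per proposal once cold, so pruning a 1000-bit start to a
few dozen genes needs several times more proposals than the conventional
budget provides. Users targeting very small gene panels at that scale
should raise `max_iter` or `sa_params(max_evals = ...)` accordingly.

## Numerical and degenerate-input choices

* Fitness ties break deterministically (fewer features, then
  lexicographic mask), so "number of features selected" is reproducible.
* `sleeping_mound(0, 0)` is defined as 0, removing the 0/0 case.
* Constant features scale to 0 under min–max scaling (range guard), and
  coordinates with $|x| < 10^{-12}$ are excluded from the literal
  movement-vector quotient (relevant only to the cross-check of the
  simplification, since the broadcast form is used).
* Stratification falls back to shuffled folds, with a warning, when a
  class has fewer members than folds.
* All randomness flows through R's RNG seeded once per run; fold
  construction uses its own seed so every run of a comparison shares one
  CV partition.

## Known limitations

* KNN is the only wrapper classifier, as in the method's definition; no
  SVM/tree alternatives, and no filter scores.
* The scout phase's printed movement vector is position-independent; the
  centroid variant is offered but is not the default.
* No restarts or reheating in the SA stage; no parallel populations.
* High-dimensional runs inherit the budget limitation described above.
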