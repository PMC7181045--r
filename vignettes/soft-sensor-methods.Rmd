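---
title: "Active-learning ensemble GP soft sensing: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning ensemble GP soft sensing: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own science: the models it
implements, the parameters that matter, the places where the design was
genuinely open and what we chose there, and what the shipped synthetic
benchmark does and does not demonstrate.

## The problem

A soft sensor predicts a quality variable that can only be measured by
off-line laboratory analysis (penicillin concentration, g/L) from process
variables that are cheap to measure continuously (volume, agitator power,
pH, temperatures, feed rate, aeration). Two structural facts shape the
design. First, *labels are scarce and expensive* — most historical samples
carry inputs only — so the question "which samples should the lab analyze
next?" matters as much as the regression model itself. Second, fed-batch
fermentations are *multiphase*: cell growth, product synthesis and
autolysis are distinct operating regimes with different input–output
relationships, which a single global regression serves poorly.

The package pairs a cluster-adaptive active-learning (AL) loop with an
ensemble of phase-local Gaussian process (GP) regressors fused by Bayesian
posterior weights, and benchmarks four variants crossing sampling strategy
(random / active) with learner (global / ensemble).

## Gaussian process regression

The kernel is the isotropic squared exponential with a noise term on the
sample index,
$$k(x_i,x_j) = \sigma_f^2\exp\!\left(-\tfrac{\|x_i-x_j\|^2}{2l^2}\right) + \delta_{ij}\sigma_n^2 .$$
Hyperparameters $(l, \sigma_f^2, \sigma_n^2)$ are estimated by maximizing
the log marginal likelihood with L-BFGS-B in log-parameter space, using
analytic gradients. The surface is multimodal, so five restarts are run:
one moments-based start (median pairwise distance, target variance) and
four seeded log-uniform draws in $[10^{-2},10^{2}]$. Cholesky
factorizations carry a jitter ladder from $10^{-10}$ to $10^{-6}$ because
standardized process data contains near-duplicate rows. The predictive
variance includes $\sigma_n^2$ by default (`include_noise = FALSE` gives
the latent-function variance); the posterior mean is the point estimate.
An automatic-relevance-determination kernel is deliberately out of scope —
the shared length-scale is part of the method being studied.

Inputs are z-scored with statistics of *all* training inputs (labeled and
pool): the inputs of unlabeled samples are observed, and a common scale
keeps the cluster tree and the phase mixture consistent across AL
iterations. Targets are z-scored with labeled-set statistics and refit
each iteration; predictions are transformed back.

## Phase identification and the component count

A full-covariance Gaussian mixture is fitted by EM (log-space E step,
closed-form M step, k-means++-style seeding, pooled-covariance start, best
of five restarts; convergence when the log-likelihood gain drops below
$10^{-6}$ or after 500 iterations). Two robustness rules matter in
practice:

* **Degeneracy guard.** A full-covariance component in $m$ dimensions
  needs at least $m+1$ points of responsibility mass; below that the
  likelihood is unbounded (a component collapses onto a low-dimensional
  subset and its density diverges). Restarts that cross this line are
  rejected, and a fit whose every restart degenerates fails — the same
  policy mclust applies when it reports `NA` for an unsupportable model.
  Without the guard, any criterion computed from the log-likelihood is
  meaningless at small sample sizes.
* **On-demand regularization.** Covariance updates are ridged
  ($10^{-6}\,\mathrm{tr}(\hat\Sigma)/m$ on the diagonal, escalating only as
  needed) *only when numerically non-positive-definite*. Unconditional
  ridging would perturb the objective every step and can violate the EM
  ascent property near convergence; applied on demand, monotone ascent
  holds exactly on well-conditioned data and the tests assert it at
  $10^{-9}$.

**The component-count criterion.** The criterion value we report is
$\mathrm{BIC} = -2\log L + 3K\log N$ (a flat per-component penalty). For
*selection*, however, `gmm_select_k` defaults to the conventional
free-parameter count $p_K = (K{-}1) + Km + Km(m{+}1)/2$. The flat penalty
is not a usable selection rule for full-covariance mixtures in seven
dimensions: splitting any cluster that is not literally Gaussian — for
instance the uniform-along-a-line segment a process trajectory traces —
gains on the order of 0.1 nat per point, so any cluster beyond roughly a
hundred points profitably splits and the argmin sits at the largest
candidate K for essentially any continuous-process data. We measured
exactly that (argmin 6 of 6 on every seed and at every sample size).
The free-parameter penalty recovers the three physiological phases on the
default benchmark inputs. Both penalties are available in `gmm_bic`.

## The cluster tree and the sampler

The unlabeled pool is clustered once per experiment by Ward linkage,
implemented through the Lance–Williams recurrence ($O(n^2)$ memory) and
validated in the tests against a direct recomputation of the merged-cluster
error sum of squares. Merge heights are the ESS increases; exact ties
break lexicographically by smallest sample id so the tree is a pure
function of the data. The initial working partition is the tree cut at the
150 highest merges (the reference pruning size; `pruning_sweep` explores
others).

Each node tracks, over the *queried* samples in its subtree, the class
fractions $p_{v,c}$ with confidence half-width
$$\Delta_{v,c} = \frac{1}{n_v} + \sqrt{\frac{d_v\,p_{v,c}}{n_v}},\qquad
d_v = 1 - p_{v,c},$$
i.e. a $1/n$ exploration term plus the Wald term
$\sqrt{p(1-p)/n}$. The $1/n_v$ term is deliberately *independent of node
purity*: a subtree vouched for by a single sample must remain wide open.
(An impurity-scaled variant, $d_v/n_v$ in the first term, makes a
one-sample node maximally confident — bounds $[1,1]$ — after which the
sampler never revisits it; in our experiments this collapsed coverage and
made active learning *worse* than random selection, so it was rejected.)
A class is admissible at a node when
$(1-p^{LB}_{v,c}) < \beta\,(1-p^{UB}_{v,c'})$ for every rival $c'$, with
$\beta = 2$; the node error is one minus the best admissible fraction,
or 1 when nothing is admissible.

**Classes for a regression task.** The sampler reasons about classes, but
the target is continuous, and no canonical discretization exists. The
default derives classes from the *input space*: a three-component mixture
fitted once to the pool inputs, hard assignments frozen as leaf classes.
Subtree purity then means "this region belongs to one operating phase",
and the sampler spreads its budget across phases and their boundaries. The
alternative — quantile bins of the labeled target, edges frozen from the
initial labeled set — is retained (`scheme = "quantile"`), but it is the
wrong default for this process: a quality variable that rises and falls
along the batch crosses every bin several times, so bin edges recur inside
phases, the affected nodes can never become admissible, and the sampler
sinks its budget into resolving bin boundaries instead of covering the
process. We measured one seed spending half its budget in a single phase
this way. Quantile classes remain sensible when the target is monotone in
the operating conditions.

**Selection.** Each of the $n_s = 20$ selections takes the pruning node
with the smallest lower confidence bound for its best class; a node with
no admissible class scores zero. Early on most nodes tie at zero, and the
tie-break determines everything: we visit the node with the *fewest
queried samples* first (so every stratum of the pruning is visited before
any is revisited), breaking remaining ties at random with probability
proportional to subtree size (so that, within a sweep, large strata are
served first when the budget is smaller than the pruning). Descent inside
the chosen node picks a child with probability proportional to its
unqueried-leaf count, which draws an unqueried leaf uniformly within the
node. Deterministic alternatives (always the largest subtree) starve
small sparse-region nodes — exactly the "most dissimilar" samples the
method exists to find — and measurably invert the AL-vs-random ordering.

**Refinement.** After each labeling round the pruning is refined toward
the antichain minimizing the total mass-weighted error
$\sum_v w_v\tilde\varepsilon_v$, $w_v$ = subtree leaf share. A node is
resolved by the subtree recursion
$\mathrm{best}(v)=\min(w_v\tilde\varepsilon_v,\ \mathrm{best}(\mathrm{left})+\mathrm{best}(\mathrm{right}))$,
with ties kept at the coarser node. This bottom-up form, rather than a
single parent-versus-children sweep, is necessary for optimality: gains
are not monotone in depth (children can be worse than their parent while
grandchildren are better), and the recursion is exactly the fixpoint of
parent-child replacement against fully refined child subtrees. The tests
verify equality with exhaustive enumeration over all prunings on hundreds
of random trees. Mass weighting makes the parent-children comparison
dimensionally consistent; the raw unweighted comparison is available via
`refine_pruning(weighted = FALSE)`.

## The ensemble and its fusion

Labeled samples are hard-assigned to mixture components; one local GP is
fitted per phase on its subset (targets on the shared labeled-set scale);
at query time the fused prediction is the posterior-weighted sum of local
means, $y_p=\sum_k y_{qk}\,p(C_k\mid x_q,\Xi)$. Per-component means and
variances are exposed as traces but variances are not combined — fusing
them would require a committee-machine assumption the method does not
make.

Two practical rules keep small labeled sets workable. Components whose
labeled support falls below three samples are absorbed into their nearest
component (Mahalanobis distance between means) and their posterior weight
flows to the absorber at query time, so no local model rests on an
ill-posed fit. And when the data cannot support the requested K
non-degenerate components at all, K falls back toward a single global
model.

**What the phase mixture is fitted on.** Fitted on the labeled inputs
alone (the default of `fit_ensemble`), the phase model is fragile exactly
when it matters: with a few dozen labels the maximum-likelihood partition
routinely merges the under-labeled growth phase into another phase and
splits the long production phase instead, and the ensemble then trails the
global model. The benchmark protocol therefore fits the mixture once per
experiment on *all* training inputs (labeled + pool) and passes it in via
`X_phases` — legitimate because unlabeled inputs are observed by
definition of the setting, and no target information is involved. This
choice is what makes the ensemble reliably at least as good as the global
model from the first reporting checkpoint on.

## The synthetic fed-batch generator

`simulate_batch` integrates a simplified Bajpai–Reuss-type model — Contois
growth, substrate-inhibited production, first-order product hydrolysis and
biomass decay, feed dilution and evaporative volume loss — with
`deSolve::lsoda`, piecewise across the feed schedule. One deliberate
extension: production carries a density-dependent oxygen-transfer
limitation $1/(1+(X/X_{crit})^{12})$. As biomass crosses
$X_{crit} = 8$ g/L mid-production, synthesis throttles and hydrolysis takes
over, so the quality trajectory *rises and falls within one operating
phase*. Without this, penicillin is monotone-trackable and a linear
regression on the seven channels explains 93–98% of its variance — no
benchmark at all; with it, the linear baseline leaves about 26%
unexplained while the relation remains an exact function of phase and
volume, fully learnable by a GP.

The measured channels follow an industrial recipe-driven plant: agitation,
aeration and fermenter temperature are per-phase setpoints
(29/32/30 W, 6/8.5/7 L/h, 298/297/296 K), pH and feed temperature are held
constant, all controlled channels carry a small AR(1) wander whose
stationary amplitude equals the measurement-noise standard deviation, and
every channel gets additive Gaussian noise with sd = 1% of its range. Two
consequences are intentional. Within-phase input manifolds are straight,
noise-dominated lines — the shape a Gaussian mixture describes honestly,
so phase-count selection is well-posed. And wander is kept at noise scale
because a slow random walk of larger amplitude makes a controlled
channel's empirical distribution multimodal, which a mixture will happily
(and spuriously) split. The quality value itself is returned noise-free,
an idealized laboratory assay; the oracle (`make_oracle`) returns it
exactly and counts queries.

Defaults: 400 h batch, 0.5 h sampling (800 rows), feed 0/27/0 g/h at
0/45/240 h, feed substrate 300 g/L, evaporation $5\times10^{-4}$ h⁻¹.
The production phase needs a short GP length-scale (steep rise-fall over a
few liters of volume change) while the long evaporation-driven starvation
drift wants a long one; this scale conflict is precisely what makes
phase-local models pay off. What the generator does *not* emulate:
batch-to-batch variability, controller dynamics and faults,
heteroscedastic or drifting sensors, missing data. Passing the shipped
benchmark therefore demonstrates correctness of the machinery and the
expected qualitative orderings on clean multiphase data, not performance
on any real plant.

## The benchmark protocol

`run_protocol` mirrors the reference study conditions: 800 samples split
400/400 train/test by alternating rows (no temporal extrapolation), 8
initial labels (2%) drawn uniformly with a recorded seed, learning step
20, pruning size 150, K = 3, seeds 1–10, RMSE and tracking precision
(TP = 1 − σ²_error/σ²_true) on the fixed test set after every iteration,
checkpoint tables after iterations 3 and 7. "Iteration 1" is the first
query batch; the initial fit is iteration 0. Sample selection is computed
once per strategy and shared by both learners of that strategy, so
same-strategy variants differ only in the model. Labeled ids are sorted
before fitting, making every fit a function of the labeled *set*; two runs
of the same configuration are byte-identical. Models are refit from
scratch after every iteration — labeled sets are small and this matches
the "updated training set is first divided" workflow. Scores on the test
set never leak into standardization or phase fitting; test points only
pass through the posterior-weight formula at prediction time.

Problem sizes throughout (n = 400/400, ten seeds, seven iterations) keep
the full four-variant benchmark under two minutes on one CPU while leaving
the orderings statistically visible; the tests run reduced versions of
everything else for the same reason.

## Known limitations

* The sampler's classes come from an input-space mixture; a process whose
  quality regimes do not align with input-space clusters would need the
  quantile scheme or a supervised discretization.
* The flat-penalty criterion value is reported but unusable for selection
  (see above); on data whose clusters are strongly non-Gaussian even the
  free-parameter BIC will over-split.
* Local models ignore cross-phase continuity of the quality variable;
  near phase boundaries the fused prediction relies on posterior weights
  rather than on sharing data across the boundary.
* The generator's three phases are recipe-crisp; processes with gradual
  regime transitions will show softer posterior weights and weaker
  ensemble gains.
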