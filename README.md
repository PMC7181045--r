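# alegpr — active-learning ensemble GPR soft sensors

`alegpr` builds **soft sensors** for multiphase bioprocesses: inferential
models that predict a hard-to-measure quality variable (here, penicillin
concentration in a fed-batch fermentation, g/L) from seven easily measured
process variables (culture volume, agitator power, pH, substrate feed
temperature, fermenter temperature, substrate feed rate, aeration rate).
The practical obstacle it addresses is **label scarcity**: quality values
require off-line laboratory assays, so a historical dataset is mostly
unlabeled. The package implements a complete
active-learning workflow that decides *which* samples are worth sending to
the lab, and an ensemble regression model that exploits the multiphase
structure of the process, together with the baselines and the benchmark
protocol needed to evaluate both.

## The method

Four pieces, composable on their own or through the benchmark driver:

1. **Gaussian process regression** (`gp_fit`, `predict`). Squared-exponential
   kernel k(xᵢ,xⱼ) = σf² exp(−‖xᵢ−xⱼ‖²/2l²) + δᵢⱼσn², hyperparameters
   Θ = {l, σf², σn²} estimated by multi-start quasi-Newton maximization of
   the log marginal likelihood
   log p(y|X) = −n/2·log 2π − ½log|K| − ½yᵀK⁻¹y, predictions by the
   standard posterior mean kₜᵀK⁻¹y and variance k(xₜ,xₜ) − kₜᵀK⁻¹kₜ.
2. **Phase identification** (`gmm_fit`, `gmm_select_k`). A full-covariance
   Gaussian mixture over the input space fitted by EM; the number of
   operating phases is chosen by BIC (three for the reference process:
   growth, production, autolysis).
3. **Hierarchical sampling** (`build_hctree`, `init_sampler`,
   `al_iteration`). A Ward-linkage merge tree over the unlabeled pool is
   cut into a working pruning (150 nodes in the reference protocol). Each
   node carries class-probability confidence bounds
   [p − Δ, p + Δ], Δ = 1/n_v + √(p(1−p)/n_v); a class is *admissible* when
   committing to it costs at most β = 2 times any rival. Each iteration
   queries the ns = 20 least-certain regions, then refines the pruning to
   the minimum-error antichain.
4. **Bayesian fusion** (`fit_ensemble`, `predict`). One local GP per phase,
   fused at query time by posterior phase probabilities:
   y_p = Σₖ y_qk · p(Cₖ|x_q, Ξ).

Four soft-sensor variants are benchmarked, crossing the sampling strategy
(random vs. active) with the learner (global vs. ensemble): `GPR`, `EGPR`,
`AL-GPR`, `AL-EGPR`.

Because the real process data behind such studies comes from simulators
that are not redistributable, the package ships its own seeded fed-batch
penicillin generator (`kinetic_params`, `simulate_batch`,
`generate_dataset`): a simplified Bajpai–Reuss kinetic model with a
three-phase operating recipe, producing 800 samples of the seven inputs
plus the quality variable per batch.

## Worked example

Eight labeled samples to start, three active-learning iterations of twenty
queries each, then an ensemble sensor — evaluated on 400 held-out samples:

```r
library(alegpr)

ds    <- generate_dataset(n_samples = 800, seed = 1)
train <- subset_ids(ds, ds$ids[seq(1, 799, 2)])
test  <- subset_ids(ds, ds$ids[seq(2, 800, 2)])

sc  <- fit_standardizer(train)
Xtr <- apply_standardizer(sc, train$X)
Xte <- apply_standardizer(sc, test$X)

split  <- split_initial(train, n_labeled_initial = 8, seed = 1)
oracle <- make_oracle(train)            # stands in for the laboratory
y0     <- oracle$query(split$labeled)

pool  <- match(split$pool, train$ids)
tree  <- build_hctree(Xtr[pool, ], ids = split$pool)
state <- refine_pruning(init_sampler(tree, X_pool = Xtr[pool, ],
                                     pruning_size = 150, seed = 1))

labeled <- split$labeled
for (it in 1:3) {
  step    <- al_iteration(state, oracle, ns = 20)
  state   <- step$state
  labeled <- c(labeled, step$ids)
}

li     <- sort(match(labeled, train$ids))
sensor <- fit_ensemble(Xtr[li, ], train$y[li], K = 3, seed = 1,
                       X_phases = Xtr)
pred   <- predict(sensor, Xte)
rmse(test$y, pred$mean)
tracking_precision(test$y, pred$mean)
oracle$count()
```

Output:

```
RMSE: 0.0403817
TP:   0.9793172
labels queried: 68
```

With 68 of 400 training samples labeled (17%), the sensor tracks the
penicillin concentration to 0.040 g/L root-mean-square error and a
tracking precision (one minus the error-variance/true-variance ratio) of
0.979. The full benchmark — `run_protocol(protocol_config())` — repeats
this for all four variants over ten seeds; its checkpoint table after
iterations 3 and 7 shows the expected ordering (means over ten seeds,
seeds 1–10):

| variant | RMSE, iter 3 | RMSE, iter 7 |
|---------|-------------:|-------------:|
| AL-EGPR | 0.0557 | 0.0283 |
| AL-GPR  | 0.0581 | 0.0290 |
| EGPR    | 0.0591 | 0.0309 |
| GPR     | 0.0608 | 0.0316 |

Active learning beats random selection at the same annotation budget, and
the phase-local ensemble beats the single global model under either
strategy.

A command-line front end with `simulate`, `benchmark` and `predict`
subcommands is installed at `inst/scripts/alegpr`.

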