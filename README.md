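# trajnet

Interpretable network SDE models of aging health trajectories and survival.

Longitudinal cohort studies of aging observe dozens of health variables at
irregular visits, with heavy missingness, and follow participants until
death or censoring. `trajnet` jointly models the two sides of such data:
the health state `x(t)` evolves by a stochastic differential equation whose
drift couples variables **linearly through a directed interaction matrix
W** — the interpretable network of pairwise interactions between health
variables — plus nonlinear per-variable self-dynamics, while mortality
follows a history-dependent hazard computed by a recurrent network along
each trajectory:

    dx_i = ( sum_j W_ij x_j + f_i(x_i, u, t) ) dt + sigma_x,i(x) dB_i
    y_tk ~ N(x(t_k), sigma_y^2)           (observed entries only)
    S(t) = exp( - int_t0^t lambda({x(s)}, u, s) ds )

Missing baseline states are multiply imputed with a normalizing-flow
variational autoencoder trained jointly with the dynamics. Inference is
scalable variational Bayes: Laplace posteriors on the interaction weights
(against sparse Laplace(0, 0.05) priors) let edges be pruned by 99%
credible intervals, so the fitted network reports only interactions the
data robustly support.

The package is aimed at quantitative aging researchers and biostatisticians
who want trajectory + survival prediction *and* an interpretable interaction
network from one model, with a ground-truth cohort simulator to validate the
machinery, the standard survival metrics (time-dependent C-index, IPCW
Brier score, D-calibration, two-sample population realism tests), and
elastic-net Cox / linear-trajectory baselines for comparison.

## Worked example

Simulate a cohort with a known sparse network, fit the joint model, and
inspect what it recovered:

```r
library(trajnet)

set.seed(101)
truth  <- sample_ground_truth(n_vars = 6, sparsity = 0.2)  # 6 true edges
cohort <- simulate_cohort(truth, M = 1000, horizon = 8, dt = 0.1)
cohort
#> cohort: 1000 individuals ( 1000 sources ), 6 health variables, 2 background covariates
#>   deaths: 95  censored: 905  mean visits: 4.32

cfg <- trajnet_config(epochs = 400, batch_size = 1000, lr = 5e-3,
                      lr_floor = 5e-4, lr_post = 1e-3, horizon = 10,
                      anneal_xz = c(0, 100), anneal_W = c(100, 200),
                      seed = 102)
fit <- trajnet(cohort, config = cfg, replicate = FALSE)

off <- row(truth$W) != col(truth$W)
cor(coef(fit)[off], truth$W[off])
#> [1] 0.8020635
```

The posterior-mean interaction matrix correlates strongly with the network
that generated the data. Predictions for new individuals give per-individual
survival curves and trajectory summaries, scored with the package's metrics:

```r
set.seed(7)
test  <- simulate_cohort(truth, M = 300, horizon = 8, dt = 0.1)
pred  <- predict(fit, test, n_samples = 10)
c_index_td(pred)
#> [1] 0.7737687
integrated_brier(pred)
#> [1] 0.04768572
```

A time-dependent concordance near 0.77 says the model ranks earlier deaths
as higher-risk in about four of five comparable pairs; the integrated Brier
score of 0.048 reflects survival-curve accuracy under this cohort's ~90%
censoring. Robust network edges (99% credible interval excluding zero) are
exported as an edge list via `export_edges(fit)`, pruned and clustered views
via `prune_network(fit)` and `cluster_network(fit)`.

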