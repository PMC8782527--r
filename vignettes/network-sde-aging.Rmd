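---
title: "Joint network-SDE modelling of aging health trajectories and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint network-SDE modelling of aging health trajectories and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`trajnet` fits a joint generative model of multivariate health trajectories
and mortality for longitudinal cohort studies of aging. An individual's
health is a latent continuous state $x(t) \in \mathbb{R}^N$ observed with
noise at irregular visit ages; observed values $y_{t_k}$ carry a binary
observation mask. The state evolves by a stochastic differential equation

$$dx_i(t) = \Big(\sum_{j \ne i} W_{ij}\, x_j(t) + f_i(x_i(t), u, t)\Big)\,dt
  + \sigma_{x,i}(x(t))\, dB_i(t),$$

where the directed matrix $W$ couples variables *linearly* — this is the
interpretable object of the analysis, a network of pairwise interactions
between health variables — while each $f_i$ is a small per-variable network
capturing nonlinear self-dynamics (the "diagonal" of the system), and
$\sigma_x$ is a state-dependent diagonal diffusion. Background covariates
$u$ (with their own missingness mask) condition $f_i$ and mortality but have
no dynamics of their own.

Mortality is history-dependent: a two-layer gated recurrent unit (hidden
sizes 25 and 10) consumes the trajectory along the integration grid and
emits a nonnegative hazard $\lambda(t)$ through an exponential link, with
its initial hidden state produced from the baseline state, $u$, and baseline
age. Survival is $S(t) = \exp(-\int_{t_0}^t \lambda)$, integrated by the
trapezoid rule on the same grid as the dynamics. An individual is summarised
by the event age $a$ (death, or last age known alive) and a censoring flag.

Missing baseline states are imputed by a normalizing-flow variational
autoencoder: an encoder maps the (temporarily population-filled) baseline,
its mask, $u$ and $t_0$ to a Gaussian base distribution plus a conditioning
vector $\gamma_z$; three RealNVP coupling layers sharpen that distribution;
a decoder maps latent samples to a baseline mean whose observation scale is
the measurement noise $\sigma_y$. Observed coordinates are always kept;
imputation is multiple by construction.

## Inference

Exact posterior inference is intractable, so the package uses stochastic
variational inference with a structured family:

* independent Laplace posteriors (location $\bar W_{ij}$, scale $b_{ij}$)
  for every off-diagonal interaction weight, against Laplace$(0, 0.05)$
  priors — the sparsity prior that makes credible-interval pruning
  meaningful;
* independent Gamma posteriors (shape $\alpha_i$, rate $\beta_i$) for each
  measurement-noise scale, against Gamma$(1, 25000)$ priors read in the
  shape/scale parameterisation — an effectively flat exponential over the
  plausible z-scored noise range (the shape/rate reading would concentrate
  the prior at $4\times10^{-5}$ and overwhelm the likelihood at cohort
  scales);
* point estimates for all network weights (uniform priors);
* a *posterior SDE* over trajectories: the drift is the prior drift at the
  posterior mean $\bar W$ plus a small correction network $g$, so posterior
  trajectory samples are produced by the same integrator;
* a Gaussian-plus-flows posterior for the imputation latent.

The per-individual objective combines the masked Gaussian likelihood of
observed values at visit ages, the survival likelihood
$(1-c)[\log \lambda(a) + \log S(a)] + c\int \log S$ plus a dead-window term
$\int_a^{a+5} \log(1 - S)$ rewarding $S \to 0$ past an observed death, and
the trajectory-space penalty
$-\tfrac12 \int \| (W x - \bar W x - g)/\sigma_x \|^2 dt$ (with $W$ a
pathwise Laplace sample) that forces the posterior SDE toward the network
dynamics. Global KL terms for the Laplace and Gamma posteriors and a
per-individual latent KL (flow-corrected) complete the bound. Individuals
replicated across alternative baseline waves enter the likelihood with
weights summing to one per source individual; the parameter KLs are not
weight-scaled.

Training uses ADAM with KL annealing: one linear ramp for the latent and
trajectory KL terms, a later ramp for the parameter-prior KL terms (the
measurement-noise KL is grouped with the latter). During annealing the
learning rate follows a deterministic halving schedule from its initial
value down to a floor — large constant rates destabilise the stochastic
objective while the KL terms are still ramping — and after annealing a
plateau rule (halve after 40 stalled epochs on a frozen-noise validation
loss) takes over, with checkpointing of the best fully-annealed validation
state.

### Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `dt` | 0.5 y | integration and hazard grid step |
| `prior_scale` | 0.05 | Laplace prior scale on $W_{ij}$ |
| `noise_prior` | (1, 25000) | Gamma prior on $\sigma_y$ |
| `keep_prob` | 0.9 | per-entry keep probability of baseline corruption |
| `latent` | 20 | imputer latent dimension |
| `n_flows` | 3 | coupling layers (hidden 30/24/10) |
| `batch_size`, `lr` | 1000, $10^{-2}$ | ADAM settings |
| `anneal_xz`, `anneal_W` | 0–300, 300–500 | KL ramp windows (epochs) |
| `window` | 5 y | dead-window length past the death age |

Architecture sizes follow the reference design: encoder hidden 95 and 70
with a 40-dimensional output split into $\mu_z$ and $\log \sigma_z$ and a
separate 10-dimensional $\gamma_z$ head off the last hidden layer; decoder
hidden 65; per-variable $f_i$ nets hidden 12; correction net $g$ hidden 8;
diffusion net hidden $N$; ELU activations. The per-variable nets are
evaluated as one block-diagonal computation, exactly equivalent to $N$
separate networks. Batch normalization is omitted: at these widths and at
cohort scales the plain MLPs train stably, and removing train/eval mode
state keeps prediction deterministic given the parameters.

## Numerical choices

* **Integrator.** `sde_integrate()` uses an explicit strong order 1.0
  scheme for diagonal noise: classical four-stage Runge-Kutta for the
  drift combined with the derivative-free Milstein correction. The training
  loop uses the single-stage-drift variant of the same scheme (Euler drift
  plus Milstein correction — also strong order 1.0) to halve the cost of
  backpropagating through the unrolled dynamics; prediction and all
  convergence tests use the four-stage version.
* **Time features.** Age enters every network as $(t - 70)/10$, centring
  late-life ages near zero.
* **Grids and integrals.** All likelihood integrals use the trapezoid rule
  on the dynamics grid. Visit ages are snapped to the nearest grid point
  (at `dt` = 0.5 y the snap error is below a quarter year, within the
  design's visit-age jitter). The grid covers the longest event-age offset
  plus the dead window, with an optional `horizon` cap that truncates the
  dead-window integral for the latest deaths.
* **Clamps.** The pre-exponential log-hazard is clamped to $[-18, 6]$;
  $\log(1-S)$ and $\log S$ are guarded at $10^{-6}$; $\sigma_z$ is bounded
  away from zero and infinity; the $\sigma_y$ plug-in is clamped to
  $[10^{-3}, 3]$ on the z-scored scale. Gradients are zero outside clamp
  ranges.
* **$\sigma_y$ plug-in.** The Gamma posterior enters the likelihood through
  its mean $\alpha/\beta$, in training and evaluation alike, keeping the
  objective differentiable in $(\alpha, \beta)$ without Gamma
  reparameterisation; the posterior itself is fit through its closed-form
  KL term. The posterior is initialised at mean 0.5 on the z-scored scale
  rather than at the prior mean of $4\times 10^{-5}$, which would make the
  initial masked-likelihood precision explode.
* **Corruption and self-supervision.** During training the baseline state
  fed to the dynamics keeps observed values only where they survived the
  keep-mask, so artificially corrupted entries flow through the decoder and
  are scored against their true values in the baseline likelihood — this is
  what makes the corruption a self-supervision signal rather than pure
  noise.
* **Latent KL estimator.** The trainer evaluates the latent term as the
  single-sample estimator $\log q(z_L) - \log p(z_L)$ with the prior
  density at the *pushed* sample ($-\sum\log\sigma_z - \tfrac12\|\epsilon\|^2
  - \log|\det| + \tfrac12\|z_L\|^2$ up to constants). The textbook shorthand
  "base-Gaussian KL minus log-determinants" (which [kl_latent()] computes,
  and which coincides for identity flows) leaves Jacobian expansion
  unpenalised and lets the flows collect unbounded reward; evaluating the
  prior at $z_L$ closes that loophole.
* **Degenerate inputs.** Zero-variance variables are rejected at schema
  fitting; strata without population statistics fall back to global
  statistics with a warning; non-finite states abort integration with the
  offending step and path identified.

## Decisions at genuinely open points

* The masking probability is read from the sampling statement (keep with
  probability 0.9, corrupt with 0.1), not from the prose that inverts it;
  `keep_prob` is configurable.
* The dead-window bound is read as a 5-year window past the death age, not
  an absolute age.
* Replicated individuals inherit the train/validation/test assignment of
  their source individual (the split happens before replication), avoiding
  leakage between splits.
* In the time-dependent concordance, pairs with equal event ages are
  excluded, ties in predicted survival count as discordant (the strict
  inequality of the definition), and pairs formed from replicas of one
  source individual are excluded.
* Censored D-calibration mass is redistributed uniformly over the quantile
  interval below the predicted survival at censoring, following the
  standard procedure for that statistic.
* Network clustering applies average linkage to
  $D = \max(\omega) - \omega$, $\omega = (W^\top + W)/2$ computed on the
  absolute robust posterior means (pruned entries set to zero first); merge
  ties resolve to the lowest-index pair.
* One pathwise Laplace sample of $W$ per batch drives the trajectory
  penalty; one posterior SDE path per individual per objective evaluation.

## The synthetic-cohort generator

`sample_ground_truth()` and `simulate_cohort()` generate cohorts with the
structure the model assumes, with known truth: a sparse directed $W$
(default magnitudes 0.2–0.5, random signs), unit-variance baselines
correlated through a single common factor (loading 0.6, pairwise $r
\approx 0.36$ — the cross-sectional correlation of health batteries that
makes baseline imputation a solvable problem), linear mean-reverting
self-dynamics (rates 0.25–0.5/y) standing in for the learned $f_i$ — a
known parametric form is required for recovery scoring — diagonal diffusion
0.12–0.2, measurement noise 0.15–0.3 on the z-scored scale, a log-linear
hazard in $(x, t)$ with baseline rate $0.01/\mathrm{y}$ at age 70 and a
3%/y age slope (calibrated to give roughly 90% censoring over an 8-year
follow-up), visits every ~2 years with Gaussian jitter, baseline ages
uniform on 65–85, ~30% entry-wise missingness, and optional nurse-wave
block missingness (nurse variables collected every second wave, then
thinned). Death truncates follow-up; survivors are censored at their last
visit.

What the generator does **not** emulate: real marginal distributions
(everything is Gaussian on the transformed scale), informative missingness,
measurement batch effects, or the catalogue of named health variables.
Passing recovery and calibration tests on these cohorts therefore
demonstrates that the inference machinery works when the model class is
correct — the identifiability claim — not that any particular real cohort
satisfies the model.

## Test-suite problem sizes

The package's own test protocol runs the recovery experiment at $N = 6$
variables with 6 true edges, $M = 1000$ individuals, 400 epochs with anneal
windows 0–100 and 100–200, a 10-year grid horizon, an initial learning rate
of $5\times 10^{-3}$ decaying to $10^{-3}$ after annealing (at this cohort
scale one epoch is a single full-batch gradient step, so rates are set
below the large-cohort default), and three simulation seeds plus a
null-network control; the imputation benchmark trains the standalone
imputer for 1000 epochs at batch 250 on five seeds of $M = 500$ cohorts
with a 25% held-out mask (the standalone reconstruction signal is only the
corrupted 10% of observed baseline entries, so it needs several thousand
gradient steps where the joint model needs few hundred). These sizes were
chosen once as a desk-scale protocol that keeps the full suite fast while
leaving the recovery signal comfortably detectable; the same machinery
scales to larger cohorts by raising `epochs` and the anneal windows back to
their defaults.

## Known limitations

* The variational family underestimates posterior width, as mean-field
  families do; pruning decisions inherit this (the null-control test bounds
  the practical false-positive rate).
* Single-baseline conditioning: predictions use one baseline state per
  replica; multi-visit conditioning is out of scope.
* The latent-space drift variant (`latent_drift()`, `latent_init()`) is
  provided and integrable with the shared integrator, including the
  1D-summary configuration that removes background covariates from the
  drift, but end-to-end training of that variant is a configuration the
  package does not exercise in its tests.
* Training cost is dominated by the unrolled grid; the reverse-mode tape is
  pure R, so very long horizons or very wide cohorts are better served by
  raising `dt`'s grid alignment with visit spacing than by long horizons at
  fine steps.
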