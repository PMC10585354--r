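---
title: "Inferring cell differentiation networks from clonal tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell differentiation networks from clonal tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonenet)
```

## The problem

Clonal tracking experiments mark haematopoietic stem cells (HSCs) with
heritable labels — lentiviral integration sites or synthetic barcodes — and
then count, at a handful of time points, how many cells each clone
contributes to each sorted blood lineage. Those counts carry the signature
of the underlying differentiation process: how fast each compartment
self-renews, dies, and feeds its downstream lineages. They are also sparse
and noisy. Progenitor compartments in the bone marrow are rarely sampled at
all, and even measurable lineages drop out of individual samples for
technical reasons (low-input replicates, detection thresholds, calling
pipelines). Treating such false negatives as observed zeros biases any
dynamic model towards spurious extinction; `clonenet` instead treats every
absent entry as *unmeasured* and lets a state-space model marginalise over
it.

## The model

Each clone is a vector $x_t \in \mathbb{R}^n$ of cell counts over the $n$
lineages of a candidate differentiation network. Three reaction types, with
mass-action hazards linear in the state, define the dynamics:

* duplication $x_i \to 2x_i$ at rate $\alpha_i x_i$ (net effect $+1$ on $i$),
* death $x_i \to \emptyset$ at rate $\delta_i x_i$ (net effect $-1$),
* differentiation $x_i \to 2x_j$ at rate $\lambda_{ij} x_i$ (net effect
  $-1$ on $i$, $+2$ on $j$), for each directed edge $i \to j$.

Collecting the net-effect vectors into the stoichiometry matrix $V$
($n \times K$) and the hazards into $h(x;\theta)$, the chemical-Langevin
approximation of the reaction network is the Itô system

$$dx = V h(x;\theta)\,dt + \left[V\,\mathrm{diag}(h(x;\theta))\,V'\right]^{1/2} dW,$$

with drift $\mu(x) = Vh(x)$ and diffusion $\beta(x) = V\,\mathrm{diag}(h)\,V'$.
Because hazards are linear in $x$, the drift can be rewritten as $A_\theta x$
with a constant generator matrix $A_\theta$; the mean of the process evolves
exactly as $e^{A_\theta t}$.

Measurements at discrete times $t_k$ select a subset of coordinates through
a selection matrix $G_k$ (rows = lineages actually detected for that clone
at that time) and add Gaussian noise whose variance grows with the signal:

$$y_k = G_k x_{t_k} + r_k, \qquad r_k \sim N\!\left(0,\ \rho_0 I + \rho_1\,
\mathrm{diag}(G_k x_{t_k})\right).$$

A lineage with no record at $t_k$ simply contributes no row to $G_k$ — the
model never sees a fabricated zero.

## Inference

The fitting loop in `fit_network()` iterates three steps until the marginal
log-likelihood stabilises:

1. **Filtering.** Between observations, the predictive mean follows the
   exact matrix-exponential solution and the predictive covariance
   integrates $\dot P = A_\theta P + P A_\theta' + s\,\beta(m(t))$ by
   fixed-step RK4, with the diffusion evaluated along the predicted mean
   path (the extended-Kalman approximation — the only approximation in the
   filter, which is otherwise exact for these linear dynamics). At each
   observation a standard Gaussian correction yields the filtered moments
   and the innovation log-density; the sum of innovation log-densities over
   times and clones is the marginal log-likelihood of $\psi = (\theta, \rho)$.
2. **Maximisation.** A bound-constrained quasi-Newton step (L-BFGS-B, lower
   bound $10^{-8}$) climbs the marginal likelihood using a forward-difference
   gradient: one extra filter pass per parameter, as many passes as there
   are free coordinates.
3. **Smoothing.** A Rauch–Tung–Striebel backward sweep conditions every
   state on the full record, giving the reconstructed latent trajectories
   (`smoothed_states()`).

Candidate topologies are compared with `compare_networks()` by
$\mathrm{AIC} = 2p - 2\ell$, where $p$ counts the *free* coordinates after
identifiability constraints plus the two noise parameters. Constrained
coordinates are deterministic functions of free ones; counting them would
penalise the same information twice.

### Identifiability constraints

Rates whose reactions involve only unobserved lineages cannot be identified.
`build_constraint_map()` expresses them linearly through identifiable rates:

* **Flux conservation**: the rate into an unobserved compartment with
  outgoing edges equals the sum of its outgoing differentiation rates.
* **Averaging**: an unobserved-to-unobserved rate equals the mean rate of
  the source into its observed offspring; duplication and death rates of an
  unobserved node equal the mean over observed same-branch nodes sharing
  its ancestor.

When both rules could apply, flux conservation wins — it is the physical
conservation law, and the choice keeps the constraint matrix sparse and the
dependency graph acyclic. Chained unobserved compartments (HSC → MPP → CMP
all hidden) resolve recursively, leaf-ward constraints first, so every
constrained coordinate ends as a nonnegative combination of free ones; the
identities then hold *exactly* on any expanded estimate, which the test
suite asserts at machine precision.

Two points the averaging rule leaves open were decided as follows. The
ancestor-sharing condition is ambiguous when the relevant ancestor is itself
unobserved: the averaging pool first tries observed nodes declaring the same
ancestor and, when that set is empty, widens to observed branch-mates
descending from that ancestor (a nearest-ancestor reading); an empty pool
after widening is an explicit unidentifiable-parameter error, never a silent
guess. Root nodes carry branch label `"none"` and average over both
branches, since the root belongs to neither.

## Numerical choices

* **Mean propagation** uses the matrix exponential (exact); the
  **covariance** uses RK4 with 32 substeps per inter-observation interval by
  default. Doubling the substeps changes the result by less than $10^{-6}$
  relatively on the systems in the test suite; the covariance equation is
  non-autonomous through $\beta(m(t))$, so no closed form exists.
* The factor $s$ scaling the diffusion term is, by default, the length of
  the current inter-observation interval (`diffusion_dt_scaling = "local"`),
  matching the local linear-approximation scheme the moment equations derive
  from; `"unit"` selects the standard moment ODE of the diffusion. With
  observation grids spaced one time unit apart the two coincide. The
  smoother's exponent is likewise scaled by the interval
  (`smoother_expm_dt = "interval"`, dimensionally consistent with the mean
  transition); a `"unit"` reading is kept switchable because the scaling
  convention is a modelling choice, not a mathematical necessity.
* All covariance factorisations use Cholesky with escalating diagonal
  jitter ($10^{-9}$ to $10^{-6}$); failure beyond that range raises a
  conditioning error rather than falling back to a pseudo-inverse. The
  jitter actually applied is folded into the reported innovation covariance
  so that the returned log-likelihood equals the log-density under the
  reported moments to machine precision.
* Hazards evaluated at negative Gaussian means are floored at zero inside
  $\beta$, keeping the diffusion PSD.
* **Per-clone priors** anchor at the clone's first observation time: the
  prior mean copies the first measurements where available and a clone-level
  fill value elsewhere; the prior variance is measurement-scale
  (`max(m0, 1)`) for anchored coordinates but *diffuse* — the squared
  maximum count of the clone — for coordinates whose mean is only a guess.
  The diffuse component matters: an overconfident prior on an unmeasured
  compartment forces the filter to explain the discrepancy with inflated
  process noise, which biases the duplication/death split upward. This was
  visible as a likelihood ridge in development and is the package's own
  refinement of the simpler uniform-variance prior.
* **Initialisation and multistart.** Free rates start uniform in
  $[0.1, 1]$ (seeded); $\rho_1$ starts at $0.1$; the first candidate's
  $\rho_0$ is the variance of first differences of observed counts (floored
  at $0.1$). That variance estimate tracks growth trends as much as noise
  and can overshoot by orders of magnitude, so the remaining candidates
  spread $\rho_0$ log-uniformly between $0.1$ and the estimate. Because the
  likelihood surface has distinct basins, the optimiser uses successive
  halving: a pool of candidate starts is ranked by one objective evaluation
  each, the survivors get a short quasi-Newton burst, and only the best
  `restarts` (default 3) of those are optimised fully. One basin deserves a
  dedicated countermeasure: a large $\rho_0$ can soak up the process
  variability while the rates sit near plausible values (only
  $\alpha_i - \delta_i$ enters the drift, so the noise attribution is the
  weakly determined direction). After the multistart, a *noise-reattribution
  probe* re-optimises once from the best rates with $\rho_0$ reset small
  whenever the incumbent $\rho_0$ is large, and the better optimum is kept.
  In development this converted nested-model comparisons from noisy (tens
  of log-likelihood units of optimiser scatter) to tight (the richer model
  exceeding the nested one by fractions of a unit, as theory dictates).
* Times are taken in the units of the input time stamps; rates are per unit
  of that time. No internal rescaling.

## The synthetic-data generator

`simulate_dataset()` and `make_benchmark()` produce the validation datasets:
Euler–Maruyama trajectories on a fine grid (default step = horizon/1000)
with the diffusion square root from a clipped symmetric eigendecomposition,
sampled at the assay times with independent per-entry dropout (probability
$\zeta$) and signal-proportional Gaussian noise. Mask draws precede noise
draws in a fixed order, so datasets differing only in $\zeta$ share the
surviving entries' noise under the same seed (common random numbers).
Simulated states are floored at zero by default because the "truth" they
represent is a cell count; `floor_states = FALSE` disables this for
validation runs that compare raw SDE moments with the linear theory.

The generator emulates the statistical structure of in-silico validation
studies: few clones, few time points, dropout up to 90%, noise parameters up
to $\rho_0 = \rho_1 = 10$, progenitor compartments hidden wholesale
(`insilico-deep` hides HSC, MPP, CMP, CLP, MEP, GMP). It does **not**
emulate read-level artefacts of real assays — PCR amplification bias,
barcode collisions, inter-sample contamination, or the study-specific
rescaling that real pipelines apply before modelling — so passing recovery
tests demonstrates correctness of the inference machinery under the model's
own assumptions, not robustness to every failure mode of real data. The
generic `rescale_by_sample()` hook is the intended entry point for
study-specific normalisation.

Benchmark scenario defaults (duplication 0.25, death 0.05, 100 root cells
at time zero, observation times 1–5, $\rho_0 = 0.1$, $\rho_1 = 0.01$) were
chosen once as biologically plausible magnitudes — self-renewal exceeding
death, differentiation dominating both in transit compartments — and are
recorded in each benchmark's ground-truth object. Differentiation rates are
constructed bottom-up (0.3 into each terminal lineage, internal edges
carrying the sum of their target's outflow) so that the generating rates
satisfy the flux-conservation and averaging identities exactly; the
in-silico validation design simulates under the same conservation laws the
constrained fit assumes, and defaults violating them would make every
benchmark fit on a hidden-progenitor topology silently misspecified.

## Problem sizes used in the validation suite

The shipped tests and `scripts/acceptance.R` run, per invocation: a
10,000-replicate Monte-Carlo check of the simulator's first two moments on a
2-node system; recovery fits on a 4-node single-branch network with 20
clones and 10 time points (3 restarts, with and without 50% dropout); a
20-replicate AIC comparison between the generating and an over-branched
topology (5 clones, 6 time points each); and a constrained fit with two
hidden compartments. These sizes are deliberate scaled-down analogues of
the larger in-silico studies the model family was validated on; they keep
the full suite in the minutes range on one CPU while preserving each
study's qualitative question.

## Known limitations

* The Gaussian (first-two-moments) approximation degrades for very small
  counts, where the true transition law is discrete and skewed; no
  higher-order moment closure is attempted.
* Rates are constant in time; time-varying or covariate-dependent rates are
  out of scope.
* The likelihood surface has a genuine ridge between duplication and death
  rates (only $\alpha_i - \delta_i$ enters the drift; their sum enters the
  diffusion), so $\alpha/\delta$ splits are the least well-determined
  quantities under heavy dropout — visible as the widest recovery ratios in
  the masked acceptance run.
* Point estimation only: no standard errors or posterior intervals for
  $\hat\psi$ are produced.

## A worked example

```{r example, eval = FALSE}
library(clonenet)

# a benchmark dataset from the small in-silico chain, plus its ground truth
b <- make_benchmark("insilico-small", n_clones = 10, seed = 1)
head(b$dataset)

# fit the generating topology
fit <- fit_network(b$dataset, b$net, fit_control(restarts = 3, seed = 1))
fit
fit$theta / b$truth$theta          # estimate-to-truth ratios

# compare candidate haematopoietic topologies on data with hidden progenitors
deep <- make_benchmark("insilico-deep", n_clones = 5, seed = 1)
ranking <- compare_networks(
  deep$dataset,
  list(dichotomic = shipped_network("dichotomic"),
       myeloid = shipped_network("myeloid-based")),
  fit_control(restarts = 2, seed = 1))
ranking

# reconstructed latent trajectories
head(smoothed_states(fit))
```
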