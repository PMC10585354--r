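#' Euler-Maruyama simulation of one clone's trajectory
#'
#' Integrates the Ito system `dx = mu(x) dt + beta(x)^{1/2} dW` on a fixed
#' time grid: `x_{t+D} = x_t + mu(x_t) D + beta(x_t)^{1/2} sqrt(D) z` with
#' `z` standard normal. The diffusion square root uses a symmetric
#' eigendecomposition with negative eigenvalues clipped at 0. Because the
#' Gaussian approximation can push a cell count below zero, states are
#' floored at 0 after each step by default; `floor_states = FALSE` disables
#' this for pure filter-validation runs where the simulated moments must
#' match the linear theory exactly.
#'
#' Randomness comes from R's RNG: call `set.seed()` (or pass `seed`) for
#' reproducible trajectories.
#'
#' @param rs a `reaction_system`.
#' @param theta full named rate vector.
#' @param x0 nonnegative initial state (length n).
#' @param t_grid increasing time grid (the first entry is the initial time).
#' @param seed optional integer seed.
#' @param floor_states floor states at 0 after each step (default `TRUE`).
#' @param stochastic if `FALSE`, suppress the diffusion term (deterministic
#'   Euler integration of the drift).
#' @return A `clone_trajectory`: list with `times` and an `n x length(times)`
#'   matrix `states` (lineages in rows).
#' @export
euler_maruyama <- function(rs, theta, x0, t_grid, seed = NULL,
                           floor_states = TRUE, stochastic = TRUE) {
  stopifnot(inherits(rs, "reaction_system"), length(x0) == rs$n,
            all(x0 >= 0), length(t_grid) >= 2, all(diff(t_grid) > 0))
  if (!is.null(seed)) set.seed(seed)
  states <- cpp_euler_maruyama(as.numeric(x0), as.numeric(t_grid), rs$V,
                               as.numeric(theta[rs$rate_index]), rs$src,
                               floor_states, stochastic)
  rownames(states) <- rs$nodes
  structure(list(times = as.numeric(t_grid), states = states),
            class = "clone_trajectory")
}

#' Measurement design for sampling a simulated trajectory
#'
#' @param observation_times the assay's sampling times.
#' @param observed_lineages lineages the assay can measure (the maximal
#'   selection rows); defaults at use time to the network's observed nodes.
#' @param dropout_fraction probability `zeta` in `[0, 1)` that an otherwise
#'   measurable entry is a false negative (masked).
#' @param rho0,rho1 measurement-noise parameters: an observation of signal
#'   `g` has variance `rho0 + rho1 * g`.
#' @return A `measurement_design` list.
#' @export
measurement_design <- function(observation_times, observed_lineages = NULL,
                               dropout_fraction = 0, rho0 = 0, rho1 = 0) {
  stopifnot(length(observation_times) >= 1, all(diff(observation_times) > 0),
            dropout_fraction >= 0, dropout_fraction < 1, rho0 >= 0, rho1 >= 0)
  structure(list(observation_times = as.numeric(observation_times),
                 observed_lineages = observed_lineages,
                 dropout_fraction = dropout_fraction,
                 rho0 = rho0, rho1 = rho1),
            class = "measurement_design")
}

#' Sample noisy partial observations from a trajectory
#'
#' For each observation time (matched to the nearest trajectory grid point)
#' every measurable lineage is independently masked with probability `zeta`;
#' surviving entries receive Gaussian noise with variance
#' `rho0 + rho1 * max(x, 0)` (floored at `rho0 + 1e-9`) and are truncated at
#' 0, since measurements are cell counts. Masked entries yield no row at all:
#' missingness is encoded by absence, never by zero. Mask draws for all
#' entries precede the noise draws (which are consumed in a fixed entry
#' order), so two designs differing only in `zeta` share the surviving
#' entries' noise under the same seed — common random numbers for dropout
#' comparisons.
#'
#' @param traj a `clone_trajectory`.
#' @param design a `measurement_design`.
#' @param clone_id identifier used in the output rows.
#' @param seed optional integer seed.
#' @return Long data.frame with columns `clone_id`, `time`, `lineage`,
#'   `count`. A warning is raised if every entry was masked.
#' @export
observe <- function(traj, design, clone_id = "clone1", seed = NULL) {
  stopifnot(inherits(traj, "clone_trajectory"),
            inherits(design, "measurement_design"))
  if (!is.null(seed)) set.seed(seed)
  lineages <- design$observed_lineages
  if (is.null(lineages)) lineages <- rownames(traj$states)
  stopifnot(all(lineages %in% rownames(traj$states)))
  tidx <- vapply(design$observation_times,
                 function(t) which.min(abs(traj$times - t)), 0L)
  x <- traj$states[lineages, tidx, drop = FALSE]  # lineage x time
  nent <- length(x)
  keep <- matrix(runif(nent) >= design$dropout_fraction, nrow(x), ncol(x))
  if (design$rho0 == 0 && design$rho1 == 0) {
    y <- x  # noiseless design: observations equal the selected true states
  } else {
    z <- matrix(rnorm(nent), nrow(x), ncol(x))
    sd <- sqrt(pmax(design$rho0 + design$rho1 * pmax(x, 0),
                    design$rho0 + 1e-9))
    y <- pmax(x + sd * z, 0)
  }
  if (!any(keep)) warning("empty dataset: all entries masked at all times")
  out <- data.frame(
    clone_id = as.character(clone_id),
    time = rep(design$observation_times, each = length(lineages)),
    lineage = rep(lineages, times = length(tidx)),
    count = as.vector(y),
    stringsAsFactors = FALSE
  )
  out[as.vector(keep), , drop = FALSE]
}

#' Simulate a clonal tracking dataset
#'
#' Forward-simulates `n_clones` independent trajectories by
#' [euler_maruyama()] on a fine grid from time 0 to the last observation
#' time (default step: horizon/1000) and samples each with [observe()].
#'
#' @param net a `diffnet`.
#' @param theta full named rate vector.
#' @param x0 initial state (length n, network node order).
#' @param design a `measurement_design`; `observed_lineages = NULL` defaults
#'   to the network's observed nodes.
#' @param n_clones number of clones.
#' @param seed integer seed (required for reproducibility; default 1).
#' @param n_steps fine-grid steps for the SDE integration (default 1000).
#' @param floor_states floor simulated states at 0 (default `TRUE`).
#' @return List with `dataset` (long data.frame), `trajectories` (list of
#'   `clone_trajectory`) and `truth` (generating parameters).
#' @export
simulate_dataset <- function(net, theta, x0, design, n_clones = 3, seed = 1,
                             n_steps = 1000, floor_states = TRUE) {
  stopifnot(inherits(net, "diffnet"), inherits(design, "measurement_design"))
  rs <- build_reaction_system(net)
  if (is.null(design$observed_lineages)) {
    design$observed_lineages <- net$nodes[net$observed]
  }
  t_max <- max(design$observation_times)
  t_grid <- seq(0, t_max, length.out = n_steps + 1)
  set.seed(seed)
  trajectories <- vector("list", n_clones)
  parts <- vector("list", n_clones)
  for (cl in seq_len(n_clones)) {
    id <- sprintf("clone%03d", cl)
    trajectories[[cl]] <- euler_maruyama(rs, theta, x0, t_grid,
                                         floor_states = floor_states)
    parts[[cl]] <- observe(trajectories[[cl]], design, clone_id = id)
    names(trajectories)[cl] <- id
  }
  dataset <- do.call(rbind, parts)
  rownames(dataset) <- NULL
  truth <- list(theta = theta, rho = c(rho0 = design$rho0, rho1 = design$rho1),
                x0 = setNames(as.numeric(x0), net$nodes), seed = seed,
                zeta = design$dropout_fraction,
                observation_times = design$observation_times,
                unobserved = net$nodes[!net$observed])
  list(dataset = dataset, trajectories = trajectories, truth = truth)
}

# Deterministic per-scenario defaults: duplication 0.25/time everywhere,
# death 0.05/time, all initial mass (100 cells) in the root. Differentiation
# rates are built bottom-up so that every internal edge carries the sum of
# its target's outgoing rates (0.3/time into each terminal lineage): the
# defaults then satisfy the flux-conservation and averaging identities
# exactly, as the constrained inference assumes of its data-generating
# process.
scenario_defaults <- function(net) {
  rs <- build_reaction_system(net)
  outflow <- function(node) {
    off <- offspring(net, node)
    if (!length(off)) return(0.3)
    sum(vapply(off, outflow, 0))
  }
  lambda <- numeric(0)
  for (e in seq_len(nrow(net$edges))) {
    lambda[paste0(net$edges[e, "from"], "->", net$edges[e, "to"])] <-
      outflow(net$edges[e, "to"])
  }
  theta <- rate_parameters(rs, alpha = 0.25, delta = 0.05, lambda = lambda)
  roots <- net$nodes[is.na(net$ancestor) & !(net$nodes %in% net$edges[, "to"])]
  if (!length(roots)) roots <- net$nodes[1]
  x0 <- setNames(numeric(length(net$nodes)), net$nodes)
  x0[roots[1]] <- 100
  list(theta = theta, x0 = x0)
}

#' Generate a benchmark dataset from a shipped network scenario
#'
#' Assembles a fully reproducible synthetic clonal tracking dataset from one
#' of the bundled topologies (see [shipped_network()]) together with the
#' ground truth that generated it. Scenario defaults: duplication rate 0.25,
#' death rate 0.05, total differentiation output 0.9 per source split evenly
#' across offspring (all per unit time), 100 cells in the root compartment at
#' time 0, observation times `1:5`, no dropout, noise `rho0 = 0.1`,
#' `rho1 = 0.01`. Only the network's observed lineages produce rows; the
#' `insilico-deep` scenario therefore yields no rows for HSC or any
#' progenitor. `overrides` replaces any of `theta`, `x0`,
#' `observation_times`, `zeta`, `rho0`, `rho1`, `n_steps`.
#'
#' @param scenario a name from [shipped_networks()].
#' @param n_clones number of clones (default 3).
#' @param overrides named list of overrides (see above).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return List with `dataset`, `trajectories`, `truth` and `net`.
#' @export
make_benchmark <- function(scenario, n_clones = 3, overrides = list(), seed = 1) {
  net <- shipped_network(scenario)
  defs <- scenario_defaults(net)
  pars <- utils::modifyList(
    list(theta = defs$theta, x0 = defs$x0, observation_times = 1:5,
         zeta = 0, rho0 = 0.1, rho1 = 0.01, n_steps = 1000),
    overrides)
  design <- measurement_design(pars$observation_times,
                               dropout_fraction = pars$zeta,
                               rho0 = pars$rho0, rho1 = pars$rho1)
  sim <- simulate_dataset(net, pars$theta, pars$x0, design,
                          n_clones = n_clones, seed = seed,
                          n_steps = pars$n_steps)
  sim$truth$scenario <- scenario
  sim$net <- net
  sim
}
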