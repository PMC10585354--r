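#' Mass-action hazards of a reaction system
#'
#' Hazard of reaction `k` is `h_k = x_{i(k)} * rate_k` with `rate_k` the
#' duplication, death or differentiation rate of the reaction (units
#' cells/time). Hazards are linear in the state.
#'
#' @param x numeric state vector (length `rs$n`).
#' @param theta full named rate vector (see [rate_parameters()]).
#' @param rs a `reaction_system`.
#' @return Numeric vector of length `rs$K` in reaction order.
#' @export
hazard <- function(x, theta, rs) {
  stopifnot(inherits(rs, "reaction_system"), length(x) == rs$n)
  unname(x[rs$src] * theta[rs$rate_index])
}

#' Drift and diffusion of the chemical-Langevin approximation
#'
#' `mu(x) = V h(x)` and `beta(x) = V diag(h(x)) V'`, the first two jump
#' moments of the reaction network; `beta` is symmetric PSD whenever the
#' hazards are nonnegative.
#'
#' @inheritParams hazard
#' @return List with `mu` (length n) and `beta` (n x n).
#' @export
drift_diffusion <- function(x, theta, rs) {
  h <- hazard(x, theta, rs)
  mu <- as.vector(rs$V %*% h)
  beta <- rs$V %*% (h * t(rs$V))
  list(mu = mu, beta = 0.5 * (beta + t(beta)))
}

#' Linear generator of the mean dynamics
#'
#' Because every hazard is linear in the state, `V h(x; theta)` can be
#' rewritten as `A x` with `A[j, i] = sum_{k: src(k)=i} v_k[j] * rate_k`.
#' `A` drives the moment ODEs between observations and its matrix
#' exponential is the exact mean transition.
#'
#' @param theta full named rate vector.
#' @param rs a `reaction_system`.
#' @return The n x n generator matrix.
#' @export
linearize <- function(theta, rs) {
  stopifnot(inherits(rs, "reaction_system"))
  rate <- as.numeric(theta[rs$rate_index])
  S <- matrix(0, rs$K, rs$n)
  S[cbind(seq_len(rs$K), rs$src)] <- rate
  A <- rs$V %*% S
  dimnames(A) <- list(rs$nodes, rs$nodes)
  A
}

#' Propagate Gaussian state moments over a time interval
#'
#' Advances the predictive mean and covariance of the state between two
#' observation times. The mean follows the exact linear solution
#' `m(t0 + dt) = expm(A dt) m(t0)`; the covariance integrates
#' `dP/dt = A P + P A' + s * beta(m(t))` with fixed-step RK4 (`substeps`
#' steps), `beta` evaluated along the exact mean path with hazards floored
#' at 0. The factor `s` is the interval length `dt` under the default
#' `diffusion_dt_scaling = "local"` (the local linear-approximation scheme
#' the moment equations stem from) or 1 under `"unit"` (the standard moment
#' ODE of the diffusion); the covariance is symmetrised after every substep.
#'
#' @param start list with `mean` (length n) and `cov` (n x n PSD).
#' @param theta full named rate vector.
#' @param rs a `reaction_system`.
#' @param dt interval length (> 0; `dt = 0` returns `start` unchanged).
#' @param substeps RK4 substeps per interval (default 32).
#' @param diffusion_dt_scaling `"local"` or `"unit"` (see above).
#' @return List with advanced `mean` and `cov`.
#' @examples
#' net <- differentiation_network("A", dup = FALSE)
#' rs <- build_reaction_system(net)
#' theta <- rate_parameters(rs, delta = 0.1)
#' out <- propagate_moments(list(mean = 100, cov = matrix(0, 1, 1)),
#'                          theta, rs, dt = 5)
#' out$mean  # 100 * exp(-0.5)
#' @export
propagate_moments <- function(start, theta, rs, dt, substeps = 32,
                              diffusion_dt_scaling = c("local", "unit")) {
  stopifnot(inherits(rs, "reaction_system"), dt >= 0, substeps >= 1)
  diffusion_dt_scaling <- match.arg(diffusion_dt_scaling)
  if (dt == 0) return(start)
  m <- as.numeric(start$mean)
  P <- as.matrix(start$cov)
  stopifnot(length(m) == rs$n, all(dim(P) == rs$n))
  A <- linearize(theta, rs)
  scale <- if (diffusion_dt_scaling == "local") dt else 1
  out <- cpp_propagate(m, P, A, rs$V, as.numeric(theta[rs$rate_index]),
                       rs$src, dt, as.integer(substeps), scale)
  list(mean = as.numeric(out$mean), cov = out$cov)
}
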