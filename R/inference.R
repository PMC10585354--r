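#' Control settings for network fitting
#'
#' @param restarts full optimisation runs kept from the screened
#'   multistart (default 3); see [fit_network()].
#' @param seed integer seed governing initialisation draws (default 1).
#' @param substeps RK4 substeps per inter-observation interval (default 32).
#' @param diffusion_dt_scaling `"local"` (diffusion term scaled by the
#'   interval length, the local linear-approximation scheme) or `"unit"`
#'   (standard moment ODE). See [propagate_moments()].
#' @param smoother_expm_dt `"interval"` or `"unit"`; see [smooth_clone()].
#' @param max_outer maximum outer filter/optimise/smooth iterations
#'   (default 50).
#' @param inner_maxit quasi-Newton iterations per outer cycle (default 25).
#' @param tol_ll relative log-likelihood convergence tolerance
#'   (default 1e-4: stop when `|dl| < tol_ll * max(1, |l|)`).
#' @param use_conservation,use_averaging identifiability constraints; see
#'   [build_constraint_map()].
#' @param prior_unobserved prior mean for lineages without a first-time
#'   measurement (default: clone's mean first-time count, floored at 1).
#' @param prior_var_scale prior variance is `max(m0, 1) * prior_var_scale`
#'   per coordinate (default 1).
#' @param lower optimiser lower bound on every coordinate (default 1e-8,
#'   keeping hazards and measurement variances well-defined).
#' @param psi0 optional explicit start `c(theta_free, rho0, rho1)`; restarts
#'   then perturb nothing and a single start is used.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(restarts = 3, seed = 1, substeps = 32,
                        diffusion_dt_scaling = c("local", "unit"),
                        smoother_expm_dt = c("interval", "unit"),
                        max_outer = 50, inner_maxit = 25, tol_ll = 1e-4,
                        use_conservation = TRUE, use_averaging = TRUE,
                        prior_unobserved = NULL, prior_var_scale = 1,
                        lower = 1e-8, psi0 = NULL) {
  structure(list(restarts = restarts, seed = seed, substeps = substeps,
                 diffusion_dt_scaling = match.arg(diffusion_dt_scaling),
                 smoother_expm_dt = match.arg(smoother_expm_dt),
                 max_outer = max_outer, inner_maxit = inner_maxit,
                 tol_ll = tol_ll, use_conservation = use_conservation,
                 use_averaging = use_averaging,
                 prior_unobserved = prior_unobserved,
                 prior_var_scale = prior_var_scale, lower = lower,
                 psi0 = psi0),
            class = "fit_control")
}

# Assemble the compiled-filter inputs once per dataset.
prepare_fit_inputs <- function(data, net, control) {
  rs <- build_reaction_system(net)
  cm <- build_constraint_map(net, control$use_conservation,
                             control$use_averaging)
  clone_data <- build_clone_data(data, net, rs,
                                 prior_unobserved = control$prior_unobserved,
                                 prior_var_scale = control$prior_var_scale)
  clones <- lapply(clone_data, function(cd) {
    list(dts = cd$dts, obs_idx = cd$obs_idx, ys = cd$ys, m0 = cd$m0,
         P0 = cd$P0)
  })
  list(rs = rs, cm = cm, clone_data = clone_data, clones = clones)
}

# Objective closure: psi = c(theta_free, rho0, rho1) -> -loglik. Filter
# conditioning errors surface as a large finite surrogate so the optimiser
# can retreat.
make_objective <- function(prep, control) {
  rs <- prep$rs
  cm <- prep$cm
  nf <- cm$n_free
  beta_mode <- if (control$diffusion_dt_scaling == "local") 1L else 0L
  function(psi) {
    theta <- as.vector(cm$C %*% psi[seq_len(nf)])
    names(theta) <- cm$full_names
    A <- linearize(theta, rs)
    ll <- tryCatch(
      cpp_loglik_clones(prep$clones, A, rs$V, as.numeric(theta[rs$rate_index]),
                        rs$src, psi[nf + 1], psi[nf + 2],
                        as.integer(control$substeps), beta_mode),
      error = function(e) {
        warning("filter evaluation failed (", conditionMessage(e),
                "); returning objective surrogate", call. = FALSE)
        -1e10
      })
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }
}

#' Negative marginal log-likelihood of a clonal tracking dataset
#'
#' Evaluates `-sum_clones l_clone(psi)` where each clone's marginal
#' log-likelihood is the product of its Gaussian innovation densities under
#' the extended Kalman filter, and `psi = c(theta_free, rho0, rho1)` with
#' the full rate vector recovered through the constraint map. Clones are
#' independent, so the value is additive over clones and invariant to their
#' order.
#'
#' @param psi numeric vector `c(theta_free, rho0, rho1)`.
#' @param data long clonal tracking data.frame
#'   (`clone_id`, `time`, `lineage`, `count`).
#' @param net a `diffnet`.
#' @param control a [fit_control()].
#' @return Scalar negative log-likelihood (finite surrogate `1e10` with a
#'   warning if the filter fails at `psi`).
#' @export
neg_marginal_loglik <- function(psi, data, net, control = fit_control()) {
  prep <- prepare_fit_inputs(data, net, control)
  stopifnot(length(psi) == prep$cm$n_free + 2)
  make_objective(prep, control)(psi)
}

#' Forward-difference numeric gradient
#'
#' One extra objective evaluation per coordinate (for the marginal
#' likelihood this means one extra full filter pass per parameter), with
#' step `h_i = max(1e-6, 1e-6 * |psi_i|)`. A non-finite perturbed value is
#' retried at `h_i / 10`.
#'
#' @param psi evaluation point.
#' @param objective function of `psi` returning a finite scalar at `psi`.
#' @param f0 optional precomputed `objective(psi)`.
#' @return Gradient vector of `objective` at `psi`.
#' @export
numeric_gradient <- function(psi, objective, f0 = NULL) {
  if (is.null(f0)) f0 <- objective(psi)
  if (!is.finite(f0)) stop("objective not finite at psi")
  g <- numeric(length(psi))
  for (i in seq_along(psi)) {
    h <- max(1e-6, 1e-6 * abs(psi[i]))
    pp <- psi
    pp[i] <- psi[i] + h
    fi <- objective(pp)
    if (!is.finite(fi)) {
      h <- h / 10
      pp[i] <- psi[i] + h
      fi <- objective(pp)
      if (!is.finite(fi)) {
        warning("gradient coordinate ", i, " non-finite after retreat; set to 0")
        fi <- f0
      }
    }
    g[i] <- (fi - f0) / h
  }
  g
}

# Noise initialisation: variance of the first differences of observed counts
# within (clone, lineage), floored at 0.1.
init_rho0 <- function(data) {
  diffs <- unlist(lapply(split(data, paste(data$clone_id, data$lineage)),
                         function(d) diff(d$count[order(d$time)])))
  if (length(diffs) < 2) return(0.1)
  max(var(diffs), 0.1)
}

#' Fit a differentiation network to clonal tracking data
#'
#' Constrained maximum marginal likelihood estimation of the duplication,
#' death and differentiation rates `theta` and the measurement-noise
#' parameters `rho = (rho0, rho1)`. The algorithm iterates a filtering step
#' (extended Kalman filter over every clone), a maximisation step
#' (bound-constrained quasi-Newton on the marginal likelihood using the
#' forward-difference gradient) and a smoothing step, until the
#' log-likelihood improvement falls below tolerance. Identifiability
#' constraints express rates involving only unobserved lineages through
#' observed-rate combinations (see [build_constraint_map()]); optimisation
#' runs in the free coordinates. The multistart uses successive halving:
#' seeded candidate starts (rates uniform in `[0.1, 1]`, `rho0` spread
#' between 0.1 and the variance of first differences of observed counts,
#' `rho1` at 0.1) are screened by one objective evaluation, survivors get a
#' short quasi-Newton burst, and the best `restarts` of those are optimised
#' fully; a final probe re-optimises from the best rates with `rho0` reset
#' small to escape the noise-dominated ridge of the likelihood.
#'
#' @param data long clonal tracking data.frame
#'   (`clone_id`, `time`, `lineage`, `count`), as read by [read_dataset()].
#' @param net a `diffnet` whose observed flags match the dataset.
#' @param control a [fit_control()].
#' @return A `clonenet_fit`: estimated parameters (`psi_free`, `theta`,
#'   `rho`), `loglik`, `aic`, `n_params`, per-outer-iteration `trace`,
#'   `converged`, smoothed belief sequences per clone and the fitted
#'   transition probabilities.
#' @export
fit_network <- function(data, net, control = fit_control()) {
  stopifnot(inherits(net, "diffnet"), inherits(control, "fit_control"))
  data <- validate_dataset(data, nodes = net$nodes)
  if (!nrow(data)) stop("empty dataset")
  prep <- prepare_fit_inputs(data, net, control)
  nf <- prep$cm$n_free
  obj <- make_objective(prep, control)
  grad <- function(psi) numeric_gradient(psi, obj)
  rho0_init <- init_rho0(data)
  n_restarts <- if (is.null(control$psi0)) control$restarts else 1L

  # Multistart by successive halving: draw a pool of candidate starts,
  # discard the worst by one cheap objective evaluation each, run a short
  # quasi-Newton burst from the survivors, and launch the full optimisation
  # only from the best `restarts` of those. The likelihood surface has
  # distinct basins (notably a noise-dominated one where rho0 absorbs the
  # process variability), and a short burst separates basins far more
  # reliably than the raw starting value. The variance-of-first-differences
  # rho0 estimate tracks growth trends as much as measurement noise, so all
  # but the first candidate spread rho0 log-uniformly between 0.1 and that
  # estimate to cover both regimes.
  starts <- if (is.null(control$psi0)) {
    set.seed(control$seed)
    n_cand <- max(16L, 8L * n_restarts)
    cands <- lapply(seq_len(n_cand), function(j) {
      th0 <- runif(nf, 0.1, 1)
      rho0_start <- if (j == 1L) rho0_init else
        10^runif(1, -1, log10(max(rho0_init, 1)))
      c(th0, rho0_start, 0.1)
    })
    vals <- vapply(cands, obj, 0)
    shortlist <- cands[order(vals)[seq_len(min(max(6L, 2L * n_restarts),
                                               n_cand))]]
    burst <- lapply(shortlist, function(p) {
      opt <- optim(p, obj, gr = grad, method = "L-BFGS-B",
                   lower = control$lower, control = list(maxit = 5))
      list(par = opt$par, value = opt$value)
    })
    bvals <- vapply(burst, `[[`, 0, "value")
    lapply(burst[order(bvals)[seq_len(min(n_restarts, length(burst)))]],
           `[[`, "par")
  } else {
    stopifnot(length(control$psi0) == nf + 2)
    list(pmax(as.numeric(control$psi0), control$lower))
  }

  run_outer <- function(psi, restart_id) {
    ll_prev <- -obj(psi)
    trace <- ll_prev
    converged <- FALSE
    n_outer <- 0L
    for (it in seq_len(control$max_outer)) {
      n_outer <- it
      opt <- optim(psi, obj, gr = grad, method = "L-BFGS-B",
                   lower = control$lower,
                   control = list(maxit = control$inner_maxit))
      ll_new <- -opt$value
      if (ll_new < ll_prev) break  # never accept a worse iterate
      psi <- opt$par
      trace <- c(trace, ll_new)
      if (abs(ll_new - ll_prev) < control$tol_ll * max(1, abs(ll_new))) {
        converged <- TRUE
        ll_prev <- ll_new
        break
      }
      ll_prev <- ll_new
    }
    list(psi = psi, loglik = ll_prev, trace = trace, converged = converged,
         n_iterations = n_outer, restart = restart_id)
  }

  best <- NULL
  for (r in seq_along(starts)) {
    cand <- run_outer(starts[[r]], r)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  # Noise-reattribution probe: the surface has a spurious basin in which a
  # large rho0 soaks up the process variability while the rates sit near
  # their true values. Re-optimising from the best rates with rho0 reset to
  # a small value escapes that ridge when it was hit; the better optimum is
  # kept either way.
  if (is.null(control$psi0) && best$psi[nf + 1] > 1) {
    probe <- best$psi
    probe[nf + 1] <- 0.1
    cand <- run_outer(probe, best$restart)
    if (cand$loglik > best$loglik) best <- cand
  }
  if (!best$converged) {
    warning("fit did not converge within max_outer iterations; ",
            "best iterate returned")
  }

  psi_hat <- setNames(best$psi, c(prep$cm$free_names, "rho0", "rho1"))
  theta_hat <- expand_theta(prep$cm, psi_hat[seq_len(nf)])
  rho_hat <- c(rho0 = unname(psi_hat[nf + 1]), rho1 = unname(psi_hat[nf + 2]))
  psi_list <- list(theta = theta_hat, rho = unname(rho_hat))

  smoothed <- lapply(prep$clone_data, function(cd) {
    b <- filter_clone(cd$obs, list(mean = cd$m0, cov = cd$P0), psi_list,
                      prep$rs, substeps = control$substeps,
                      diffusion_dt_scaling = control$diffusion_dt_scaling)
    smooth_clone(b, theta_hat, prep$rs,
                 smoother_expm_dt = control$smoother_expm_dt)
  })

  n_params <- nf + 2L
  structure(list(
    psi_free = psi_hat, theta = theta_hat, rho = rho_hat,
    loglik = best$loglik, n_params = n_params,
    aic = 2 * n_params - 2 * best$loglik,
    converged = best$converged, n_iterations = best$n_iterations,
    restart = best$restart, trace = best$trace,
    smoothed = smoothed,
    transition_probs = tryCatch(transition_probabilities(net, theta_hat),
                                error = function(e) NULL),
    constraint_map = prep$cm, net = net, control = control,
    n_clones = length(prep$clone_data), n_obs = nrow(data)
  ), class = "clonenet_fit")
}

#' @export
print.clonenet_fit <- function(x, ...) {
  cat("Differentiation-network fit:", x$n_clones, "clones,", x$n_obs,
      "observations\n")
  cat("  log-likelihood:", format(x$loglik), "  AIC:", format(x$aic),
      "  parameters:", x$n_params,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  rates:\n")
  print(round(x$theta, 4))
  cat("  noise: rho0 =", format(x$rho["rho0"], digits = 4),
      ", rho1 =", format(x$rho["rho1"], digits = 4), "\n")
  invisible(x)
}

#' @export
logLik.clonenet_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2 p - 2 l` with `p` the number of free parameters after the
#' identifiability constraints (free rates plus the two noise parameters) —
#' constrained rates are deterministic functions of free ones and are not
#' counted.
#'
#' @param object a `clonenet_fit`.
#' @param ... ignored.
#' @param k penalty per parameter (default 2).
#' @return Scalar AIC.
#' @export
AIC.clonenet_fit <- function(object, ..., k = 2) {
  k * object$n_params - 2 * object$loglik
}

#' Compare candidate differentiation networks by AIC
#'
#' Fits each candidate independently (fresh initialisation seeds per model;
#' the noise parameters are re-estimated per model) and ranks them by
#' ascending AIC, ties broken by fewer parameters and then declaration
#' order. A model that fails to fit is kept in the table with `AIC = Inf`
#' and its error message, never dropped silently.
#'
#' @param data long clonal tracking data.frame.
#' @param nets named list of `diffnet` candidates (at least one; unnamed
#'   lists get `model1`, `model2`, ...).
#' @param control a [fit_control()]; each model `i` is fitted with seed
#'   `control$seed + 101 * (i - 1)`.
#' @return A data.frame of class `clonenet_ranking` with columns `model`,
#'   `loglik`, `n_params`, `aic`, `converged`, `note`, sorted by AIC, with
#'   the fits in `attr(, "fits")`.
#' @export
compare_networks <- function(data, nets, control = fit_control()) {
  stopifnot(is.list(nets), length(nets) >= 1)
  if (is.null(names(nets)) || any(names(nets) == "")) {
    names(nets) <- paste0("model", seq_along(nets))
  }
  rows <- vector("list", length(nets))
  fits <- vector("list", length(nets))
  names(fits) <- names(nets)
  for (i in seq_along(nets)) {
    ctrl <- control
    ctrl$seed <- control$seed + 101L * (i - 1L)
    res <- tryCatch(fit_network(data, nets[[i]], ctrl), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(model = names(nets)[i], loglik = NA_real_,
                              n_params = NA_integer_, aic = Inf,
                              converged = FALSE,
                              note = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(model = names(nets)[i], loglik = res$loglik,
                              n_params = res$n_params, aic = res$aic,
                              converged = res$converged, note = "",
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$n_params, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("clonenet_ranking", "data.frame")
  tab
}

#' Write a fit report to JSON
#'
#' Machine-readable record of a fit: full and free parameter estimates,
#' log-likelihood, AIC, convergence information and an echo of the control
#' settings — enough to reproduce the run.
#'
#' @param fit a `clonenet_fit`.
#' @param path output JSON path.
#' @return Invisibly, the report list.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "clonenet_fit"))
  ctrl <- fit$control
  ctrl$psi0 <- NULL
  report <- list(
    package_version = as.character(packageVersion("clonenet")),
    theta = as.list(fit$theta),
    rho = as.list(fit$rho),
    psi_free = as.list(fit$psi_free),
    loglik = fit$loglik, aic = fit$aic, n_params = fit$n_params,
    converged = fit$converged, n_iterations = fit$n_iterations,
    seed = ctrl$seed, control = ctrl[!vapply(ctrl, is.null, TRUE)],
    transition_probabilities = fit$transition_probs
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
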