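#' Build a per-clone observation sequence
#'
#' Packs one clone's records into the structure consumed by the filter:
#' strictly increasing observation times, and for each time the indices of
#' the measured state coordinates (the rows of the selection matrix) with
#' their measured values. Times with no surviving record simply do not
#' appear; a lineage absent at a time is unobserved there.
#'
#' @param times numeric vector of observation times (strictly increasing).
#' @param lineages list (one element per time) of lineage-name vectors.
#' @param values list (one element per time) of measured counts, matching
#'   `lineages`.
#' @param rs a `reaction_system` (fixes the state order).
#' @return An `observation_sequence`.
#' @export
observation_sequence <- function(times, lineages, values, rs) {
  stopifnot(inherits(rs, "reaction_system"),
            length(times) == length(lineages),
            length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("observation times must be strictly increasing")
  }
  obs_idx <- lapply(lineages, function(l) {
    idx <- match(l, rs$nodes)
    if (anyNA(idx)) stop("unknown lineage name(s): ",
                         paste(l[is.na(idx)], collapse = ", "))
    as.integer(idx)
  })
  structure(list(times = as.numeric(times), obs_idx = obs_idx,
                 ys = lapply(values, as.numeric), n = rs$n),
            class = "observation_sequence")
}

#' Single Gaussian correction step of the extended Kalman filter
#'
#' Given the predictive moments `(m*, P*)` and a measurement `y` of the
#' state coordinates `obs_idx`, computes the innovation moments
#' `mu = G m*`, `S = G P* G' + R` with `R = rho0 I + rho1 diag(max(G m*, 0))`
#' (the noise variance is evaluated at the predictive mean since the true
#' state is unknown at update time), the gain `K = P* G' S^-1`, the filtered
#' moments, and the log-likelihood increment `log N(y; mu, S)`. Covariance
#' inversions go through a Cholesky factorisation with escalating diagonal
#' jitter (1e-9 to 1e-6); failure beyond that raises a conditioning error.
#'
#' @param pred list with `mean` and `cov` (the predictive moments).
#' @param y measured values.
#' @param obs_idx integer indices of the measured state coordinates
#'   (distinct; empty means no measurement, returning `pred` unchanged with
#'   a zero log-likelihood increment).
#' @param rho length-2 noise vector `c(rho0, rho1)`.
#' @return List with `mean`, `cov`, `innovation_mean`, `innovation_cov`,
#'   `gain` and `loglik`.
#' @examples
#' kf_update(list(mean = 10, cov = matrix(4, 1, 1)), y = 12, obs_idx = 1,
#'           rho = c(1, 0))
#' @export
kf_update <- function(pred, y, obs_idx, rho) {
  stopifnot(length(rho) == 2, all(rho >= 0))
  m <- as.numeric(pred$mean)
  P <- as.matrix(pred$cov)
  obs_idx <- as.integer(obs_idx)
  if (anyDuplicated(obs_idx)) stop("obs_idx must select distinct coordinates")
  if (length(obs_idx) == 0) {
    return(list(mean = m, cov = P, innovation_mean = numeric(0),
                innovation_cov = matrix(0, 0, 0), gain = matrix(0, length(m), 0),
                loglik = 0))
  }
  stopifnot(all(obs_idx >= 1), all(obs_idx <= length(m)), all(is.finite(y)))
  out <- cpp_update(m, P, obs_idx, as.numeric(y), rho[1], rho[2])
  gain <- (P[, obs_idx, drop = FALSE]) %*% solve(out$innovation_cov)
  list(mean = as.numeric(out$mean), cov = out$cov,
       innovation_mean = as.numeric(out$innovation_mean),
       innovation_cov = out$innovation_cov, gain = gain,
       loglik = out$loglik)
}

#' Run the forward (filtering) pass over one clone
#'
#' Alternates moment prediction (see [propagate_moments()]) and Gaussian
#' correction (see [kf_update()]) over the clone's observation times. The
#' prior sits at `prior_time` (default: the first observation time, so the
#' first predictive distribution is the prior itself). The marginal
#' log-likelihood is the sum of the per-time innovation log-densities.
#'
#' @param obs an `observation_sequence`.
#' @param prior list with `mean` (length n) and `cov` (n x n PSD).
#' @param psi list with `theta` (full named rate vector) and `rho`
#'   (`c(rho0, rho1)`).
#' @param rs a `reaction_system`.
#' @param prior_time time at which the prior is anchored (default
#'   `obs$times[1]`).
#' @param substeps,diffusion_dt_scaling passed to the moment integrator.
#' @return A `belief_sequence`: predictive and filtered moments, innovation
#'   moments and the total `loglik`.
#' @export
filter_clone <- function(obs, prior, psi, rs, prior_time = NULL,
                         substeps = 32,
                         diffusion_dt_scaling = c("local", "unit")) {
  stopifnot(inherits(obs, "observation_sequence"), inherits(rs, "reaction_system"))
  diffusion_dt_scaling <- match.arg(diffusion_dt_scaling)
  if (is.null(prior_time)) prior_time <- obs$times[1]
  stopifnot(prior_time <= obs$times[1])
  dts <- diff(c(prior_time, obs$times))
  A <- linearize(psi$theta, rs)
  out <- cpp_filter_clone(dts, obs$obs_idx, obs$ys, as.numeric(prior$mean),
                          as.matrix(prior$cov), A, rs$V,
                          as.numeric(psi$theta[rs$rate_index]), rs$src,
                          psi$rho[1], psi$rho[2], as.integer(substeps),
                          if (diffusion_dt_scaling == "local") 1L else 0L,
                          TRUE)
  rownames(out$m_pred) <- rs$nodes
  rownames(out$m_filt) <- rs$nodes
  structure(list(times = obs$times, dts = dts, obs = obs,
                 m_pred = out$m_pred, P_pred = out$P_pred,
                 m_filt = out$m_filt, P_filt = out$P_filt,
                 innovation_mean = out$innovation_mean,
                 innovation_cov = out$innovation_cov,
                 loglik = out$loglik, n = rs$n, nodes = rs$nodes),
            class = "belief_sequence")
}

#' Rauch-Tung-Striebel smoothing of a filtered belief sequence
#'
#' Backward recursion from the last observation time: the smoother gain is
#' `B_{k+1} = P_k expm(A' s) (P*_{k+1})^{-1}` and
#' `m^s_k = m_k + B_{k+1} (m^s_{k+1} - m*_{k+1})`,
#' `P^s_k = P_k + B_{k+1} (P^s_{k+1} - P*_{k+1}) B'_{k+1}`, seeded with the
#' filtered moments at the final time. The exponent is scaled by the
#' inter-observation interval `s = t_{k+1} - t_k` by default
#' (`smoother_expm_dt = "interval"`, dimensionally consistent with the mean
#' transition); `"unit"` keeps a fixed unit exponent.
#'
#' @param beliefs a `belief_sequence` from [filter_clone()].
#' @param theta full named rate vector (same as used for filtering).
#' @param rs a `reaction_system`.
#' @param smoother_expm_dt `"interval"` or `"unit"`.
#' @return The `belief_sequence` with `m_smooth` and `P_smooth` added.
#' @export
smooth_clone <- function(beliefs, theta, rs,
                         smoother_expm_dt = c("interval", "unit")) {
  stopifnot(inherits(beliefs, "belief_sequence"), inherits(rs, "reaction_system"))
  smoother_expm_dt <- match.arg(smoother_expm_dt)
  A <- linearize(theta, rs)
  out <- cpp_smooth_clone(beliefs$m_pred, beliefs$P_pred, beliefs$m_filt,
                          beliefs$P_filt, A, beliefs$dts,
                          smoother_expm_dt == "interval")
  beliefs$m_smooth <- out$mean
  rownames(beliefs$m_smooth) <- beliefs$nodes
  beliefs$P_smooth <- out$cov
  beliefs
}

#' @export
print.belief_sequence <- function(x, ...) {
  cat("Gaussian belief sequence:", length(x$times), "observation times,",
      x$n, "lineages; marginal log-likelihood", format(x$loglik), "\n")
  if (!is.null(x$m_smooth)) cat("  (smoothed)\n")
  invisible(x)
}

# ---- dataset -> per-clone filter inputs -------------------------------------

# Split a validated long dataset into per-clone observation sequences plus
# empirical priors. The prior mean takes the clone's first-time measurements
# for measured lineages and `prior_unobserved` elsewhere (default: mean of
# the first-time measurements, floored at 1). The prior covariance is
# diagonal: max(m0, 1) * prior_var_scale for coordinates anchored by a
# first-time measurement, and a diffuse (max clone count + 1)^2 *
# prior_var_scale for coordinates whose prior mean is only a guess —
# an overconfident prior on an unmeasured compartment otherwise forces the
# filter to absorb the mismatch into inflated process noise.
build_clone_data <- function(dataset, net, rs, prior_unobserved = NULL,
                             prior_var_scale = 1) {
  dataset <- validate_dataset(dataset, nodes = net$nodes)
  clones <- sort(unique(dataset$clone_id))
  out <- vector("list", length(clones))
  names(out) <- clones
  for (ci in seq_along(clones)) {
    d <- dataset[dataset$clone_id == clones[ci], , drop = FALSE]
    times <- sort(unique(d$time))
    lineages <- vector("list", length(times))
    values <- vector("list", length(times))
    for (k in seq_along(times)) {
      dk <- d[d$time == times[k], , drop = FALSE]
      lineages[[k]] <- dk$lineage
      values[[k]] <- dk$count
    }
    obs <- observation_sequence(times, lineages, values, rs)
    m0 <- setNames(numeric(rs$n), rs$nodes)
    fill <- if (is.null(prior_unobserved)) {
      max(mean(values[[1]]), 1)
    } else prior_unobserved
    m0[] <- fill
    m0[lineages[[1]]] <- values[[1]]
    v0 <- rep((max(d$count) + 1)^2 * prior_var_scale, rs$n)
    v0[match(lineages[[1]], rs$nodes)] <-
      pmax(values[[1]], 1) * prior_var_scale
    P0 <- diag(v0, rs$n)
    out[[ci]] <- list(obs = obs, m0 = unname(m0), P0 = P0,
                      dts = diff(c(times[1], times)),
                      obs_idx = obs$obs_idx, ys = obs$ys)
  }
  out
}

#' Extract smoothed state trajectories from a fit
#'
#' Long-format table of the smoothed (posterior) mean and standard deviation
#' of every lineage of every clone at each of its observation times — the
#' reconstruction of the latent cell counts given the full observation
#' record.
#'
#' @param fit a `clonenet_fit` from [fit_network()].
#' @param path optional CSV path; when given the table is also written.
#' @return Data.frame with columns `clone_id`, `time`, `lineage`,
#'   `smoothed_mean`, `smoothed_sd`.
#' @export
smoothed_states <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "clonenet_fit"))
  parts <- lapply(names(fit$smoothed), function(id) {
    b <- fit$smoothed[[id]]
    tau <- length(b$times)
    sds <- vapply(seq_len(tau), function(k) {
      Pk <- matrix(b$P_smooth[, , k], b$n, b$n)
      sqrt(pmax(diag(Pk), 0))
    }, numeric(b$n))
    data.frame(clone_id = id,
               time = rep(b$times, each = b$n),
               lineage = rep(b$nodes, times = tau),
               smoothed_mean = as.vector(b$m_smooth),
               smoothed_sd = as.vector(sds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
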