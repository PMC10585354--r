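# Independent reference implementations used as oracles. Deliberately
# separate from the package's code paths: matrix exponentials via
# Matrix::expm, covariance integrals via fine-grid Simpson quadrature, and
# a textbook discrete-time Kalman filter / RTS smoother.

r_expm <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# beta(m) with floored hazards, recomputed from first principles.
oracle_beta <- function(m, theta, rs) {
  h <- pmax(m[rs$src], 0) * as.numeric(theta[rs$rate_index])
  B <- rs$V %*% diag(h, length(h)) %*% t(rs$V)
  0.5 * (B + t(B))
}

# Q = int_0^dt e^{A(dt-s)} scale*beta(m(s)) e^{A'(dt-s)} ds with
# m(s) = e^{As} m0, by Simpson quadrature on n_grid intervals (n_grid even).
oracle_process_cov <- function(A, m0, theta, rs, dt, scale = 1,
                               n_grid = 512) {
  stopifnot(n_grid %% 2 == 0)
  s <- seq(0, dt, length.out = n_grid + 1)
  h <- dt / n_grid
  Es <- r_expm(A * h)
  w <- c(1, rep(c(4, 2), length.out = n_grid - 1), 1)
  m <- m0
  E_rev <- r_expm(A * dt)           # e^{A(dt - 0)}
  E_step_inv <- r_expm(-A * h)      # walks e^{A(dt-s)} down as s grows
  Q <- matrix(0, nrow(A), ncol(A))
  Erev <- E_rev
  for (i in seq_along(s)) {
    Q <- Q + w[i] * (Erev %*% (scale * oracle_beta(m, theta, rs)) %*% t(Erev))
    m <- as.vector(Es %*% m)
    Erev <- Erev %*% E_step_inv
  }
  Q * h / 3
}

# Textbook discrete-time Kalman filter over one clone: transition
# F_k = e^{A dt_k}, process noise Q_k from the quadrature above, measurement
# noise R = rho0 I + rho1 diag(max(G m_pred, 0)) to match the package's
# convention. Returns all moments and the marginal log-likelihood.
oracle_kf <- function(dts, obs_idx, ys, m0, P0, A, theta, rs, rho,
                      scale_mode = c("unit", "interval"), n_grid = 512) {
  scale_mode <- match.arg(scale_mode)
  n <- length(m0)
  tau <- length(dts)
  m <- m0; P <- P0
  m_pred <- matrix(NA_real_, n, tau); m_filt <- m_pred
  P_pred <- array(NA_real_, c(n, n, tau)); P_filt <- P_pred
  ll <- 0
  for (k in seq_len(tau)) {
    dt <- dts[k]
    if (dt > 0) {
      F_k <- r_expm(A * dt)
      scale <- if (scale_mode == "interval") dt else 1
      Q_k <- oracle_process_cov(A, m, theta, rs, dt, scale, n_grid)
      m <- as.vector(F_k %*% m)
      P <- F_k %*% P %*% t(F_k) + Q_k
    }
    m_pred[, k] <- m; P_pred[, , k] <- P
    idx <- obs_idx[[k]]
    if (length(idx)) {
      y <- ys[[k]]
      mu <- m[idx]
      R <- diag(rho[1] + rho[2] * pmax(mu, 0), length(idx))
      S <- P[idx, idx, drop = FALSE] + R
      K <- P[, idx, drop = FALSE] %*% solve(S)
      ll <- ll + as.numeric(mvn_logdens(y, mu, S))
      m <- m + as.vector(K %*% (y - mu))
      P <- P - K %*% S %*% t(K)
      P <- 0.5 * (P + t(P))
    }
    m_filt[, k] <- m; P_filt[, , k] <- P
  }
  list(m_pred = m_pred, P_pred = P_pred, m_filt = m_filt, P_filt = P_filt,
       loglik = ll)
}

# Textbook fixed-interval RTS smoother on the oracle filter output.
oracle_rts <- function(kf, A, dts) {
  n <- nrow(kf$m_filt); tau <- ncol(kf$m_filt)
  ms <- kf$m_filt; Ps <- kf$P_filt
  if (tau < 2) return(list(m_smooth = ms, P_smooth = Ps))
  for (k in seq(tau - 1, 1)) {
    F_next <- r_expm(A * dts[k + 1])
    C <- kf$P_filt[, , k] %*% t(F_next) %*% solve(kf$P_pred[, , k + 1])
    ms[, k] <- kf$m_filt[, k] + C %*% (ms[, k + 1] - kf$m_pred[, k + 1])
    Pk <- kf$P_filt[, , k] +
      C %*% (Ps[, , k + 1] - kf$P_pred[, , k + 1]) %*% t(C)
    Ps[, , k] <- 0.5 * (Pk + t(Pk))
  }
  list(m_smooth = ms, P_smooth = Ps)
}

mvn_logdens <- function(y, mu, S) {
  d <- length(y)
  -0.5 * d * log(2 * pi) - 0.5 * determinant(S, logarithm = TRUE)$modulus -
    0.5 * t(y - mu) %*% solve(S) %*% (y - mu)
}
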