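test_that("the scalar correction step matches the hand-worked values", {
  u <- kf_update(list(mean = 10, cov = matrix(4, 1, 1)), y = 12, obs_idx = 1,
                 rho = c(1, 0))
  expect_equal(u$innovation_mean, 10)
  expect_equal(u$innovation_cov[1, 1], 5, tolerance = 1e-8)
  expect_equal(u$gain[1, 1], 0.8, tolerance = 1e-8)
  expect_equal(u$mean, 11.6, tolerance = 1e-7)
  expect_equal(u$cov[1, 1], 0.8, tolerance = 1e-7)
  expect_equal(u$loglik, -0.5 * log(2 * pi * 5) - 0.4, tolerance = 1e-7)
})

test_that("an empty selection leaves the prediction untouched", {
  pred <- list(mean = c(3, 4), cov = diag(2))
  u <- kf_update(pred, numeric(0), integer(0), c(1, 0))
  expect_equal(u$mean, pred$mean)
  expect_equal(u$cov, pred$cov)
  expect_equal(u$loglik, 0)
})

test_that("the exact-measurement limit collapses onto the observation", {
  P <- rbind(c(4, 1), c(1, 3))
  u <- kf_update(list(mean = c(10, 20), cov = P), y = c(12, 19),
                 obs_idx = 1:2, rho = c(1e-10, 0))
  expect_equal(u$mean, c(12, 19), tolerance = 1e-6)
  expect_lt(max(abs(u$cov)), 1e-6)
})

test_that("a single-observation filter reproduces the lone update", {
  solo <- differentiation_network("A", dup = FALSE, death = FALSE)
  rs <- build_reaction_system(solo)
  obs <- observation_sequence(2, list("A"), list(12), rs)
  psi <- list(theta = rate_parameters(rs), rho = c(1, 0))
  b <- filter_clone(obs, list(mean = 10, cov = matrix(4, 1, 1)), psi, rs)
  expect_equal(b$loglik, -0.5 * log(2 * pi * 5) - 0.4, tolerance = 1e-7)
  expect_equal(unname(b$m_filt[1, 1]), 11.6, tolerance = 1e-7)
})

test_that("a fully missing clone contributes nothing to the likelihood", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  psi <- list(theta = two_node_theta(rs), rho = c(1, 0.1))
  obs <- observation_sequence(c(1, 2, 3), list(character(0), character(0),
                                               character(0)),
                              list(numeric(0), numeric(0), numeric(0)), rs)
  b <- filter_clone(obs, list(mean = c(10, 5), cov = diag(2)), psi, rs)
  expect_equal(b$loglik, 0)
  expect_equal(b$m_filt, b$m_pred)
})

test_that("filter and smoother match the discrete Kalman/RTS oracle", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  rho <- c(0.5, 0.05)
  A <- linearize(theta, rs)
  set.seed(41)
  times <- 1:6
  # partial selections, including one empty time
  lineages <- list("A", c("A", "B"), "B", character(0), c("A", "B"), "A")
  values <- lapply(lineages, function(l) 60 * runif(length(l)) + 10)
  obs <- observation_sequence(times, lineages, values, rs)
  prior <- list(mean = c(70, 15), cov = diag(c(10, 4)))
  b <- filter_clone(obs, prior, list(theta = theta, rho = rho), rs,
                    substeps = 64, diffusion_dt_scaling = "unit")
  b <- smooth_clone(b, theta, rs, smoother_expm_dt = "interval")
  ok <- oracle_kf(b$dts, obs$obs_idx, obs$ys, prior$mean, prior$cov, A,
                  theta, rs, rho, scale_mode = "unit", n_grid = 2048)
  expect_equal(b$loglik, ok$loglik, tolerance = 1e-6)
  expect_equal(unname(b$m_pred), ok$m_pred, tolerance = 1e-6)
  expect_equal(unname(b$m_filt), ok$m_filt, tolerance = 1e-6)
  expect_equal(b$P_filt, ok$P_filt, tolerance = 1e-6)
  ors <- oracle_rts(ok, A, b$dts)
  expect_equal(unname(b$m_smooth), ors$m_smooth, tolerance = 1e-6)
  expect_equal(b$P_smooth, ors$P_smooth, tolerance = 1e-6)
})

test_that("smoothing base cases: one time point, and identity dynamics", {
  # tau = 1: smoothed = filtered
  solo <- differentiation_network("A", dup = FALSE, death = FALSE)
  rs1 <- build_reaction_system(solo)
  obs1 <- observation_sequence(1, list("A"), list(12), rs1)
  psi1 <- list(theta = rate_parameters(rs1), rho = c(1, 0))
  b1 <- smooth_clone(filter_clone(obs1, list(mean = 10, cov = matrix(4, 1, 1)),
                                  psi1, rs1), psi1$theta, rs1)
  expect_equal(b1$m_smooth, b1$m_filt)
  expect_equal(b1$P_smooth, b1$P_filt)

  # zero rates, no observation at t2: the backward step is the identity
  net <- two_node_net()
  rs <- build_reaction_system(net)
  psi <- list(theta = rate_parameters(rs), rho = c(1, 0))
  obs <- observation_sequence(c(1, 2), list(c("A", "B"), character(0)),
                              list(c(12, 6), numeric(0)), rs)
  b <- smooth_clone(filter_clone(obs, list(mean = c(10, 5), cov = diag(2)),
                                 psi, rs), psi$theta, rs)
  expect_equal(b$m_smooth[, 1], b$m_filt[, 1], tolerance = 1e-10)
})

test_that("smoothing never inflates the marginal state variance", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  psi <- list(theta = theta, rho = c(0.5, 0.02))
  set.seed(51)
  for (rep in 1:5) {
    times <- sort(sample(seq(0.5, 8, 0.5), 5))
    lineages <- lapply(1:5, function(i) sample(c("A", "B"),
                                               sample(1:2, 1)))
    values <- lapply(lineages, function(l) runif(length(l), 5, 80))
    obs <- observation_sequence(times, lineages, values, rs)
    b <- smooth_clone(filter_clone(obs, list(mean = c(60, 20), cov = diag(c(9, 9))),
                                   psi, rs), theta, rs)
    for (k in seq_along(times)) {
      expect_true(all(diag(b$P_smooth[, , k]) <=
                        diag(b$P_filt[, , k]) + 1e-8))
    }
  }
})

test_that("the reported likelihood equals the innovation log-densities", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  psi <- list(theta = theta, rho = c(0.5, 0.05))
  obs <- observation_sequence(1:4, list("A", c("A", "B"), "B", c("A", "B")),
                              list(50, c(40, 18), 25, c(30, 35)), rs)
  b <- filter_clone(obs, list(mean = c(60, 10), cov = diag(c(10, 10))), psi, rs)
  ll <- 0
  for (k in 1:4) {
    mu <- b$innovation_mean[[k]]
    S <- b$innovation_cov[[k]]
    y <- obs$ys[[k]]
    ll <- ll + as.numeric(mvn_logdens(y, mu, S))
  }
  expect_equal(b$loglik, ll, tolerance = 1e-12)
})
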