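test_that("hazards are the mass-action rates times source counts", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  expect_equal(hazard(c(10, 5), theta, rs), c(2, 1, 2, 0.25, 3))
  expect_equal(hazard(c(0, 0), theta, rs), rep(0, 5))
  expect_equal(hazard(c(10, 5), rate_parameters(rs), rs), rep(0, 5))
})

test_that("drift and diffusion match the hand-computed jump moments", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  dd <- drift_diffusion(c(10, 5), theta, rs)
  expect_equal(dd$mu, c(-2, 7.75))
  expect_equal(unname(dd$beta), rbind(c(6, -6), c(-6, 14.25)))
  z <- drift_diffusion(c(0, 0), theta, rs)
  expect_equal(z$mu, c(0, 0))
  expect_equal(unname(z$beta), matrix(0, 2, 2))
})

test_that("the linear generator reproduces V h(x) for all states", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  A <- linearize(theta, rs)
  expect_equal(unname(A), rbind(c(-0.2, 0), c(0.6, 0.35)))
  expect_equal(as.vector(A %*% c(10, 5)), c(-2, 7.75))
  expect_equal(unname(linearize(rate_parameters(rs), rs)), matrix(0, 2, 2))
  solo <- differentiation_network("A", dup = FALSE)
  rs1 <- build_reaction_system(solo)
  expect_equal(unname(linearize(rate_parameters(rs1, delta = 0.1), rs1)),
               matrix(-0.1, 1, 1))
})

test_that("generator/hazard consistency holds on random systems", {
  set.seed(3)
  worst <- 0
  for (rep in 1:10) {
    net <- random_tree_net(sample(2:8, 1), seed = rep + 100)
    rs <- build_reaction_system(net)
    for (i in 1:100) {
      theta <- random_theta(rs)
      A <- linearize(theta, rs)
      x <- runif(rs$n, -50, 50)
      worst <- max(worst, max(abs(A %*% x - rs$V %*% hazard(x, theta, rs))))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("diffusion matrices are PSD for nonnegative states and rates", {
  set.seed(5)
  for (rep in 1:10) {
    net <- random_tree_net(sample(2:8, 1), seed = rep + 200)
    rs <- build_reaction_system(net)
    theta <- random_theta(rs)
    x <- runif(rs$n, 0, 100)
    ev <- eigen(drift_diffusion(x, theta, rs)$beta, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("moment propagation is exact for the mean and idle at zero rates", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  start <- list(mean = c(10, 5), cov = diag(c(2, 3)))
  out0 <- propagate_moments(start, rate_parameters(rs), rs, dt = 2)
  expect_equal(out0$mean, start$mean)
  expect_equal(out0$cov, start$cov)

  solo <- differentiation_network("A", dup = FALSE)
  rs1 <- build_reaction_system(solo)
  th1 <- rate_parameters(rs1, delta = 0.1)
  out <- propagate_moments(list(mean = 100, cov = matrix(0, 1, 1)), th1, rs1,
                           dt = 5)
  expect_equal(out$mean, 100 * exp(-0.5), tolerance = 1e-8)

  # random 3-node generator vs the independent matrix exponential
  net3 <- differentiation_network(c("S", "X", "Y"),
                                  rbind(c("S", "X"), c("S", "Y")))
  rs3 <- build_reaction_system(net3)
  set.seed(9)
  for (i in 1:10) {
    theta <- random_theta(rs3)
    m0 <- runif(3, 1, 100)
    out <- propagate_moments(list(mean = m0, cov = diag(3)), theta, rs3,
                             dt = 1.7)
    expect_equal(out$mean, as.vector(r_expm(linearize(theta, rs3) * 1.7) %*% m0),
                 tolerance = 1e-8)
  }
})

test_that("covariance integration matches a fine-grid quadrature oracle", {
  solo <- differentiation_network("A", dup = FALSE)
  rs1 <- build_reaction_system(solo)
  th1 <- rate_parameters(rs1, delta = 0.1)
  A <- linearize(th1, rs1)
  # dt = 1: the interval-scaled and unit-scaled variants coincide
  out <- propagate_moments(list(mean = 100, cov = matrix(0, 1, 1)), th1, rs1,
                           dt = 1, diffusion_dt_scaling = "unit")
  Q <- oracle_process_cov(A, 100, th1, rs1, dt = 1, scale = 1, n_grid = 2048)
  expect_equal(out$cov[1, 1], Q[1, 1], tolerance = 1e-6)

  # 2-node system, both scaling conventions, against the same oracle
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  A2 <- linearize(theta, rs)
  m0 <- c(80, 10)
  P0 <- diag(c(4, 1))
  for (mode in c("unit", "local")) {
    dt <- 2.5
    s <- if (mode == "local") dt else 1
    out2 <- propagate_moments(list(mean = m0, cov = P0), theta, rs, dt = dt,
                              substeps = 64, diffusion_dt_scaling = mode)
    F2 <- r_expm(A2 * dt)
    expected <- F2 %*% P0 %*% t(F2) +
      oracle_process_cov(A2, m0, theta, rs, dt, scale = s, n_grid = 2048)
    expect_equal(out2$cov, unname(as.matrix(expected)), tolerance = 1e-6)
  }
})

test_that("covariance is insensitive to doubling the substeps", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  start <- list(mean = c(80, 10), cov = diag(c(4, 1)))
  a <- propagate_moments(start, theta, rs, dt = 2, substeps = 32)
  b <- propagate_moments(start, theta, rs, dt = 2, substeps = 64)
  expect_equal(a$cov, b$cov, tolerance = 1e-6)
})

test_that("mean propagation composes over subintervals (semigroup property)", {
  net <- two_node_net()
  rs <- build_reaction_system(net)
  theta <- two_node_theta(rs)
  start <- list(mean = c(80, 10), cov = diag(2))
  one <- propagate_moments(start, theta, rs, dt = 3)
  two <- propagate_moments(propagate_moments(start, theta, rs, dt = 1.5),
                           theta, rs, dt = 1.5)
  expect_equal(one$mean, two$mean, tolerance = 1e-10)
  # covariance composes under unit scaling (autonomous in P given the path)
  oneu <- propagate_moments(start, theta, rs, dt = 3, substeps = 64,
                            diffusion_dt_scaling = "unit")
  twou <- propagate_moments(
    propagate_moments(start, theta, rs, dt = 1.5, substeps = 64,
                      diffusion_dt_scaling = "unit"),
    theta, rs, dt = 1.5, substeps = 64, diffusion_dt_scaling = "unit")
  expect_equal(oneu$cov, twou$cov, tolerance = 1e-6)
})
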