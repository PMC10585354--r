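make_static_dataset <- function() {
  # one clone, one time point, one lineage
  data.frame(clone_id = "c1", time = 1, lineage = "A", count = 12,
             stringsAsFactors = FALSE)
}

static_net <- function() {
  differentiation_network("A", dup = FALSE, death = FALSE)
}

test_that("the objective reproduces the hand-worked single-update value", {
  # prior mean 12 (the observation), variance 12; S = 12 + rho0
  net <- static_net()
  ctl <- fit_control()
  val <- neg_marginal_loglik(c(1, 0), make_static_dataset(), net, ctl)
  expect_equal(val, 0.5 * log(2 * pi * (12 + 1 + 1e-9)), tolerance = 1e-9)
})

test_that("the likelihood is additive over clones and order-invariant", {
  b <- make_benchmark("insilico-small", n_clones = 4, seed = 5)
  net <- b$net
  ctl <- fit_control()
  prep <- clonenet:::prepare_fit_inputs(b$dataset, net, ctl)
  psi <- c(unname(b$truth$theta[prep$cm$free_names]), 0.5, 0.1)
  total <- neg_marginal_loglik(psi, b$dataset, net, ctl)
  per_clone <- vapply(unique(b$dataset$clone_id), function(id) {
    neg_marginal_loglik(psi, b$dataset[b$dataset$clone_id == id, ], net, ctl)
  }, 0)
  expect_equal(total, sum(per_clone), tolerance = 1e-10)
  shuffled <- b$dataset[sample(nrow(b$dataset)), ]
  expect_equal(neg_marginal_loglik(psi, shuffled, net, ctl), total,
               tolerance = 1e-12)
  # duplicating the sole clone's data doubles the value
  one <- b$dataset[b$dataset$clone_id == "clone001", ]
  two <- one
  two$clone_id <- "clone999"
  expect_equal(neg_marginal_loglik(psi, rbind(one, two), net, ctl),
               2 * neg_marginal_loglik(psi, one, net, ctl), tolerance = 1e-10)
})

test_that("identity constraint maps leave the objective unchanged", {
  b <- make_benchmark("insilico-small", n_clones = 2, seed = 6)
  ctl_c <- fit_control()  # all nodes observed: map is identity anyway
  cm <- build_constraint_map(b$net)
  expect_equal(cm$n_free, cm$n_full)
  psi <- c(unname(b$truth$theta), 0.5, 0.1)
  v1 <- neg_marginal_loglik(psi, b$dataset, b$net, ctl_c)
  ctl_n <- fit_control(use_conservation = FALSE, use_averaging = FALSE)
  expect_identical(neg_marginal_loglik(psi, b$dataset, b$net, ctl_n), v1)
})

test_that("the numeric gradient agrees with analytic and central differences", {
  centre <- c(0.4, 1.2, 3)
  quad <- function(p) sum((p - centre)^2)
  g <- numeric_gradient(c(1, 1, 1), quad)
  expect_equal(g, 2 * (c(1, 1, 1) - centre), tolerance = 1e-4)

  # d/d rho0 of the single-observation log-density, against the closed form
  net <- static_net()
  ctl <- fit_control()
  f <- function(psi) neg_marginal_loglik(psi, make_static_dataset(), net, ctl)
  g2 <- numeric_gradient(c(2, 0), f)
  S <- 12 + 2 + 1e-9
  expect_equal(g2[1], 0.5 / S, tolerance = 1e-4)

  # central-difference oracle on a small real objective
  b <- make_benchmark("insilico-small", n_clones = 2, seed = 8)
  ctl2 <- fit_control()
  prep <- clonenet:::prepare_fit_inputs(b$dataset, b$net, ctl2)
  obj <- clonenet:::make_objective(prep, ctl2)
  psi <- c(unname(b$truth$theta[prep$cm$free_names]), 0.5, 0.1)
  gf <- numeric_gradient(psi, obj)
  gc <- vapply(seq_along(psi), function(i) {
    h <- 1e-5 * max(1, abs(psi[i]))
    up <- psi; up[i] <- psi[i] + h
    dn <- psi; dn[i] <- psi[i] - h
    (obj(up) - obj(dn)) / (2 * h)
  }, 0)
  expect_equal(gf, gc, tolerance = 1e-3)
})

test_that("AIC arithmetic and the free-parameter count are exact", {
  fake <- structure(list(loglik = -100, n_params = 5L), class = "clonenet_fit")
  expect_equal(AIC(fake), 210)
  fake0 <- structure(list(loglik = 0, n_params = 0L), class = "clonenet_fit")
  expect_equal(AIC(fake0), 0)
  fake1 <- structure(list(loglik = -100, n_params = 6L), class = "clonenet_fit")
  expect_equal(AIC(fake1) - AIC(fake), 2)
})

test_that("fitting is deterministic and does not degrade a truth start", {
  b <- make_benchmark("insilico-small", n_clones = 3, seed = 13,
                      overrides = list(observation_times = 1:4))
  ctl <- fit_control(restarts = 1, seed = 3, inner_maxit = 8, max_outer = 2)
  f1 <- suppressWarnings(fit_network(b$dataset, b$net, ctl))
  f2 <- suppressWarnings(fit_network(b$dataset, b$net, ctl))
  expect_identical(f1$psi_free, f2$psi_free)
  expect_identical(f1$loglik, f2$loglik)

  cm <- build_constraint_map(b$net)
  psi_true <- c(unname(b$truth$theta[cm$free_names]), 0.1, 0.01)
  ctl_t <- fit_control(psi0 = psi_true, inner_maxit = 10, max_outer = 3)
  prep <- clonenet:::prepare_fit_inputs(b$dataset, b$net, ctl_t)
  ll_start <- -clonenet:::make_objective(prep, ctl_t)(psi_true)
  suppressWarnings(ft <- fit_network(b$dataset, b$net, ctl_t))
  expect_gte(ft$loglik, ll_start)
  # the outer-loop trace never decreases
  expect_true(all(diff(ft$trace) >= -1e-6))
  # estimates respect the bounds
  expect_true(all(ft$psi_free >= 0))
})

test_that("model comparison returns a complete ranked table", {
  b <- make_benchmark("insilico-small", n_clones = 3, seed = 17,
                      overrides = list(observation_times = 1:4))
  ctl <- fit_control(restarts = 1, inner_maxit = 8, max_outer = 2)
  nets <- list(true_net = b$net, duplicate = b$net)
  suppressWarnings(tab <- compare_networks(b$dataset, nets, ctl))
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$aic, sort(tab$aic))
  expect_true(all(c("model", "loglik", "n_params", "aic") %in% names(tab)))
  # single candidate
  suppressWarnings(tab1 <- compare_networks(b$dataset, list(only = b$net), ctl))
  expect_equal(nrow(tab1), 1L)
  # a failing model is reported, not dropped
  bad <- differentiation_network(c("Z1", "Z2"), rbind(c("Z1", "Z2")))
  suppressWarnings(tab2 <- compare_networks(b$dataset,
                                            list(good = b$net, bad = bad), ctl))
  expect_equal(nrow(tab2), 2L)
  expect_true(is.infinite(tab2$aic[tab2$model == "bad"]))
  expect_match(tab2$note[tab2$model == "bad"], "lineage")
})

test_that("fit reports round-trip through JSON with exact arithmetic", {
  b <- make_benchmark("insilico-small", n_clones = 2, seed = 19,
                      overrides = list(observation_times = 1:3))
  ctl <- fit_control(restarts = 1, inner_maxit = 5, max_outer = 1)
  suppressWarnings(fit <- fit_network(b$dataset, b$net, ctl))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$loglik, fit$loglik)
  expect_equal(rep$n_params, fit$n_params)
  # smoothed-state export covers every clone, lineage and time
  sm <- smoothed_states(fit)
  expect_setequal(unique(sm$clone_id), unique(b$dataset$clone_id))
  expect_setequal(unique(sm$lineage), b$net$nodes)
  expect_true(all(sm$smoothed_sd >= 0))
})
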