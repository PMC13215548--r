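test_that("random-walk structure matrices match their definitions", {
  expect_equal(build_rw_precision(3, 1),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE))
  R2 <- build_rw_precision(12, 2)
  expect_lt(max(abs(R2 %*% rep(1, 12))), 1e-12)
  expect_lt(max(abs(R2 %*% seq_len(12))), 1e-12)
  expect_equal(qr(R2)$rank, 10)
  # explicit second-difference product, T = 5
  D2 <- matrix(0, 3, 5)
  for (k in 1:3) D2[k, k + 0:2] <- c(1, -2, 1)
  expect_equal(build_rw_precision(5, 2), t(D2) %*% D2)
  expect_error(build_rw_precision(10, 3), "order")
})

fit_small <- function(cells, graph, ...) {
  gibbs_fit(cells, graph,
            model_spec(n_iter = 600, n_burn = 200, thin = 2, ...))
}

test_that("the sampler is deterministic and every draw honours its constraints", {
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2014, seed = 44)
  f1 <- fit_small(sim$cells, g, seed = 5)
  f2 <- fit_small(sim$cells, g, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_small(sim$cells, g, seed = 6)
  expect_false(identical(f1$draws$mu, f3$draws$mu))

  d <- f1$draws
  expect_lt(max(abs(rowSums(d$alpha))), 1e-8)
  expect_lt(max(abs(rowSums(d$gamma))), 1e-8)
  expect_lt(max(abs(rowSums(d$theta))), 1e-8)
  expect_lt(max(abs(rowSums(d$phi))), 1e-8)
  # interaction: row and column means vanish within every draw
  for (s in c(1, 50, f1$n_draws)) {
    expect_lt(max(abs(rowMeans(d$delta[s, , ]))), 1e-8)
    expect_lt(max(abs(colMeans(d$delta[s, , ]))), 1e-8)
  }
  expect_true(all(d$tau > 0))
})

test_that("with all effects pinned the posterior of mu matches the closed form", {
  g <- square_graph()
  set.seed(10)
  cells <- data.frame(region = rep(g$region_names, 4),
                      year = rep(2001:2004, each = 4),
                      logit_mean = rnorm(16, -2, 0.5),
                      logit_variance = runif(16, 0.05, 0.2))
  # RW1: pinning tau_gamma removes gamma entirely (its null space, a
  # constant, is absorbed by the sum-to-zero recentring); under RW2 a free
  # linear trend would survive the pin and the scalar closed form would not
  # apply
  pin <- list(alpha = 1e12, gamma = 1e12, theta = 1e12, phi = 1e12,
              delta = 1e12)
  fit <- gibbs_fit(cells, g, model_spec(temporal_order = 1, n_iter = 3000,
                                        n_burn = 500, seed = 2,
                                        fix_tau = pin, thin = 1))
  w <- 1 / cells$logit_variance
  m_true <- sum(w * cells$logit_mean) / (sum(w) + 1e-6)
  v_true <- 1 / (sum(w) + 1e-6)
  mu <- fit$draws$mu
  expect_lt(abs(mean(mu) - m_true), 3 * mcse_mean(mu) + 1e-4)
  expect_equal(var(mu), v_true, tolerance = 0.2)
})

test_that("posterior summaries inherit constraints and recover a strong spatial signal", {
  g <- load_adjacency()
  sim <- simulate_model_cells(g, 1990:2022, var_phi = 0.08, v_obs = 0.005,
                              seed = 77)
  fit <- gibbs_fit(sim$cells, g, model_spec(n_iter = 1200, n_burn = 300,
                                            thin = 2, seed = 9))
  ps <- posterior_summaries(fit)
  phi_med <- ps$median[ps$effect == "phi"]
  # the constraint is exact on each draw (hence on posterior means); the
  # sum of elementwise medians inherits it only up to Monte-Carlo asymmetry
  expect_lt(abs(sum(colMeans(fit$draws$phi))), 1e-8)
  expect_lt(abs(sum(phi_med)), 0.1)
  expect_gt(cor(phi_med, sim$components$phi, method = "spearman"), 0.8)
  u5 <- ps[ps$effect == "u5mr", ]
  expect_true(all(u5$lower <= u5$median & u5$median <= u5$upper))
})

test_that("smoothing beats the raw estimates on noisy synthetic data", {
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2019, v_obs = 0.05, seed = 15)
  fit <- fit_small(sim$cells, g, seed = 3)
  eta_med <- apply(matrix(fit$draws$eta, nrow = fit$n_draws), 2, median)
  mse_fit <- mean((eta_med - as.vector(sim$eta))^2)
  mse_raw <- mean((sim$cells$logit_mean - as.vector(sim$eta))^2)
  expect_lt(mse_fit, mse_raw)
})

test_that("input validation catches bad cells and H = 0 forecasts are empty", {
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2009, seed = 1)
  bad <- sim$cells; bad$region[1] <- "Nowhere"
  expect_error(gibbs_fit(bad, g, model_spec()), "absent from the graph")
  bad2 <- sim$cells; bad2$logit_variance[3] <- 0
  expect_error(gibbs_fit(bad2, g, model_spec()), "positive")

  fit <- fit_small(sim$cells, g, seed = 4)
  expect_equal(nrow(forecast(fit, 0)), 0)
  fc <- forecast(fit, 3, seed = 1)
  expect_equal(nrow(fc), 4 * 3)
  expect_true(all(fc$lower <= fc$median & fc$median <= fc$upper))
})

test_that("missing cells are tolerated and smoothed over", {
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2014, var_phi = 0.1, var_gamma = 1e-4,
                              v_obs = 0.005, seed = 31)
  holes <- sim$cells[-c(3, 17, 40), ]
  fit <- fit_small(holes, g, seed = 8, temporal_order = 2)
  expect_equal(dim(fit$draws$eta)[2:3], c(4, 15))
  eta_med <- apply(matrix(fit$draws$eta, nrow = fit$n_draws), 2, median)
  expect_gt(cor(eta_med, as.vector(sim$eta)), 0.9)
})
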