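# Builds a minimal mort_fit by hand so degenerate draw configurations
# (point masses) can be tested directly.
fake_fit <- function(eta_draws, y, v, order = 2) {
  S <- dim(eta_draws)[1]; n <- dim(eta_draws)[2]; Tt <- dim(eta_draws)[3]
  structure(list(
    draws = list(mu = numeric(S), alpha = matrix(0, S, Tt),
                 gamma = matrix(0, S, Tt), theta = matrix(0, S, n),
                 phi = matrix(0, S, n), delta = array(0, c(S, n, Tt)),
                 eta = eta_draws,
                 tau = matrix(1, S, 5, dimnames = list(NULL,
                   c("alpha", "gamma", "theta", "phi", "delta")))),
    spec = model_spec(temporal_order = order, n_iter = 2, n_burn = 0,
                      thin = 1),
    years = seq_len(Tt), regions = paste0("r", seq_len(n)),
    y = y, v = v, n_draws = S), class = "mort_fit")
}

test_that("DIC collapses correctly on point-mass draws and obeys its identity", {
  n <- 2; Tt <- 3; S <- 150
  y <- matrix(rnorm(6), n, Tt)
  v <- matrix(0.2, n, Tt)
  eta0 <- matrix(0.3, n, Tt)
  draws <- array(rep(eta0, each = S), c(S, n, Tt))
  fit <- fake_fit(draws, y, v)
  d <- dic(fit)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, -2 * sum(dnorm(y, eta0, sqrt(v), log = TRUE)),
               tolerance = 1e-10)
  # identity DIC = mean deviance + pD on a stochastic fit
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2009, seed = 3)
  fit2 <- gibbs_fit(sim$cells, g, model_spec(n_iter = 500, n_burn = 100,
                                             thin = 2, seed = 1))
  d2 <- dic(fit2)
  expect_equal(d2$DIC - d2$mean_deviance, d2$pD)
})

test_that("pD approximates the number of free mean parameters on a diffuse toy", {
  # mu + theta free with an essentially flat prior on theta: k = n free
  # effective parameters (n-1 identified contrasts + the mean)
  g <- square_graph()
  set.seed(8)
  cells <- data.frame(region = rep(g$region_names, 25),
                      year = rep(2001:2025, each = 4),
                      logit_mean = rnorm(100, rep(c(-1, -2, -3, -4), 25), 0.3),
                      logit_variance = 0.09)
  pin <- list(alpha = 1e12, gamma = 1e12, phi = 1e12, delta = 1e12,
              theta = 1e-4)
  fit <- gibbs_fit(cells, g, model_spec(n_iter = 4000, n_burn = 1000,
                                        thin = 2, seed = 12, fix_tau = pin))
  d <- dic(fit)
  expect_equal(d$pD, 4, tolerance = 0.25)
})

test_that("CPO equals the density under point-mass draws and obeys the bound", {
  n <- 2; Tt <- 2; S <- 120
  y <- matrix(c(0.1, -0.4, 0.2, 0), n, Tt)
  v <- matrix(0.25, n, Tt)
  eta0 <- matrix(c(0, 0.1, -0.2, 0.3), n, Tt)
  fit <- fake_fit(array(rep(eta0, each = S), c(S, n, Tt)), y, v)
  cp <- cpo_lcpo(fit)
  expect_equal(unname(cp$CPO), as.vector(dnorm(y, eta0, sqrt(v))),
               tolerance = 1e-12)
  expect_equal(cp$LCPO, sum(dnorm(y, eta0, sqrt(v), log = TRUE)),
               tolerance = 1e-10)

  # harmonic-mean bound: CPO never exceeds the per-cell max draw density
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2009, seed = 21)
  fit2 <- gibbs_fit(sim$cells, g, model_spec(n_iter = 500, n_burn = 100,
                                             thin = 2, seed = 2))
  cp2 <- cpo_lcpo(fit2)
  obs <- which(!is.na(fit2$y))
  eta <- matrix(fit2$draws$eta, nrow = fit2$n_draws)[, obs]
  dmax <- sapply(seq_along(obs), function(j)
    max(dnorm(fit2$y[obs[j]], eta[, j], sqrt(fit2$v[obs[j]]))))
  expect_true(all(cp2$CPO <= dmax + 1e-12))
  expect_true(is.finite(cp2$LCPO))
})

test_that("variance decomposition sums to 100, respects limits and relabeling", {
  n <- 3; Tt <- 4; S <- 110
  base <- fake_fit(array(0, c(S, n, Tt)), matrix(0, n, Tt),
                   matrix(1, n, Tt))
  base$draws$phi <- matrix(rep(c(-1, 0, 1), each = S), S, n)
  vd <- variance_decomposition(base)
  expect_equal(sum(vd$percentage), 100, tolerance = 1e-10)
  expect_equal(vd$percentage[vd$component == "phi"], 100)

  # degenerate: nothing varies
  expect_error(variance_decomposition(
    fake_fit(array(0, c(S, n, Tt)), matrix(0, n, Tt), matrix(1, n, Tt))),
    "degenerate")

  # relabeling regions permutes the spatial draws but leaves shares unchanged
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2014, seed = 51)
  fit <- gibbs_fit(sim$cells, g, model_spec(n_iter = 500, n_burn = 100,
                                            thin = 2, seed = 3))
  vd1 <- variance_decomposition(fit)
  perm <- c(3, 1, 4, 2)
  fitp <- fit
  fitp$regions <- fit$regions[perm]
  fitp$draws$phi <- fit$draws$phi[, perm]
  fitp$draws$theta <- fit$draws$theta[, perm]
  fitp$draws$delta <- fit$draws$delta[, perm, ]
  vd2 <- variance_decomposition(fitp)
  expect_equal(vd1$percentage, vd2$percentage, tolerance = 1e-12)
})

test_that("model comparison reports both criteria, flags ties, rejects mismatches", {
  g <- square_graph()
  sim <- simulate_model_cells(g, 2000:2014, seed = 61)
  fit1 <- gibbs_fit(sim$cells, g, model_spec(temporal_order = 1, n_iter = 500,
                                             n_burn = 100, thin = 2, seed = 4))
  fit2 <- gibbs_fit(sim$cells, g, model_spec(temporal_order = 2, n_iter = 500,
                                             n_burn = 100, thin = 2, seed = 4))
  cmp <- compare_models(fit1, fit2)
  for (m in cmp$models) {
    expect_true(is.finite(m$DIC))
    expect_true(is.finite(m$LCPO))
  }
  expect_true(cmp$selected %in% names(cmp$models))

  tie <- compare_models(fit1, fit1, labels = c("first", "second"))
  expect_true(tie$tie)
  expect_equal(tie$selected, "first")

  other <- simulate_model_cells(g, 2000:2014, seed = 62)
  fit3 <- gibbs_fit(other$cells, g, model_spec(n_iter = 500, n_burn = 100,
                                               thin = 2, seed = 4))
  expect_error(compare_models(fit1, fit3), "different data")
})
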