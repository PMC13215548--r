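test_that("ICAR draws honour the sum-to-zero constraint and degenerate limit", {
  g <- load_adjacency()
  x <- sample_icar(g, precision = 1, seed = 11)
  expect_lt(abs(sum(x)), 1e-9)
  x0 <- sample_icar(g, precision = 1e12, seed = 12)
  expect_lt(max(abs(x0)), 1e-4)
})

test_that("ICAR empirical covariance matches the pseudo-inverse of Q", {
  g <- path3_graph()
  Q <- build_icar_precision(g)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > 1e-10
  Qpinv <- e$vectors[, pos] %*% diag(1 / e$values[pos]) %*% t(e$vectors[, pos])
  set.seed(21)
  draws <- t(replicate(10000, sample_icar(g, precision = 1)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - Qpinv)), 0.06)  # MC error at 10k draws
})

test_that("random-walk draws have the right difference variance and projections", {
  x0 <- sample_rw(20, 2, precision = 1e12, seed = 1)
  expect_lt(max(abs(x0)), 1e-3)
  expect_error(sample_rw(10, 3, 1), "order")

  set.seed(31)
  d2 <- replicate(4000, diff(sample_rw(10, 2, precision = 4), differences = 2))
  expect_equal(mean(d2^2), 1 / 4, tolerance = 0.1)
  set.seed(32)
  d1 <- replicate(4000, diff(sample_rw(2, 1, precision = 1)))
  expect_equal(mean(d1^2), 1, tolerance = 0.1)

  x <- sample_rw(33, 2, precision = 10, seed = 33)
  expect_lt(abs(sum(x)), 1e-9)
  expect_lt(abs(sum(x * seq_len(33))), 1e-8)
  x1 <- sample_rw(33, 1, precision = 10, seed = 34)
  expect_lt(abs(sum(x1)), 1e-9)
})

test_that("a zero-variance truth surface is deterministic and flat", {
  g <- square_graph()
  sp <- truth_spec(mu = qlogis(0.05),
                   variances = c(alpha = 0, gamma = 0, theta = 0, phi = 0,
                                 delta = 0),
                   trend = 0, years = 2000:2010, graph = g, seed = 1)
  tr <- simulate_truth(sp)
  expect_equal(unname(tr$q5), matrix(50, 4, 11))
  expect_equal(unname(tr$eta), matrix(qlogis(0.05), 4, 11))
  expect_equal(tr$q5, 1000 * plogis(tr$eta))
})

test_that("constrained truth components sum to zero and dominance is preserved", {
  sp <- truth_spec(variances = c(alpha = 1e-4, gamma = 1e-6, theta = 1e-4,
                                 phi = 0.2, delta = 1e-4),
                   trend = 0, seed = 3)
  tr <- simulate_truth(sp)
  co <- tr$components
  expect_lt(abs(sum(co$gamma)), 1e-9)
  expect_lt(abs(sum(co$phi)), 1e-9)
  expect_lt(abs(sum(co$alpha)), 1e-9)
  # variance bookkeeping: with sigma_phi^2 dominant the phi component
  # dominates the empirical decomposition of eta
  vars <- c(alpha = var(co$alpha), gamma = var(co$gamma),
            theta = var(co$theta), phi = var(co$phi),
            delta = var(as.vector(co$delta)))
  expect_equal(names(which.max(vars)), "phi")
  expect_gt(vars["phi"] / sum(vars), 0.5)
})

test_that("hazard inversion reproduces q5 exactly", {
  expect_equal(unname(hazards_from_q5(0)), rep(0, 6))
  # flat shape: constant monthly hazard h solves q5 = 1 - (1-h)^60
  q5 <- 1 - 0.998^60
  h <- hazards_from_q5(q5, shape = rep(1, 6))
  expect_equal(unname(h), rep(0.002, 6), tolerance = 1e-10)
  # round trip at the default (age-skewed) shape
  for (p in c(0.005, 0.03, 0.12, 0.4)) {
    hh <- hazards_from_q5(p)
    expect_equal(u5mr_from_hazards(hh) / 1000, p, tolerance = 1e-10)
  }
  expect_error(hazards_from_q5(1), "\\[0, 1\\)")
  expect_error(hazards_from_q5(0.1, shape = c(-1, 1, 1, 1, 1, 1)), "positive")
})

test_that("birth histories obey censoring, determinism and the no-death limit", {
  g <- square_graph()
  des <- survey_design(clusters_per_stratum = 3, women_per_cluster = 5,
                       births_per_woman_mean = 2)
  # q5 ~ 0 everywhere -> no deaths
  sp0 <- truth_spec(mu = -30, variances = c(alpha = 0, gamma = 0, theta = 0,
                                            phi = 0, delta = 0),
                    trend = 0, years = 2000:2010, graph = g, seed = 2)
  rec0 <- simulate_birth_histories(simulate_truth(sp0), des, seed = 5)
  expect_true(all(is.na(rec0$death_age_months)))

  sp <- truth_spec(mu = qlogis(0.15), variances = c(alpha = 0, gamma = 0,
                                                    theta = 0, phi = 0,
                                                    delta = 0),
                   trend = 0, years = 2000:2010, graph = g, seed = 2)
  tr <- simulate_truth(sp)
  rec <- simulate_birth_histories(tr, des, seed = 6)
  # censoring contract: any observed death happens on or before the interview
  d <- rec$death_age_months
  expect_true(all(is.na(d) | rec$birth_month + d <= rec$interview_month))
  expect_true(all(d[!is.na(d)] %in% 0:59))
  # byte-identical reruns under the same seed
  rec2 <- simulate_birth_histories(tr, des, seed = 6)
  expect_identical(rec, rec2)
  expect_false(identical(rec,
                         simulate_birth_histories(tr, des, seed = 7)))
})

test_that("empirical cohort mortality matches the surface's q5", {
  g <- square_graph()
  sp <- truth_spec(mu = qlogis(0.08), variances = c(alpha = 0, gamma = 0,
                                                    theta = 0, phi = 0,
                                                    delta = 0),
                   trend = 0, years = 2000:2015, graph = g, seed = 4)
  tr <- simulate_truth(sp)
  des <- survey_design(clusters_per_stratum = 12, women_per_cluster = 25,
                       births_per_woman_mean = 3)
  rec <- simulate_birth_histories(tr, des, seed = 8)
  # children with full 60-month exposure form a closed cohort
  full <- rec$interview_month - rec$birth_month >= 60
  p_hat <- mean(!is.na(rec$death_age_months[full]))
  n <- sum(full)
  se <- sqrt(0.08 * 0.92 / n)
  expect_lt(abs(p_hat - 0.08), 3 * se)
})
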