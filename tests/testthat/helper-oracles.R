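# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (explicit loops, direct
# linear algebra, textbook recursions) so they share no code path with the
# package implementations they check.

# Brute-force synthetic-cohort life table for one region x year cell:
# explicit per-child, per-month enumeration of deaths and person-months by
# age band, then the life-table product.
oracle_cell_q5 <- function(records, region, year) {
  D <- E <- numeric(6)
  widths <- c(1, 11, 12, 12, 12, 12)
  for (r in seq_len(nrow(records))) {
    if (records$region[r] != region) next
    dth <- records$death_age_months[r]
    last <- min(if (is.na(dth)) 59 else dth,
                records$interview_month[r] - records$birth_month[r], 59)
    if (last < 0) next
    for (a in 0:last) {
      yr <- 1900 + (records$birth_month[r] + a) %/% 12
      if (yr != year) next
      b <- if (a == 0) 1 else if (a <= 11) 2 else if (a <= 23) 3 else
        if (a <= 35) 4 else if (a <= 47) 5 else 6
      E[b] <- E[b] + records$weight[r]
      if (!is.na(dth) && dth == a) D[b] <- D[b] + records$weight[r]
    }
  }
  if (any(E == 0)) return(NA_real_)
  h <- D / E
  1000 * (1 - prod((1 - h)^widths))
}

# Textbook Cox-de Boor recursion (evaluate away from knots to sidestep
# half-open interval conventions).
deboor_B <- function(i, k, t, x) {
  if (k == 1) return(as.numeric(x >= t[i] && x < t[i + 1]))
  d1 <- t[i + k - 1] - t[i]
  d2 <- t[i + k] - t[i + 1]
  a <- if (d1 > 0) (x - t[i]) / d1 * deboor_B(i, k - 1, t, x) else 0
  b <- if (d2 > 0) (t[i + k] - x) / d2 * deboor_B(i + 1, k - 1, t, x) else 0
  a + b
}

deboor_matrix <- function(knots, x, ord) {
  nb <- length(knots) - ord
  out <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) for (ii in seq_along(x))
    out[ii, j] <- deboor_B(j, ord, knots, x[ii])
  out
}

# Exact Gaussian posterior for a linear-Gaussian model y ~ N(X beta, 1/w),
# prior beta ~ N(0, P0^{-1}); returns mean/cov of the linear functionals
# C beta.
oracle_gaussian_posterior <- function(X, y, w, P0, C = diag(ncol(X))) {
  P <- t(X) %*% (X * w) + P0
  m <- solve(P, t(X) %*% (w * y))
  list(mean = drop(C %*% m), cov = C %*% solve(P) %*% t(C))
}

# Effective sample size from the initial positive autocorrelations, and the
# implied Monte-Carlo standard error of a posterior mean.
ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)[1]
  if (!is.na(neg)) ac <- ac[seq_len(max(0, neg - 1))]
  max(1, n / (1 + 2 * sum(ac)))
}

mcse_mean <- function(x) stats::sd(x) / sqrt(ess(x))

# Graph fixtures -------------------------------------------------------

path3_graph <- function()
  adjacency_graph(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))

square_graph <- function()
  adjacency_graph(c("N", "E", "S", "W"),
                  list(c("N", "E"), c("E", "S"), c("S", "W"), c("W", "N")))

# Minimal birth-record builder with sensible defaults.
make_records <- function(n, region = "A", cluster = "c1", weight = 1,
                         birth_month = month_index(1990, 1),
                         death_age = NA_integer_,
                         interview = month_index(1999, 12)) {
  data.frame(
    child_id = sprintf("%s_%s_k%03d", region, cluster, seq_len(n)),
    cluster_id = rep_len(cluster, n),
    stratum_id = paste0(rep_len(region, n), "_s"),
    region = rep_len(region, n),
    weight = rep_len(weight, n),
    birth_month = rep_len(birth_month, n),
    death_age_months = rep_len(death_age, n),
    interview_month = rep_len(interview, n),
    stringsAsFactors = FALSE
  )
}

# Gaussian-stage simulation straight from the space-time model: returns the
# observed-cell table plus the true eta matrix. Used for recovery and
# model-selection checks where the survey stage is irrelevant.
simulate_model_cells <- function(graph, years, mu = -2.5,
                                 var_alpha = 0.002, var_gamma = 1e-6,
                                 var_theta = 0.003, var_phi = 0.05,
                                 var_delta = 0.002, v_obs = 0.01,
                                 order = 2, seed = 1, gamma_fun = NULL) {
  set.seed(seed)
  n <- graph$n_regions
  Tt <- length(years)
  alpha <- rnorm(Tt, sd = sqrt(var_alpha)); alpha <- alpha - mean(alpha)
  gamma <- if (is.null(gamma_fun)) sample_rw(Tt, order, 1 / var_gamma)
  else gamma_fun(seq_len(Tt))
  theta <- rnorm(n, sd = sqrt(var_theta)); theta <- theta - mean(theta)
  phi <- sample_icar(graph, 1 / var_phi)
  delta <- matrix(rnorm(n * Tt, sd = sqrt(var_delta)), n, Tt)
  delta <- delta - rowMeans(delta)
  delta <- sweep(delta, 2, colMeans(delta))
  eta <- mu + outer(theta + phi, alpha + gamma, `+`) + delta
  y <- eta + rnorm(n * Tt, sd = sqrt(v_obs))
  cells <- data.frame(region = rep(graph$region_names, Tt),
                      year = rep(years, each = n),
                      logit_mean = as.vector(y),
                      logit_variance = v_obs)
  list(cells = cells, eta = eta, components = list(
    alpha = alpha, gamma = gamma, theta = theta, phi = phi, delta = delta))
}
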