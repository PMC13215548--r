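# Bayesian hierarchical space-time smoothing of logit-scale direct
# estimates. The observation stage is a Gaussian pseudo-likelihood with
# known design-based variances,
#   y_it ~ N(eta_it, v_it),
#   eta_it = mu + alpha_t + gamma_t + theta_i + phi_i + delta_it,
# with iid alpha/theta/delta, a random-walk prior (order 1 or 2) on gamma,
# an ICAR prior on phi, and Gamma(a, b) priors on the five precisions (b is
# a RATE: Gamma(0.5, 0.001) has mean 500). Every full conditional is
# conjugate, so the model is fitted by a plain Gibbs sampler with sum-to-zero
# identification enforced by recentring each sweep (the removed means are
# absorbed into parent terms, so eta -- and hence the likelihood -- is
# unchanged by recentring).

#' Random-walk structure matrix
#'
#' R = D' D where D is the order-th difference operator; rank T - order.
#' The order-2 matrix annihilates constant and linear vectors, which is why
#' an RW2 prior extrapolates linearly in the no-innovation limit.
#'
#' @param T_len number of time points (>= order + 1).
#' @param order 1 or 2.
#' @return a T x T matrix.
#' @export
build_rw_precision <- function(T_len, order) {
  if (!order %in% c(1, 2)) stop_ms("random-walk order must be 1 or 2")
  stopifnot(T_len >= order + 1)
  D <- diff(diag(T_len), differences = order)
  crossprod(D)
}

#' Sampler specification for the space-time model
#'
#' @param temporal_order 1 (Model I, RW1) or 2 (Model II, RW2) for the
#'   structured temporal effect.
#' @param hyper_a,hyper_b shape and rate of the Gamma priors on all five
#'   precisions (default Gamma(0.5, 0.001)).
#' @param n_iter,n_burn,thin MCMC controls; `n_iter > n_burn >= 0`.
#' @param seed integer seed; fits are deterministic given the seed.
#' @param mu_prior_var variance of the (near-flat) Normal prior on mu.
#' @param fix_tau named list pinning selected precisions instead of sampling
#'   them, e.g. `list(delta = 1e12)` effectively removes the interaction.
#'   Names among `alpha`, `gamma`, `theta`, `phi`, `delta`.
#' @return an object of class `mort_model_spec`.
#' @export
model_spec <- function(temporal_order = 2, hyper_a = 0.5, hyper_b = 0.001,
                       n_iter = 20000, n_burn = 5000, thin = 5, seed = 1L,
                       mu_prior_var = 1e6, fix_tau = list()) {
  if (!temporal_order %in% c(1, 2)) stop_ms("temporal_order must be 1 or 2")
  stopifnot(hyper_a > 0, hyper_b > 0, n_iter > n_burn, n_burn >= 0, thin >= 1,
            mu_prior_var > 0)
  bad <- setdiff(names(fix_tau), c("alpha", "gamma", "theta", "phi", "delta"))
  if (length(bad)) stop_ms("unknown fix_tau component(s): %s", paste(bad, collapse = ", "))
  structure(list(temporal_order = as.integer(temporal_order),
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 mu_prior_var = mu_prior_var, fix_tau = fix_tau),
            class = "mort_model_spec")
}

# Draw from N(P^{-1} b, P^{-1}) given precision matrix P.
rmvnorm_prec <- function(b, P) {
  U <- chol(P)
  mean <- backsolve(U, forwardsolve(t(U), b))
  drop(mean + backsolve(U, rnorm(length(b))))
}

#' Fit the space-time model by Gibbs sampling
#'
#' @param cells data.frame of observed cells with columns `region`, `year`,
#'   `logit_mean` (y) and `logit_variance` (v, treated as known). Missing
#'   region x year cells are allowed and are smoothed over.
#' @param graph a connected `mort_graph` whose regions index the spatial
#'   effects.
#' @param spec a `mort_model_spec`.
#' @param years full vector of years to model (default the range of the
#'   observed cells); years with no observation are interpolated.
#' @return an object of class `mort_fit` containing posterior draws of
#'   `mu`, `alpha`, `gamma`, `theta`, `phi`, `delta`, `eta` and the five
#'   precisions, plus the data and spec echoes.
#' @export
gibbs_fit <- function(cells, graph, spec, years = NULL) {
  stopifnot(inherits(graph, "mort_graph"), inherits(spec, "mort_model_spec"))
  need <- c("region", "year", "logit_mean", "logit_variance")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop_ms("cells missing column(s): %s", paste(miss, collapse = ", "))
  cells <- cells[!is.na(cells$logit_mean) & !is.na(cells$logit_variance), ]
  if (any(cells$logit_variance <= 0)) stop_ms("logit_variance must be positive")
  regions <- graph$region_names
  unknown <- setdiff(unique(cells$region), regions)
  if (length(unknown))
    stop_ms("cells reference region(s) absent from the graph: %s",
            paste(unknown, collapse = ", "))
  years <- as.integer(years %||% seq(min(cells$year), max(cells$year)))
  if (!all(cells$year %in% years)) stop_ms("cells reference years outside the model window")
  n <- length(regions); Tt <- length(years)
  if (Tt < spec$temporal_order + 1) stop_ms("too few years for the temporal prior")

  y <- v <- matrix(NA_real_, n, Tt, dimnames = list(regions, years))
  y[cbind(match(cells$region, regions), match(cells$year, years))] <- cells$logit_mean
  v[cbind(match(cells$region, regions), match(cells$year, years))] <- cells$logit_variance
  if (any(colSums(!is.na(y)) == 0))
    warning("some years have no observed cells; their effects are sampled from the prior conditional")
  if (any(rowSums(!is.na(y)) == 0))
    warning("some regions have no observed cells; their effects are sampled from the prior conditional")
  w <- ifelse(is.na(v), 0, 1 / v)
  y0 <- ifelse(is.na(y), 0, y)

  Q <- build_icar_precision(graph)
  R <- build_rw_precision(Tt, spec$temporal_order)
  # Moore-Penrose pseudo-inverse of Q: the marginal covariance of the
  # sum-to-zero ICAR field, used by the collapsed precision update
  eQ <- eigen(Q, symmetric = TRUE)
  posQ <- eQ$values > max(eQ$values) * 1e-10
  Qpinv <- eQ$vectors[, posQ] %*% (t(eQ$vectors[, posQ]) / eQ$values[posQ])
  wr <- rowSums(w); wc <- colSums(w); wtot <- sum(w)
  a0 <- spec$hyper_a; b0 <- spec$hyper_b
  fix <- spec$fix_tau
  rank_q <- list(alpha = Tt - 1, theta = n - 1,
                 gamma = Tt - spec$temporal_order, phi = n - 1,
                 delta = (n - 1) * (Tt - 1))

  set.seed(spec$seed)
  mu <- sum(w * y0) / max(wtot, 1e-12)
  alpha <- gamma <- numeric(Tt)
  theta <- phi <- numeric(n)
  delta <- matrix(0, n, Tt)
  tau <- c(alpha = 100, gamma = 100, theta = 100, phi = 100, delta = 100)
  for (nm in names(fix)) tau[nm] <- fix[[nm]]

  S <- (spec$n_iter - spec$n_burn) %/% spec$thin
  if (S < 1) stop_ms("no retained draws; check n_iter/n_burn/thin")
  out <- list(mu = numeric(S),
              alpha = matrix(0, S, Tt), gamma = matrix(0, S, Tt),
              theta = matrix(0, S, n), phi = matrix(0, S, n),
              delta = array(0, c(S, n, Tt)), eta = array(0, c(S, n, Tt)),
              tau = matrix(0, S, 5,
                           dimnames = list(NULL, c("alpha", "gamma", "theta",
                                                   "phi", "delta"))))
  s <- 0L
  for (it in seq_len(spec$n_iter)) {
    # mu | rest
    rest <- outer(theta + phi, alpha + gamma, `+`) + delta
    prec_mu <- wtot + 1 / spec$mu_prior_var
    mu <- rnorm(1, sum(w * (y0 - rest)) / prec_mu, sqrt(1 / prec_mu))

    # (alpha, gamma) | rest: joint Gaussian update. Only alpha_t + gamma_t
    # enters the likelihood, so single-site updates mix very poorly across
    # the iid/structured attribution; the joint draw samples the pair from
    # its exact 2T-dimensional conditional.
    resid_g <- y0 - mu - (theta + phi) - delta  # n-vector recycles down columns
    bc <- colSums(w * resid_g)
    Pt <- matrix(0, 2 * Tt, 2 * Tt)
    Pt[seq_len(Tt), seq_len(Tt)] <- diag(tau["alpha"] + wc, Tt)
    Pt[seq_len(Tt), Tt + seq_len(Tt)] <- diag(wc, Tt)
    Pt[Tt + seq_len(Tt), seq_len(Tt)] <- diag(wc, Tt)
    Pt[Tt + seq_len(Tt), Tt + seq_len(Tt)] <- tau["gamma"] * R + diag(wc, Tt)
    ag <- rmvnorm_prec(c(bc, bc), Pt)
    alpha <- ag[seq_len(Tt)]
    gamma <- ag[Tt + seq_len(Tt)]

    # (theta, phi) | rest: joint update for the same reason (only the sum
    # theta_i + phi_i is likelihood-identified).
    resid_s <- y0 - mu - rep(alpha + gamma, each = n) - delta
    br <- rowSums(w * resid_s)

    # Collapsed Metropolis update of (tau_theta, tau_phi) with the spatial
    # effects integrated out. The conditional tau | effects is a near-point
    # mass that freezes the iid/ICAR attribution; marginalizing the effects
    # lets the chain move between attribution modes.
    upd_s <- c(theta = is.null(fix$theta), phi = is.null(fix$phi))
    if (any(upd_s)) {
      obs_i <- wr > 0
      m_i <- br[obs_i] / wr[obs_i]
      base_var <- 1 / wr[obs_i]
      In <- diag(sum(obs_i))
      marg_sp <- function(lth, lph) {
        V <- diag(base_var, sum(obs_i)) + exp(-lth) * In +
          exp(-lph) * Qpinv[obs_i, obs_i]
        ch <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(ch)) return(-Inf)
        lp <- -sum(log(diag(ch))) - 0.5 * sum(forwardsolve(t(ch), m_i)^2)
        if (upd_s["theta"]) lp <- lp + a0 * lth - b0 * exp(lth)
        if (upd_s["phi"]) lp <- lp + a0 * lph - b0 * exp(lph)
        lp
      }
      cur <- log(tau[c("theta", "phi")])
      lp_cur <- marg_sp(cur[1], cur[2])
      for (k in 1:2) {
        prop <- cur + 0.6 * rnorm(2) * upd_s
        lp_prop <- marg_sp(prop[1], prop[2])
        if (log(runif(1)) < lp_prop - lp_cur) {
          cur <- prop; lp_cur <- lp_prop
        }
      }
      tau["theta"] <- exp(cur[1]); tau["phi"] <- exp(cur[2])
    }
    Ps <- matrix(0, 2 * n, 2 * n)
    Ps[seq_len(n), seq_len(n)] <- diag(tau["theta"] + wr, n)
    Ps[seq_len(n), n + seq_len(n)] <- diag(wr, n)
    Ps[n + seq_len(n), seq_len(n)] <- diag(wr, n)
    Ps[n + seq_len(n), n + seq_len(n)] <- tau["phi"] * Q + diag(wr, n)
    tp <- rmvnorm_prec(c(br, br), Ps)
    theta <- tp[seq_len(n)]
    phi <- tp[n + seq_len(n)]

    # delta_it | rest (iid cells; unobserved cells draw from the prior)
    resid_d <- y0 - mu - (outer(theta + phi, alpha + gamma, `+`))
    pr <- tau["delta"] + w
    delta <- matrix(rnorm(n * Tt, (w * resid_d) / pr, sqrt(1 / pr)), n, Tt)

    # identification sweep: recentre, pushing removed means up the hierarchy
    # so eta is unchanged
    dm_r <- rowMeans(delta); delta <- delta - dm_r; theta <- theta + dm_r
    dm_c <- colMeans(delta); delta <- sweep(delta, 2, dm_c); alpha <- alpha + dm_c
    m <- mean(alpha); alpha <- alpha - m; mu <- mu + m
    m <- mean(gamma); gamma <- gamma - m; mu <- mu + m
    m <- mean(theta); theta <- theta - m; mu <- mu + m
    m <- mean(phi);   phi <- phi - m;     mu <- mu + m

    # precision updates (Gamma full conditionals, rate parametrization)
    if (is.null(fix$alpha))
      tau["alpha"] <- rgamma(1, a0 + rank_q$alpha / 2, rate = b0 + sum(alpha^2) / 2)
    if (is.null(fix$gamma))
      tau["gamma"] <- rgamma(1, a0 + rank_q$gamma / 2,
                             rate = b0 + drop(crossprod(gamma, R %*% gamma)) / 2)
    # (tau_theta, tau_phi are updated by the collapsed Metropolis step above)
    if (is.null(fix$delta))
      tau["delta"] <- rgamma(1, a0 + rank_q$delta / 2, rate = b0 + sum(delta^2) / 2)

    if (it > spec$n_burn && (it - spec$n_burn) %% spec$thin == 0) {
      s <- s + 1L
      out$mu[s] <- mu
      out$alpha[s, ] <- alpha; out$gamma[s, ] <- gamma
      out$theta[s, ] <- theta; out$phi[s, ] <- phi
      out$delta[s, , ] <- delta
      out$eta[s, , ] <- mu + outer(theta + phi, alpha + gamma, `+`) + delta
      out$tau[s, ] <- tau
    }
  }
  structure(list(draws = out, spec = spec, graph = graph, years = years,
                 regions = regions, y = y, v = v, n_draws = S),
            class = "mort_fit")
}

#' @export
print.mort_fit <- function(x, ...) {
  cat(sprintf("mort_fit: %d regions x %d years, RW%d temporal prior, %d retained draws\n",
              length(x$regions), length(x$years), x$spec$temporal_order,
              x$n_draws))
  invisible(x)
}

#' Posterior summaries of effects and fitted rates
#'
#' Elementwise posterior medians and central credible intervals for every
#' effect block and for eta; eta is also back-transformed to U5MR per 1000.
#'
#' @param fit a `mort_fit` with at least 100 retained draws.
#' @param level credible level (default 0.95).
#' @return data.frame with columns `effect`, `region`, `year`, `median`,
#'   `lower`, `upper` (region/year NA where not applicable; effect `u5mr`
#'   rows are on the per-1000 scale).
#' @export
posterior_summaries <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mort_fit"))
  if (fit$n_draws < 100)
    warning("fewer than 100 retained draws; summaries will be noisy")
  pr <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qs <- function(x) quantile(x, pr, names = FALSE)
  rows <- list()
  add <- function(effect, region, year, draws_mat) {
    qm <- apply(draws_mat, 2, qs)
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, region = region, year = year,
      median = qm[2, ], lower = qm[1, ], upper = qm[3, ])
  }
  d <- fit$draws
  add("mu", NA, NA, matrix(d$mu, ncol = 1))
  add("alpha", NA, fit$years, d$alpha)
  add("gamma", NA, fit$years, d$gamma)
  add("theta", fit$regions, NA, d$theta)
  add("phi", fit$regions, NA, d$phi)
  nT <- expand.grid(region = fit$regions, year = fit$years,
                    stringsAsFactors = FALSE)
  eta_flat <- matrix(d$eta, nrow = fit$n_draws)
  add("delta", nT$region, nT$year, matrix(d$delta, nrow = fit$n_draws))
  add("eta", nT$region, nT$year, eta_flat)
  add("u5mr", nT$region, nT$year, 1000 * expit(eta_flat))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forecast future rates from a fitted space-time model
#'
#' Per retained draw, the structured temporal effect is propagated forward
#' through its random-walk recursion (order 2: gamma_(T+h) =
#' 2 gamma_(T+h-1) - gamma_(T+h-2) + innovation with variance 1/tau_gamma of
#' that draw). The forecast linear predictor is
#' eta_i,T+h = mu + gamma_(T+h) + theta_i + phi_i: the iid temporal effect
#' carries no autoregressive structure and the interaction no temporal
#' structure, so neither is projected forward, and the forecast reflects only
#' the smooth temporal component plus the regional levels.
#'
#' @param fit a `mort_fit`.
#' @param H forecast horizon in years (>= 0; 0 yields an empty table).
#' @param seed optional seed for the forecast innovations.
#' @param level credible level (default 0.95).
#' @return data.frame: `region`, `year`, `horizon`, `median`, `lower`,
#'   `upper` on the U5MR per-1000 scale.
#' @export
forecast <- function(fit, H, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "mort_fit"), H >= 0)
  if (H == 0)
    return(data.frame(region = character(), year = integer(),
                      horizon = integer(), median = numeric(),
                      lower = numeric(), upper = numeric()))
  if (!is.null(seed)) set.seed(seed)
  d <- fit$draws
  S <- fit$n_draws
  n <- length(fit$regions); Tt <- length(fit$years)
  order <- fit$spec$temporal_order
  gfut <- matrix(0, S, H)
  sd_inn <- 1 / sqrt(d$tau[, "gamma"])
  g1 <- d$gamma[, Tt]
  g0 <- if (Tt >= 2) d$gamma[, Tt - 1] else rep(0, S)
  for (h in seq_len(H)) {
    inn <- rnorm(S, 0, sd_inn)
    gnew <- if (order == 2) 2 * g1 - g0 + inn else g1 + inn
    gfut[, h] <- gnew
    g0 <- g1; g1 <- gnew
  }
  pr <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  rows <- vector("list", n * H)
  k <- 0
  for (i in seq_len(n)) for (h in seq_len(H)) {
    eta_f <- d$mu + gfut[, h] + d$theta[, i] + d$phi[, i]
    q <- quantile(1000 * expit(eta_f), pr, names = FALSE)
    k <- k + 1
    rows[[k]] <- data.frame(region = fit$regions[i],
                            year = max(fit$years) + h, horizon = h,
                            median = q[2], lower = q[1], upper = q[3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
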