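# Model assessment: DIC, conditional predictive ordinates (CPO/LCPO),
# variance-component decomposition, and the RW1-vs-RW2 comparison report.

# S x n_obs matrix of per-draw log likelihood contributions, plus the
# observed y/v vectors, for the cells with data.
loglik_draws <- function(fit) {
  obs <- which(!is.na(fit$y))
  yv <- fit$y[obs]; vv <- fit$v[obs]
  eta <- matrix(fit$draws$eta, nrow = fit$n_draws)[, obs, drop = FALSE]
  ll <- dnorm(rep(yv, each = fit$n_draws), eta,
              rep(sqrt(vv), each = fit$n_draws), log = TRUE)
  list(ll = matrix(ll, nrow = fit$n_draws), obs = obs, y = yv, v = vv,
       eta = eta)
}

#' Deviance information criterion
#'
#' Deviance is D(eta) = -2 sum log N(y_it | eta_it, v_it) over observed
#' cells. DIC = mean deviance + pD with the effective number of parameters
#' pD = mean deviance - deviance at the posterior mean of eta
#' (Spiegelhalter's plug-in form; `pd_variant = "half_var"` gives the
#' alternative half-variance-of-deviance estimate).
#'
#' @param fit a `mort_fit`.
#' @param pd_variant `"plugin"` (default) or `"half_var"`.
#' @return list with `DIC`, `pD`, `mean_deviance`.
#' @export
dic <- function(fit, pd_variant = c("plugin", "half_var")) {
  pd_variant <- match.arg(pd_variant)
  if (fit$n_draws < 100) warning("fewer than 100 retained draws; DIC will be noisy")
  ld <- loglik_draws(fit)
  dev <- -2 * rowSums(ld$ll)
  dbar <- mean(dev)
  eta_bar <- colMeans(ld$eta)
  dhat <- -2 * sum(dnorm(ld$y, eta_bar, sqrt(ld$v), log = TRUE))
  pd <- if (pd_variant == "plugin") dbar - dhat else var(dev) / 2
  if (pd < 0)
    warning("negative pD: a mixing diagnostic; the posterior mean is a poor plug-in")
  list(DIC = dbar + pd, pD = pd, mean_deviance = dbar)
}

#' Conditional predictive ordinates
#'
#' CPO_it is the leave-one-out predictive density of each observation,
#' estimated from posterior draws by the harmonic mean of per-draw
#' likelihoods: CPO_it = \[S^-1 sum_s 1/f(y_it | eta_it^(s), v_it)\]^-1,
#' computed through log-sum-exp to avoid underflow. LCPO is the sum of log
#' CPO over cells (higher = better predictive fit).
#'
#' @param fit a `mort_fit`.
#' @return list with `CPO` (vector over observed cells, named region.year),
#'   `LCPO`, and `flagged` (indices with non-finite terms).
#' @export
cpo_lcpo <- function(fit) {
  ld <- loglik_draws(fit)
  S <- nrow(ld$ll)
  log_cpo <- vapply(seq_along(ld$obs), function(j) {
    log(S) - logsumexp(-ld$ll[, j])
  }, numeric(1))
  idx <- arrayInd(ld$obs, dim(fit$y))
  names(log_cpo) <- paste(fit$regions[idx[, 1]], fit$years[idx[, 2]], sep = ".")
  flagged <- which(!is.finite(log_cpo))
  list(CPO = exp(log_cpo), LCPO = sum(log_cpo[is.finite(log_cpo)]),
       flagged = flagged)
}

#' Variance decomposition of the fitted random effects
#'
#' For each component the empirical variance of its posterior-median
#' elements (over years for the temporal effects, over regions for the
#' spatial ones, over all cells for the interaction), expressed as a
#' percentage of their total. The ICAR and random-walk priors define
#' variances only conditionally, so the empirical variance of the
#' identified, constrained effects is the well-defined summary.
#'
#' @param fit a `mort_fit`.
#' @return data.frame with `component`, `interpretation`, `variance`,
#'   `percentage` (percentages sum to 100).
#' @export
variance_decomposition <- function(fit) {
  d <- fit$draws
  med <- function(m) apply(m, 2, median)
  vars <- c(
    theta = var(med(d$theta)),
    phi = var(med(d$phi)),
    gamma = var(med(d$gamma)),
    alpha = var(med(d$alpha)),
    delta = var(as.vector(med(matrix(d$delta, nrow = fit$n_draws)))))
  if (sum(vars) <= 0)
    stop_ms("all variance components are degenerate; nothing to decompose")
  interp <- c(theta = "Space unstructured (independent space)",
              phi = "Space structured (ICAR space)",
              gamma = sprintf("Time structured (RW%d time)", fit$spec$temporal_order),
              alpha = "Time unstructured (independent time)",
              delta = "Space-time interaction (independent)")
  data.frame(component = names(vars),
             interpretation = unname(interp[names(vars)]),
             variance = unname(vars),
             percentage = unname(100 * vars / sum(vars)))
}

#' Compare two fitted space-time models
#'
#' Computes DIC and LCPO for both fits (which must be fitted to identical
#' observed cells) and selects the model with the lower DIC, flagging ties
#' and any disagreement between the DIC and LCPO orderings.
#'
#' @param fit_a,fit_b `mort_fit` objects, e.g. the RW1 and RW2 variants.
#' @param labels display labels for the two models.
#' @return an object of class `mort_assessment`: per-model criteria, the
#'   selected label, and flags.
#' @export
compare_models <- function(fit_a, fit_b, labels = c("Model I (RW1)",
                                                    "Model II (RW2)")) {
  same_data <- isTRUE(all.equal(fit_a$y, fit_b$y)) &&
    isTRUE(all.equal(fit_a$v, fit_b$v))
  if (!same_data)
    stop_ms("models were fitted to different data; comparison undefined")
  crit <- function(f) {
    dd <- dic(f); cc <- cpo_lcpo(f)
    list(DIC = dd$DIC, pD = dd$pD, mean_deviance = dd$mean_deviance,
         LCPO = cc$LCPO, CPO = cc$CPO)
  }
  ca <- crit(fit_a); cb <- crit(fit_b)
  tie <- isTRUE(all.equal(ca$DIC, cb$DIC))
  selected <- if (tie || ca$DIC <= cb$DIC) labels[1] else labels[2]
  disagreement <- !tie && ((ca$DIC < cb$DIC) != (ca$LCPO > cb$LCPO))
  structure(list(models = setNames(list(ca, cb), labels),
                 selected = selected, tie = tie,
                 dic_lcpo_disagree = disagreement,
                 rule = "lower DIC preferred; LCPO reported (higher = better)"),
            class = "mort_assessment")
}

#' @export
print.mort_assessment <- function(x, ...) {
  cat("Model comparison (rule:", x$rule, ")\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-16s DIC = %8.2f  (pD = %6.2f)   LCPO = %8.2f\n",
                nm, m$DIC, m$pD, m$LCPO))
  }
  cat("  selected:", x$selected, if (x$tie) "(tie; first retained)" else "", "\n")
  if (x$dic_lcpo_disagree)
    cat("  note: DIC and LCPO orderings disagree\n")
  invisible(x)
}
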