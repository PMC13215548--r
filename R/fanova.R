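# One-way functional ANOVA on mortality curves: pointwise least squares of
# curve values on group indicators with the weighted sum-to-zero constraint,
# the pointwise F statistic, and permutation-based pointwise and global
# (max-statistic) inference.

# Coerce inputs to a values matrix (curves x grid points).
curve_values <- function(curves, grid) {
  if (is.matrix(curves)) {
    if (ncol(curves) != length(grid))
      stop_ms("values matrix must have one column per grid point")
    return(curves)
  }
  stopifnot(is.list(curves), length(curves) >= 2)
  b0 <- curves[[1]]$basis
  if (!all(vapply(curves, function(cu) same_basis(cu$basis, b0), logical(1))))
    stop_ms("curves must share a common basis")
  t(vapply(curves, predict, numeric(length(grid)), newx = grid))
}

default_grid <- function(curves) {
  if (is.matrix(curves)) {
    if (is.null(colnames(curves))) seq_len(ncol(curves))
    else as.numeric(colnames(curves))
  } else {
    b0 <- curves[[1]]$basis
    seq(b0$domain[1], b0$domain[2])
  }
}

#' Fit a one-way functional ANOVA
#'
#' At each grid point t the curve values are decomposed as
#' y_gj(t) = mu(t) + beta_g(t) + e_gj(t) by least squares under the weighted
#' sum-to-zero constraint sum_g n_g beta_g(t) = 0: mu is the grand mean
#' curve and beta_g the group deviations. Requires more curves than groups
#' (positive residual degrees of freedom) -- one curve per group leaves the
#' residual variance, and hence the F statistic, undefined.
#'
#' @param curves list of `mort_curve` objects on a shared basis, or a
#'   numeric matrix of curve values (rows = curves, columns = grid points).
#' @param labels group label for each curve.
#' @param grid evaluation grid (default one point per year of the domain).
#' @return an object of class `mort_fanova`: `grid`, `values`, `labels`,
#'   `mu` (grand mean values), `beta` (group x grid effect matrix),
#'   `residuals`, `n_per_group`.
#' @export
fit_fanova <- function(curves, labels, grid = NULL) {
  grid <- grid %||% default_grid(curves)
  V <- curve_values(curves, grid)
  labels <- as.character(labels)
  if (length(labels) != nrow(V))
    stop_ms("need one label per curve")
  G <- length(unique(labels))
  N <- nrow(V)
  if (N <= G)
    stop_ms(paste("functional ANOVA needs more curves than groups (N > G):",
                  "with one curve per group there are no residual degrees of",
                  "freedom; supply replicate curves (e.g. stratum-level",
                  "estimates within each region)"))
  mu <- colMeans(V)
  # rowsum and table both order groups by sorted label
  ng <- as.vector(table(labels))
  beta <- sweep(rowsum(V, labels) / ng, 2, mu)
  fitted <- matrix(mu, N, length(grid), byrow = TRUE) +
    beta[match(labels, sort(unique(labels))), , drop = FALSE]
  structure(list(grid = grid, values = V, labels = labels,
                 groups = sort(unique(labels)), n_per_group = ng,
                 mu = mu, beta = beta, residuals = V - fitted),
            class = "mort_fanova")
}

#' Pointwise F statistic of a fitted functional ANOVA
#'
#' F(t) = \[SSB(t)/(G-1)\] / \[SSW(t)/(N-G)\] at each grid point, the same
#' statistic scalar one-way ANOVA computes from the curve values at t.
#' Points with zero residual sum of squares are reported as `Inf` and
#' flagged in the `degenerate` attribute.
#'
#' @param fit a `mort_fanova`.
#' @return numeric vector of F values on the fit's grid, with attribute
#'   `degenerate` marking zero-residual points.
#' @export
pointwise_F <- function(fit) {
  stopifnot(inherits(fit, "mort_fanova"))
  G <- length(fit$groups)
  N <- nrow(fit$values)
  ssb <- colSums(fit$n_per_group * fit$beta^2)
  ssw <- colSums(fit$residuals^2)
  tol <- 1e-12 * pmax(colSums(fit$values^2), 1)  # rounding-level SS are zero
  f <- (ssb / (G - 1)) / (ssw / (N - G))
  f[ssw <= tol & ssb > tol] <- Inf
  f[ssw <= tol & ssb <= tol] <- 0
  attr(f, "degenerate") <- which(ssw <= tol)
  f
}

# F(t) for an arbitrary label assignment, from precomputed pieces.
f_stat_values <- function(V, labels, ng, tot_ss, grand) {
  G <- length(ng)
  N <- nrow(V)
  M <- rowsum(V, labels) / ng
  ssb <- colSums(ng * M^2) - N * grand^2
  ssw <- pmax(tot_ss - ssb, 0)
  tol <- 1e-12 * pmax(colSums(V^2), 1)
  f <- (ssb / (G - 1)) / (ssw / (N - G))
  f[ssw <= tol] <- 0
  f
}

#' Permutation F test for group differences between curves
#'
#' Recomputes the pointwise F statistic under `n_perm` random permutations
#' of the group labels. Pointwise critical values are the per-point
#' (1-level) empirical quantiles of the permuted F(t); the global
#' (max-statistic) critical value is the same quantile of max_t F(t), which
#' controls the familywise error of the pointwise comparisons. The global
#' p-value uses the add-one correction
#' p = (1 + #\{perm max-F >= observed max-F\}) / (n_perm + 1).
#'
#' @inheritParams fit_fanova
#' @param n_perm number of permutations (>= 100; percentile estimates are
#'   unstable below that).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param level significance level for the critical values (default 0.05).
#' @return an object of class `mort_fanova_test`: `F_observed`,
#'   `pointwise_crit`, `max_crit`, `p_global`, `n_perm`, `seed`, `level`,
#'   `grid`, plus the underlying `fit`.
#' @export
permutation_test <- function(curves, labels, n_perm = 1000, seed = 1L,
                             level = 0.05, grid = NULL) {
  if (n_perm < 100)
    stop_ms("n_perm must be at least 100 for stable critical values")
  fit <- fit_fanova(curves, labels, grid = grid)
  V <- fit$values
  labels <- fit$labels
  ng <- fit$n_per_group
  grand <- fit$mu
  tot_ss <- colSums(sweep(V, 2, grand)^2)
  f_obs <- as.numeric(pointwise_F(fit))
  set.seed(seed)
  perm_F <- matrix(0, n_perm, length(fit$grid))
  for (p in seq_len(n_perm)) {
    perm_F[p, ] <- f_stat_values(V, sample(labels), ng, tot_ss, grand)
  }
  pointwise_crit <- apply(perm_F, 2, quantile, probs = 1 - level, names = FALSE)
  max_perm <- apply(perm_F, 1, max)
  max_crit <- quantile(max_perm, probs = 1 - level, names = FALSE)
  p_global <- (1 + sum(max_perm >= max(f_obs))) / (n_perm + 1)
  structure(list(F_observed = f_obs, pointwise_crit = pointwise_crit,
                 max_crit = max_crit, p_global = p_global,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 level = level, grid = fit$grid, fit = fit),
            class = "mort_fanova_test")
}

#' @export
print.mort_fanova_test <- function(x, ...) {
  cat(sprintf(
    "Permutation functional ANOVA: %d permutations, level %.2f\n",
    x$n_perm, x$level))
  cat(sprintf("  max observed F = %.3f, global critical value = %.3f\n",
              max(x$F_observed), x$max_crit))
  cat(sprintf("  global p-value = %.4f\n", x$p_global))
  n_sig <- sum(x$F_observed > x$pointwise_crit)
  cat(sprintf("  grid points above the pointwise critical value: %d of %d\n",
              n_sig, length(x$grid)))
  invisible(x)
}
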