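# Penalized B-spline representation of annual mortality series. Curves are
# stored as coefficients on a shared basis so cross-sectional statistics
# (means, ANOVA effects) are exact linear operations on coefficients.

#' Build a B-spline basis system
#'
#' Equally spaced interior knots strictly inside the domain, boundary knots
#' replicated to full multiplicity; the number of basis functions is
#' `n_interior_knots + order` (order 4 = cubic).
#'
#' @param domain length-2 numeric `[min, max]`, e.g. `c(1990, 2022)`.
#' @param n_interior_knots number of interior knots (>= 0).
#' @param order spline order (polynomial degree + 1), >= 2.
#' @param penalty_order derivative order of the roughness penalty (default 2,
#'   integrated squared second derivative).
#' @return an object of class `mort_basis`.
#' @export
build_basis <- function(domain, n_interior_knots = 10, order = 4,
                        penalty_order = 2) {
  stopifnot(length(domain) == 2, domain[2] > domain[1],
            order >= 2, n_interior_knots >= 0, penalty_order >= 1,
            penalty_order < order)
  interior <- if (n_interior_knots > 0)
    seq(domain[1], domain[2],
        length.out = n_interior_knots + 2)[-c(1, n_interior_knots + 2)]
  else numeric(0)
  knots <- c(rep(domain[1], order), interior, rep(domain[2], order))
  structure(list(domain = domain, order = order, interior_knots = interior,
                 knots = knots, nbasis = n_interior_knots + order,
                 penalty_order = penalty_order),
            class = "mort_basis")
}

#' Evaluate the basis (or a derivative) at a set of points
#' @param basis a `mort_basis`.
#' @param x evaluation points within the domain.
#' @param deriv derivative order (0 = function values).
#' @return matrix, `length(x)` rows by `nbasis` columns.
#' @export
eval_basis <- function(basis, x, deriv = 0) {
  stopifnot(inherits(basis, "mort_basis"))
  if (any(x < basis$domain[1] - 1e-9 | x > basis$domain[2] + 1e-9))
    stop_ms("evaluation points outside the basis domain")
  x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        derivs = rep(deriv, length(x)))
}

# Gram matrix of the penalty-order derivatives, integrated over the domain.
# The integrand is piecewise polynomial, so per-interval Gauss-Legendre with
# `order` nodes is exact.
penalty_matrix <- function(basis) {
  br <- sort(unique(basis$knots))
  gl <- gauss_legendre(basis$order)
  P <- matrix(0, basis$nbasis, basis$nbasis)
  for (j in seq_len(length(br) - 1)) {
    a <- br[j]; b <- br[j + 1]
    xs <- (b - a) / 2 * gl$nodes + (a + b) / 2
    ws <- (b - a) / 2 * gl$weights
    B2 <- eval_basis(basis, xs, deriv = basis$penalty_order)
    P <- P + t(B2 * ws) %*% B2
  }
  P
}

same_basis <- function(a, b) {
  isTRUE(all.equal(a$knots, b$knots)) && a$order == b$order
}

#' Penalized smoothing of an annual series onto a B-spline basis
#'
#' Penalized least squares with an integrated-squared-derivative roughness
#' penalty: minimizes ||y - B c||^2 + lambda c' P c. With `lambda = "gcv"`
#' the penalty weight minimizing generalized cross-validation,
#' GCV(lambda) = n RSS / (n - tr A)^2, is selected over a log-spaced grid.
#'
#' @param series the observations: a data.frame with columns `year` and
#'   `value`, or a numeric vector named by year.
#' @param basis a `mort_basis`.
#' @param lambda nonnegative penalty weight, or `"gcv"`.
#' @param label optional curve label.
#' @return an object of class `mort_curve`: `basis`, `coefficients`,
#'   `lambda`, `label`, plus the fit's `gcv` and effective df.
#' @export
smooth_curve <- function(series, basis, lambda = "gcv", label = NULL) {
  if (is.data.frame(series)) {
    x <- series$year; y <- series$value
  } else {
    x <- as.numeric(names(series)); y <- as.numeric(series)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_ms("non-finite values in the series to smooth")
  n <- length(y)
  if (identical(lambda, 0) && n < basis$nbasis)
    stop_ms("unpenalized fit needs at least %d observations", basis$nbasis)
  if (n < 3) stop_ms("need at least 3 observations")
  B <- eval_basis(basis, x)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  P <- penalty_matrix(basis)
  ridge <- diag(1e-10 * max(diag(BtB)), basis$nbasis)
  fit_at <- function(lam) {
    # tiny ridge (relative to B'B) keeps rank-deficient unpenalized fits
    # solvable without disturbing the penalty null space at large lambda
    M <- BtB + lam * P + ridge
    U <- chol(M)  # Cholesky solve: M is PD but can be very ill-conditioned
    Minv <- chol2inv(U)
    co <- Minv %*% Bty
    yhat <- drop(B %*% co)
    edf <- sum(diag(Minv %*% BtB))
    rss <- sum((y - yhat)^2)
    gcv <- n * rss / (n - min(edf, n - 1e-8))^2
    list(coefficients = drop(co), edf = edf, rss = rss, gcv = gcv, lambda = lam)
  }
  if (identical(lambda, "gcv")) {
    grid <- 10^seq(-6, 6, by = 0.25)
    fits <- lapply(grid, fit_at)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "gcv"))]]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    best <- fit_at(lambda)
  }
  structure(c(best, list(basis = basis, label = label)),
            class = "mort_curve")
}

#' Evaluate a fitted curve
#' @param object a `mort_curve`.
#' @param newx evaluation points (default: one point per integer year).
#' @param ... unused.
#' @return numeric vector of curve values.
#' @export
predict.mort_curve <- function(object, newx = NULL, ...) {
  newx <- newx %||% seq(object$basis$domain[1], object$basis$domain[2])
  drop(eval_basis(object$basis, newx) %*% object$coefficients)
}

#' @export
print.mort_curve <- function(x, ...) {
  cat(sprintf("mort_curve '%s': %d basis fns, lambda = %.3g, edf = %.2f\n",
              x$label %||% "", x$basis$nbasis, x$lambda, x$edf))
  invisible(x)
}

#' Cross-sectional mean curve with pointwise confidence band
#'
#' Pointwise mean over curves evaluated on a common grid, with the normal
#' interval mean +/- z * sd / sqrt(n) at each grid point.
#'
#' @param curves list of `mort_curve` objects on a common basis.
#' @param level confidence level (default 0.95).
#' @param grid evaluation grid (default one point per year).
#' @return data.frame with `grid`, `mean`, `lower`, `upper`, `sd`, `n`.
#' @export
mean_curve_ci <- function(curves, level = 0.95, grid = NULL) {
  stopifnot(length(curves) >= 2)
  b0 <- curves[[1]]$basis
  if (!all(vapply(curves, function(cu) same_basis(cu$basis, b0), logical(1))))
    stop_ms("curves must share a common basis")
  grid <- grid %||% seq(b0$domain[1], b0$domain[2])
  V <- matrix(vapply(curves, predict, numeric(length(grid)), newx = grid),
              nrow = length(grid))
  m <- rowMeans(V)
  s <- apply(V, 1, sd)
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * s / sqrt(length(curves))
  data.frame(grid = grid, mean = m, lower = m - half, upper = m + half,
             sd = s, n = length(curves))
}
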