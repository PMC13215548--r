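#' @importFrom stats plogis qlogis rnorm runif rpois rgamma quantile median
#'   qnorm dnorm uniroot var sd setNames aggregate lm resid
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logit and inverse-logit
#'
#' Thin wrappers over [stats::qlogis()] / [stats::plogis()] used throughout:
#' direct estimates are carried on the logit scale, where the smoothing model
#' is linear-Gaussian.
#'
#' @param p probability in (0, 1).
#' @param x real number.
#' @return `logit()` returns log(p/(1-p)); `expit()` its inverse.
#' @export
logit <- function(p) qlogis(p)

#' @rdname logit
#' @export
expit <- function(x) plogis(x)

#' Month index from calendar year and month
#'
#' Months are integer counts from January 1900 (the century-month convention
#' of demographic surveys), 0-based: `month_index(1900, 1) == 0`.
#'
#' @param year calendar year.
#' @param month month of year, 1-12.
#' @return integer month index.
#' @export
month_index <- function(year, month = 1) {
  stopifnot(month >= 1, month <= 12)
  as.integer((year - 1900L) * 12L + (month - 1L))
}

#' @rdname month_index
#' @param m integer month index.
#' @export
month_year <- function(m) as.integer(1900L + m %/% 12L)

# Deterministic per-stage seed derived from a global seed and a stage tag.
# Keeps every stage independently reproducible without seed collisions.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigen method.
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

stop_ms <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
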