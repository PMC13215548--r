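# Ground-truth surface simulation: the generator draws each random-effect
# component of the logit-scale space-time surface at a known variance, so
# downstream estimation and smoothing can be tested against known truth.

#' Draw from an intrinsic CAR (ICAR) field
#'
#' Samples the improper Gaussian with structure matrix Q = D - W at the given
#' precision, constrained to sum to zero. The draw is built on the
#' eigenvectors of Q with nonzero eigenvalue (all orthogonal to the constant
#' vector on a connected graph), so the sum-to-zero constraint holds exactly
#' and the covariance equals the scaled Moore-Penrose pseudo-inverse of Q.
#'
#' @param graph a connected `mort_graph`.
#' @param precision scalar precision tau > 0.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return named numeric vector, one entry per region, summing to zero.
#' @export
sample_icar <- function(graph, precision, seed = NULL) {
  stopifnot(precision > 0)
  if (!is.null(seed)) set.seed(seed)
  Q <- build_icar_precision(graph)  # errors if disconnected
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  z <- rnorm(sum(pos)) / sqrt(precision * e$values[pos])
  x <- drop(e$vectors[, pos, drop = FALSE] %*% z)
  setNames(x - mean(x), graph$region_names)
}

#' Draw from a random-walk prior of order 1 or 2
#'
#' Cumulates Gaussian innovations with variance 1/precision (order-fold
#' cumulative sum), then projects the draw onto the identified subspace:
#' sum-to-zero for order 1; sum-to-zero and orthogonal-to-linear for order 2.
#' The projection removes exactly the null space of the difference penalty,
#' so the distribution of the order-th differences is unchanged.
#'
#' @param T_len number of time points (>= order + 1).
#' @param order 1 or 2.
#' @param precision innovation precision tau > 0.
#' @param seed optional integer seed.
#' @return numeric vector of length `T_len`.
#' @export
sample_rw <- function(T_len, order, precision, seed = NULL) {
  if (!order %in% c(1, 2)) stop_ms("random-walk order must be 1 or 2")
  stopifnot(T_len >= order + 1, precision > 0)
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(T_len - order, sd = 1 / sqrt(precision))
  if (order == 1) {
    x <- c(0, cumsum(e))
    x - mean(x)
  } else {
    x <- numeric(T_len)
    for (t in 3:T_len) x[t] <- 2 * x[t - 1] - x[t - 2] + e[t - 2]
    tt <- seq_len(T_len)
    unname(resid(lm(x ~ tt)))
  }
}

#' Specification of a ground-truth mortality surface
#'
#' Defines the logit-scale surface eta[i, t] = mu + trend*(t - tbar) +
#' alpha_t + gamma_t + theta_i + phi_i + delta_it from which synthetic
#' surveys are drawn: `alpha` iid time, `gamma` structured time (random walk),
#' `theta` iid space, `phi` ICAR space, `delta` iid space-time interaction.
#' Defaults emulate three decades of declining under-five mortality across
#' eight divisions: a grand mean near 60 per 1000, a secular logit-scale
#' decline of about 0.035 per year, and spatial variation dominated by the
#' structured (ICAR) component.
#'
#' @param mu logit-scale grand mean.
#' @param variances named nonnegative variances for components
#'   `alpha`, `gamma`, `theta`, `phi`, `delta`. For `gamma` this is the
#'   random-walk innovation variance; for `phi` the ICAR conditional scale
#'   1/tau.
#' @param trend logit-scale change per year, applied as an explicit linear
#'   term centred on the study mid-year (the structured random-walk component
#'   is kept orthogonal to linear trends, so the secular decline is its own
#'   bookkeeping entry).
#' @param temporal_order 1 or 2, the random-walk order for `gamma`.
#' @param years inclusive integer year range of the surface.
#' @param graph a connected `mort_graph`.
#' @param seed integer seed for [simulate_truth()].
#' @return an object of class `mort_truth_spec`.
#' @export
truth_spec <- function(mu = qlogis(0.06),
                       variances = c(alpha = 0.002, gamma = 4e-4,
                                     theta = 0.004, phi = 0.03, delta = 0.002),
                       trend = -0.035,
                       temporal_order = 2,
                       years = 1990:2022,
                       graph = load_adjacency(),
                       seed = 1L) {
  need <- c("alpha", "gamma", "theta", "phi", "delta")
  if (!all(need %in% names(variances)))
    stop_ms("variances must name all of: %s", paste(need, collapse = ", "))
  variances <- variances[need]
  if (any(variances < 0)) stop_ms("variances must be nonnegative")
  if (!temporal_order %in% c(1, 2)) stop_ms("temporal_order must be 1 or 2")
  years <- as.integer(years)
  if (length(years) < temporal_order + 1)
    stop_ms("need at least temporal_order + 1 years")
  stopifnot(inherits(graph, "mort_graph"))
  structure(list(mu = mu, variances = variances, trend = trend,
                 temporal_order = temporal_order, years = years,
                 graph = graph, seed = as.integer(seed)),
            class = "mort_truth_spec")
}

#' Simulate a ground-truth space-time mortality surface
#'
#' Draws every component of the surface at its specified variance and stores
#' the components alongside `eta` and `q5 = 1000 * expit(eta)` so recovery
#' tests can compare fitted effects with the generating ones.
#'
#' @param spec a `mort_truth_spec`.
#' @return an object of class `mort_truth`: `eta` and `q5` are region x year
#'   matrices; `components` holds the generating vectors/matrices.
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "mort_truth_spec"))
  set.seed(spec$seed)
  g <- spec$graph
  n <- g$n_regions
  Tt <- length(spec$years)
  v <- spec$variances
  alpha <- if (v[["alpha"]] > 0) rnorm(Tt, sd = sqrt(v[["alpha"]])) else numeric(Tt)
  alpha <- alpha - mean(alpha)
  gamma <- if (v[["gamma"]] > 0)
    sample_rw(Tt, spec$temporal_order, 1 / v[["gamma"]]) else numeric(Tt)
  theta <- if (v[["theta"]] > 0) rnorm(n, sd = sqrt(v[["theta"]])) else numeric(n)
  theta <- theta - mean(theta)
  phi <- if (v[["phi"]] > 0) sample_icar(g, 1 / v[["phi"]]) else
    setNames(numeric(n), g$region_names)
  delta <- if (v[["delta"]] > 0)
    matrix(rnorm(n * Tt, sd = sqrt(v[["delta"]])), n, Tt) else matrix(0, n, Tt)
  delta <- delta - rowMeans(delta)
  delta <- sweep(delta, 2, colMeans(delta))
  trend_t <- spec$trend * (spec$years - mean(spec$years))
  eta <- matrix(spec$mu, n, Tt,
                dimnames = list(g$region_names, spec$years)) +
    rep(trend_t + alpha + gamma, each = n) +
    (theta + phi) +
    delta
  structure(list(
    eta = eta,
    q5 = 1000 * expit(eta),
    years = spec$years,
    graph = g,
    spec = spec,
    components = list(mu = spec$mu, trend = trend_t, alpha = alpha,
                      gamma = gamma, theta = theta, phi = phi, delta = delta)
  ), class = "mort_truth")
}

# DHS-convention age bands (months): 0, 1-11, 12-23, 24-35, 36-47, 48-59.
band_widths <- function() c(1L, 11L, 12L, 12L, 12L, 12L)
band_starts <- function() c(0L, 1L, 12L, 24L, 36L, 48L)
band_of_age <- function(age_months) findInterval(age_months, band_starts())

#' Monthly age-band hazards consistent with a given five-year death probability
#'
#' Inverts the synthetic-cohort relation q5 = 1 - prod_a (1 - h_a)^{n_a}:
#' given a relative hazard shape over the six age bands, finds the scalar c
#' such that hazards h_a = c * shape_a reproduce `q5_prob` exactly. The
#' default shape concentrates risk in the first month and first year of life,
#' matching the age pattern of under-five deaths in high-mortality survey
#' settings.
#'
#' @param q5_prob probability of death before 60 months, in `[0, 1)`.
#' @param shape positive relative monthly hazards for bands 0, 1-11, 12-23,
#'   24-35, 36-47, 48-59 months.
#' @return numeric vector of six monthly hazards in `[0, 1)`.
#' @export
hazards_from_q5 <- function(q5_prob,
                            shape = c(15, 1.5, 0.35, 0.2, 0.15, 0.1)) {
  if (length(shape) != 6 || any(shape <= 0))
    stop_ms("shape must be six positive relative hazards")
  if (q5_prob < 0 || q5_prob >= 1)
    stop_ms("q5_prob must lie in [0, 1)")
  nb <- band_widths()
  if (q5_prob == 0) return(setNames(numeric(6), paste0("band", 1:6)))
  f <- function(cc) 1 - prod((1 - cc * shape)^nb) - q5_prob
  upper <- (1 - 1e-12) / max(shape)
  cc <- uniroot(f, lower = 0, upper = upper, tol = 1e-14)$root
  setNames(pmin(pmax(cc * shape, 0), 1 - 1e-12), paste0("band", 1:6))
}

#' Two-stage stratified survey design
#'
#' Describes a DHS-style sample: each region is split into an urban and a
#' rural stratum; a fixed number of clusters is drawn per stratum; a fixed
#' number of women is interviewed per cluster; each woman reports a full
#' birth history with a Poisson number of births. Sampling weights are
#' proportional to the stratum population share and constant within stratum,
#' normalized to mean 1 over children. Defaults approximate a national
#' survey of roughly 675 clusters and 65,000 child records over eight
#' regions.
#'
#' @param clusters_per_stratum clusters sampled in each region x urban/rural
#'   stratum.
#' @param women_per_cluster women interviewed per cluster.
#' @param births_per_woman_mean Poisson mean number of births per woman over
#'   the reporting window.
#' @param urban_share population share of the urban stratum in each region
#'   (rural gets the complement); drives relative weights.
#' @param interview_month month index of the interview, or `NULL` to use
#'   December of the surface's last year.
#' @param births_lead_years how many years before the first surface year
#'   births begin, so that early calendar years have exposure at all ages
#'   under five (a child aged four in the first study year must have been
#'   born earlier).
#' @return an object of class `mort_design`.
#' @export
survey_design <- function(clusters_per_stratum = 42,
                          women_per_cluster = 30,
                          births_per_woman_mean = 3.2,
                          urban_share = 0.3,
                          interview_month = NULL,
                          births_lead_years = 5) {
  stopifnot(clusters_per_stratum >= 1, women_per_cluster >= 1,
            births_per_woman_mean > 0, urban_share > 0, urban_share < 1,
            births_lead_years >= 0)
  structure(list(clusters_per_stratum = as.integer(clusters_per_stratum),
                 women_per_cluster = as.integer(women_per_cluster),
                 births_per_woman_mean = births_per_woman_mean,
                 urban_share = urban_share,
                 interview_month = interview_month,
                 births_lead_years = as.integer(births_lead_years)),
            class = "mort_design")
}

#' Simulate full birth histories under a survey design
#'
#' Women are assigned to clusters within region x urban/rural strata; births
#' are placed uniformly over calendar months of the reporting window; each
#' child's survival is simulated month by month under the monthly hazard of
#' the age band it currently occupies and the calendar year it currently
#' occupies (period hazards, matching the period estimand of the direct
#' estimator). Observation is right-censored at the interview month.
#'
#' @param surface a `mort_truth` surface.
#' @param design a `mort_design`.
#' @param seed integer seed.
#' @param shape relative age-band hazard shape passed to [hazards_from_q5()].
#' @return a data.frame of one row per child with columns `child_id`,
#'   `cluster_id`, `stratum_id`, `region`, `weight`, `birth_month`,
#'   `death_age_months` (NA if alive or censored) and `interview_month`.
#' @export
simulate_birth_histories <- function(surface, design, seed = 1L,
                                     shape = c(15, 1.5, 0.35, 0.2, 0.15, 0.1)) {
  stopifnot(inherits(surface, "mort_truth"), inherits(design, "mort_design"))
  set.seed(seed)
  years <- surface$years
  regions <- surface$graph$region_names
  interview <- design$interview_month %||% month_index(max(years), 12)
  start_month <- month_index(min(years) - design$births_lead_years, 1)
  if (interview < start_month)
    stop_ms("interview_month precedes the start of the reporting window")

  # per-(region, year) monthly hazards by band
  H <- array(0, dim = c(length(regions), length(years), 6),
             dimnames = list(regions, years, NULL))
  for (i in seq_along(regions)) for (t in seq_along(years))
    H[i, t, ] <- hazards_from_q5(surface$q5[i, t] / 1000, shape = shape)

  # roster of women -> births
  strata <- expand.grid(region = regions, stratum = c("urban", "rural"),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    reg <- strata$region[s]; st <- strata$stratum[s]
    n_wom <- design$clusters_per_stratum * design$women_per_cluster
    births <- rpois(n_wom, design$births_per_woman_mean)
    cl <- rep(seq_len(design$clusters_per_stratum),
              each = design$women_per_cluster)
    rows[[s]] <- data.frame(
      region = reg,
      stratum_id = paste(reg, st, sep = "_"),
      cluster_id = sprintf("%s_%s_c%03d", reg, st, rep(cl, births)),
      share = if (st == "urban") design$urban_share else 1 - design$urban_share,
      stringsAsFactors = FALSE
    )
  }
  kids <- do.call(rbind, rows)
  N <- nrow(kids)
  if (N == 0) stop_ms("design produced no births; increase births_per_woman_mean")
  kids$child_id <- sprintf("C%06d", seq_len(N))
  kids$birth_month <- start_month +
    floor(runif(N) * (interview - start_month + 1))
  kids$interview_month <- interview
  # weights: inverse sampling fraction is proportional to the stratum
  # population share (equal cluster counts per stratum); normalized to mean 1
  kids$weight <- kids$share / mean(kids$share)
  kids$share <- NULL

  # month-by-month survival under period hazards
  reg_idx <- match(kids$region, regions)
  death_age <- rep(NA_integer_, N)
  alive <- rep(TRUE, N)
  for (a in 0:59) {
    cal <- kids$birth_month + a
    at_risk <- alive & cal <= interview
    if (!any(at_risk)) break
    yr <- pmin(pmax(month_year(cal[at_risk]), min(years)), max(years))
    h <- H[cbind(reg_idx[at_risk], match(yr, years),
                 rep(band_of_age(a), sum(at_risk)))]
    dies <- runif(sum(at_risk)) < h
    idx <- which(at_risk)[dies]
    death_age[idx] <- a
    alive[idx] <- FALSE
  }
  kids$death_age_months <- death_age
  rownames(kids) <- NULL
  kids[, c("child_id", "cluster_id", "stratum_id", "region", "weight",
           "birth_month", "death_age_months", "interview_month")]
}

#' Write / read birth-history and truth CSV files
#'
#' The birth-history CSV has exactly the columns `child_id, cluster_id,
#' stratum_id, region, weight, birth_month, death_age_months,
#' interview_month`, with `death_age_months` empty for children alive at
#' interview. The truth CSV is long-format region x year with `eta` and `q5`.
#'
#' @param records birth-history data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_birth_histories <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_birth_histories
#' @param truth a `mort_truth`.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(
    region = rep(rownames(truth$eta), times = ncol(truth$eta)),
    year = rep(truth$years, each = nrow(truth$eta)),
    eta = as.vector(truth$eta),
    q5 = as.vector(truth$q5)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
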