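# Design-weighted direct estimation of region x year U5MR from birth
# histories: discrete monthly hazards within DHS age bands, combined by the
# synthetic-cohort life-table product, with delete-one-cluster jackknife
# variances on the logit scale.

#' @import data.table
NULL

validate_records <- function(records) {
  need <- c("child_id", "cluster_id", "stratum_id", "region", "weight",
            "birth_month", "death_age_months", "interview_month")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_ms("birth-history table is missing column(s): %s",
            paste(miss, collapse = ", "))
  if (any(records$weight <= 0, na.rm = TRUE))
    stop_ms("weights must be strictly positive")
  bad <- which(records$birth_month > records$interview_month)
  if (length(bad))
    stop_ms("row %d: birth_month after interview_month", bad[1])
  d <- records$death_age_months
  bad <- which(!is.na(d) &
                 records$birth_month + d > records$interview_month)
  if (length(bad))
    stop_ms("row %d: death occurs after the interview", bad[1])
  if (any(!is.na(d) & (d < 0 | d > 59)))
    stop_ms("death_age_months must lie in [0, 59]")
  invisible(records)
}

# Person-month exposure and death events per (group, cluster, year, band).
# Each child contributes one weighted person-month to the cell of every age
# month it begins alive and under observation (the death month included),
# and one weighted death event to the cell containing its death month.
exposure_table <- function(records, group_col = "region") {
  validate_records(records)
  if (!group_col %in% names(records)) stop_ms("unknown group column '%s'", group_col)
  n_m <- pmin(ifelse(is.na(records$death_age_months), Inf,
                     records$death_age_months),
              records$interview_month - records$birth_month, 59) + 1L
  idx <- rep(seq_len(nrow(records)), n_m)
  age <- sequence(n_m) - 1L
  dt <- data.table(
    group = records[[group_col]][idx],
    cluster_id = records$cluster_id[idx],
    year = month_year(records$birth_month[idx] + age),
    band = band_of_age(age),
    w = records$weight[idx],
    death = !is.na(records$death_age_months[idx]) &
      age == records$death_age_months[idx]
  )
  dt[, .(wdeaths = sum(w * death), wmonths = sum(w)),
     by = .(group, cluster_id, year, band)]
}

#' Weighted age-band exposure and hazards for one region x year cell
#'
#' Tabulates weighted deaths, weighted person-months at risk and the implied
#' monthly hazard for each of the six age bands (0, 1-11, 12-23, 24-35,
#' 36-47, 48-59 months) within one calendar-year cell. A band with no
#' exposure is flagged with a missing hazard, never zero.
#'
#' @param records validated birth-history table.
#' @param region region (or group) label.
#' @param year calendar year.
#' @param group_col column defining the spatial grouping (default `region`;
#'   use `stratum_id` for stratum-level curves).
#' @return data.frame with one row per band: `region`, `year`, `band`,
#'   `weighted_deaths`, `weighted_exposure_months`, `hazard`.
#' @export
band_exposure <- function(records, region, year, group_col = "region") {
  et <- exposure_table(records, group_col)
  .reg <- region; .yr <- year
  cell <- et[group == .reg & year == .yr,
             .(wdeaths = sum(wdeaths), wmonths = sum(wmonths)), by = band]
  out <- data.frame(region = region, year = year, band = 1:6,
                    weighted_deaths = 0, weighted_exposure_months = 0,
                    hazard = NA_real_)
  if (nrow(cell)) {
    out$weighted_deaths[cell$band] <- cell$wdeaths
    out$weighted_exposure_months[cell$band] <- cell$wmonths
  }
  pos <- out$weighted_exposure_months > 0
  out$hazard[pos] <- out$weighted_deaths[pos] / out$weighted_exposure_months[pos]
  out
}

#' Combine age-band hazards into U5MR
#'
#' Synthetic-cohort life-table combination: q5 = 1000 * (1 - prod_a
#' (1 - h_a)^(n_a)) with band widths n = (1, 11, 12, 12, 12, 12) months.
#'
#' @param band_hazards six monthly hazards in `[0, 1]`.
#' @return U5MR per 1000 live births.
#' @export
u5mr_from_hazards <- function(band_hazards) {
  if (length(band_hazards) != 6)
    stop_ms("expected six band hazards")
  if (any(!is.finite(band_hazards)) ||
      any(band_hazards < 0 | band_hazards > 1))
    stop_ms("band hazards must lie in [0, 1]")
  1000 * (1 - prod((1 - band_hazards)^band_widths()))
}

#' Logit transform with delta-method variance
#'
#' Carries a probability-scale estimate and variance to the logit scale:
#' `logit_variance = var_q5 / (p (1 - p))^2`. Boundary estimates (p of 0
#' or 1) either raise an error or, when a continuity correction is supplied,
#' are nudged inside the open interval first.
#'
#' @param q5_prob probability in `[0, 1]`.
#' @param var_q5 nonnegative probability-scale variance.
#' @param correction `NULL` (raise on boundary) or a small probability used
#'   to replace p = 0 (and 1 - p = 1 symmetrically).
#' @return list with `logit_mean` and `logit_variance`.
#' @export
logit_with_delta_variance <- function(q5_prob, var_q5, correction = NULL) {
  stopifnot(var_q5 >= 0)
  if (q5_prob <= 0 || q5_prob >= 1) {
    if (is.null(correction))
      stop_ms("q5 estimate on the boundary (p = %g) and no continuity correction configured",
              q5_prob)
    q5_prob <- min(max(q5_prob, correction), 1 - correction)
  }
  list(logit_mean = logit(q5_prob),
       logit_variance = var_q5 / (q5_prob * (1 - q5_prob))^2)
}

# q5 (probability scale) from per-band deaths D and exposure E.
# `fallback_h`: hazards substituted for bands with zero exposure (used by
# leave-one-out replicates); `corr_mass`: weighted death mass added to the
# first band when the cell has no deaths, keeping the logit finite.
q5_prob_from_de <- function(D, E, fallback_h = NULL, corr_mass = NULL) {
  h <- rep(NA_real_, 6)
  pos <- E > 0
  h[pos] <- D[pos] / E[pos]
  if (any(!pos)) {
    if (is.null(fallback_h)) return(NA_real_)
    h[!pos] <- fallback_h[!pos]
  }
  if (sum(D) == 0 && !is.null(corr_mass) && E[1] > 0)
    h[1] <- min(corr_mass / E[1], 1 - 1e-12)
  h <- pmin(pmax(h, 0), 1)
  1 - prod((1 - h)^band_widths())
}

jk_variance <- function(theta_loo, var_floor = 1e-6) {
  K <- length(theta_loo)
  v <- (K - 1) / K * sum((theta_loo - mean(theta_loo))^2)
  max(v, var_floor)
}

#' Delete-one-cluster jackknife variance of a cell's logit U5MR
#'
#' Recomputes the cell estimate leaving each contributing cluster out in
#' turn; the jackknife variance of the logit-scale estimates is floored at
#' `var_floor`. Bands emptied by a deletion fall back to the full-cell
#' hazard, and zero-death replicates receive the continuity correction.
#'
#' @inheritParams band_exposure
#' @param var_floor minimum reported variance.
#' @return list: `logit_variance`, `n_clusters`, `theta_loo`.
#' @export
jackknife_variance <- function(records, region, year, group_col = "region",
                               var_floor = 1e-6) {
  et <- exposure_table(records, group_col)
  corr <- continuity_mass(et)
  .reg <- region; .yr <- year
  cell <- et[group == .reg & year == .yr]
  if (!nrow(cell)) stop_ms("no exposure in cell %s x %s", region, year)
  res <- cell_jackknife(cell, corr, var_floor)
  if (is.null(res))
    stop_ms("only one cluster contributes to cell %s x %s; pool periods or regions before estimating a design-based variance",
            region, year)
  res
}

continuity_mass <- function(et) {
  dw <- et[wdeaths > 0, wdeaths]
  if (length(dw)) 0.5 * min(dw) else 0.5
}

# Jackknife over the clusters of one cell; `cell` holds that cell's
# (cluster, band) rows. Returns NULL if fewer than 2 clusters contribute.
cell_jackknife <- function(cell, corr_mass, var_floor) {
  clusters <- unique(cell$cluster_id)
  K <- length(clusters)
  if (K < 2) return(NULL)
  D <- E <- matrix(0, K, 6)
  ii <- match(cell$cluster_id, clusters)
  D[cbind(ii, cell$band)] <- cell$wdeaths
  E[cbind(ii, cell$band)] <- cell$wmonths
  totD <- colSums(D); totE <- colSums(E)
  full_h <- ifelse(totE > 0, totD / totE, 0)
  theta <- vapply(seq_len(K), function(k) {
    p <- q5_prob_from_de(totD - D[k, ], totE - E[k, ],
                         fallback_h = full_h, corr_mass = corr_mass)
    logit(min(max(p, 1e-12), 1 - 1e-12))
  }, numeric(1))
  list(logit_variance = jk_variance(theta, var_floor),
       n_clusters = K, theta_loo = theta)
}

#' Direct estimates of U5MR for every region x year cell
#'
#' Computes the design-weighted synthetic-cohort U5MR, its logit, and the
#' delete-one-cluster jackknife variance for every requested cell. Cells
#' lacking exposure in any age band are retained as missing rows (the
#' Bayesian smoother can interpolate them) and listed in the attached
#' diagnostics; requested regions entirely absent from the records are
#' reported, never silently dropped. Deterministic.
#'
#' @param records birth-history table.
#' @param years integer years to estimate; default all years with exposure.
#' @param regions group labels to estimate; default all present.
#' @param group_col column defining the grouping (default `region`).
#' @param var_floor minimum logit-scale variance.
#' @return data.frame with columns `region`, `year`, `u5mr_per_1000`,
#'   `logit_mean`, `logit_variance`, `n_clusters_contributing`; attribute
#'   `diagnostics` lists missing cells and absent regions.
#' @export
estimate_all <- function(records, years = NULL, regions = NULL,
                         group_col = "region", var_floor = 1e-6) {
  if (nrow(records) == 0) {
    out <- data.frame(region = character(), year = integer(),
                      u5mr_per_1000 = numeric(), logit_mean = numeric(),
                      logit_variance = numeric(),
                      n_clusters_contributing = integer())
    attr(out, "diagnostics") <- list(missing_cells = data.frame(),
                                     absent_regions = regions %||% character(),
                                     note = "empty input")
    return(out)
  }
  et <- exposure_table(records, group_col)
  present <- sort(unique(et$group))
  regions <- regions %||% present
  years <- as.integer(years %||% sort(unique(et$year)))
  absent <- setdiff(regions, present)
  corr <- continuity_mass(et)
  grid <- expand.grid(region = regions, year = years,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    .reg <- grid$region[r]; .yr <- grid$year[r]
    cell <- et[group == .reg & year == .yr]
    D <- E <- numeric(6)
    if (nrow(cell)) {
      agg <- cell[, .(d = sum(wdeaths), m = sum(wmonths)), by = band]
      D[agg$band] <- agg$d; E[agg$band] <- agg$m
    }
    if (any(E <= 0)) {
      rows[[r]] <- data.frame(region = .reg, year = .yr,
                              u5mr_per_1000 = NA_real_, logit_mean = NA_real_,
                              logit_variance = NA_real_,
                              n_clusters_contributing = length(unique(cell$cluster_id)))
      next
    }
    p <- q5_prob_from_de(D, E, corr_mass = corr)
    jk <- cell_jackknife(cell, corr, var_floor)
    lv <- logit_with_delta_variance(p, 0, correction = corr / sum(E))
    rows[[r]] <- data.frame(
      region = .reg, year = .yr,
      u5mr_per_1000 = 1000 * expit(lv$logit_mean),
      logit_mean = lv$logit_mean,
      logit_variance = if (is.null(jk)) NA_real_ else jk$logit_variance,
      n_clusters_contributing = if (is.null(jk)) 1L else jk$n_clusters)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  missing_cells <- out[is.na(out$u5mr_per_1000), c("region", "year")]
  attr(out, "diagnostics") <- list(missing_cells = missing_cells,
                                   absent_regions = absent)
  out
}

#' Write / read the direct-estimates CSV
#' @param estimates output of [estimate_all()].
#' @param path file path.
#' @return `path` (write) or the estimates data.frame (read).
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "u5mr_per_1000", "logit_mean", "logit_variance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ms("estimates file missing column(s): %s", paste(miss, collapse = ", "))
  df
}
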