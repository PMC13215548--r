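test_that("band exposure matches hand enumeration on a 3-child toy", {
  # three children born January 1990; one dies at age 6 months
  rec <- make_records(3, birth_month = month_index(1990, 1))
  rec$death_age_months[1] <- 6L
  be <- band_exposure(rec, "A", 1990)
  # month 0: all three at risk -> 3 person-months in band 1, no deaths
  expect_equal(be$weighted_exposure_months[1], 3)
  expect_equal(be$weighted_deaths[1], 0)
  expect_equal(be$hazard[1], 0)
  # months 1-11 of 1990: child 1 contributes months 1..6 (dies in month 6),
  # children 2-3 contribute months 1..11 -> 6 + 11 + 11 = 28 person-months
  expect_equal(be$weighted_exposure_months[2], 28)
  expect_equal(be$weighted_deaths[2], 1)
  expect_equal(be$hazard[2], 1 / 28)
  # no 1990 exposure above band 2 for January births
  expect_true(all(is.na(be$hazard[3:6])))
  expect_equal(be$weighted_exposure_months[3:6], rep(0, 4))
})

test_that("hazards are invariant to a global weight rescaling", {
  rec <- make_records(6, cluster = rep(c("c1", "c2"), 3),
                      birth_month = month_index(1991, 1))
  rec$death_age_months[c(1, 4)] <- c(3L, 20L)
  be1 <- band_exposure(rec, "A", 1991)
  rec7 <- rec; rec7$weight <- rec7$weight * 7
  be7 <- band_exposure(rec7, "A", 1991)
  expect_equal(be1$hazard, be7$hazard)
  e1 <- estimate_all(rec)
  e7 <- estimate_all(rec7)
  expect_equal(e1$u5mr_per_1000, e7$u5mr_per_1000)
  expect_equal(e1$logit_variance, e7$logit_variance)
})

test_that("life-table combination handles limits and the closed form", {
  expect_equal(u5mr_from_hazards(rep(0, 6)), 0)
  expect_equal(u5mr_from_hazards(c(1, 0, 0, 0, 0, 0)), 1000)
  expect_equal(u5mr_from_hazards(rep(0.002, 6)), 1000 * (1 - 0.998^60))
  expect_error(u5mr_from_hazards(c(rep(0.1, 5), 1.2)), "\\[0, 1\\]")
  expect_error(u5mr_from_hazards(rep(0.1, 5)), "six")
  # monotonicity: raising any band hazard weakly raises q5
  h <- rep(0.001, 6)
  base <- u5mr_from_hazards(h)
  for (b in 1:6) {
    h2 <- h; h2[b] <- 0.002
    expect_gt(u5mr_from_hazards(h2), base)
  }
})

test_that("logit delta-method transform matches algebra and its contract", {
  lv <- logit_with_delta_variance(0.25, 0)
  expect_equal(lv$logit_mean, log(1 / 3))
  lv <- logit_with_delta_variance(0.1, 1e-4)
  expect_equal(lv$logit_variance, 1e-4 / 0.0081)
  expect_error(logit_with_delta_variance(0, 0.1), "boundary")
  lv <- logit_with_delta_variance(0, 1e-4, correction = 0.01)
  expect_equal(lv$logit_mean, qlogis(0.01))
})

test_that("jackknife variance matches the hand formula on a two-cluster toy", {
  # each cluster covers all six age bands during 1992 on its own, so the
  # leave-one-out estimates are plain life tables on the remaining cluster
  mk <- function(cluster, deaths) {
    bm <- c(month_index(1988, 1), month_index(1989, 1), month_index(1990, 1),
            month_index(1991, 1), month_index(1991, 7), month_index(1992, 1))
    r <- make_records(6, cluster = cluster, birth_month = bm,
                      interview = month_index(1997, 6))
    r$death_age_months <- deaths
    r
  }
  rec <- rbind(mk("c1", c(NA, NA, NA, 14L, NA, NA)),
               mk("c2", c(NA, 40L, NA, NA, NA, 1L)))
  rec$child_id <- sprintf("k%02d", 1:12)
  jk <- jackknife_variance(rec, "A", 1992)
  expect_equal(jk$n_clusters, 2)
  # hand-computed leave-one-out logit estimates
  theta <- sapply(c("c2", "c1"), function(keep)
    qlogis(oracle_cell_q5(rec[rec$cluster_id == keep, ], "A", 1992) / 1000))
  v_hand <- (2 - 1) / 2 * sum((theta - mean(theta))^2)
  expect_equal(jk$logit_variance, unname(v_hand), tolerance = 1e-12)

  # identical cluster compositions -> variance collapses to the floor
  rec_id <- make_records(8, cluster = rep(c("c1", "c2"), 4),
                         birth_month = month_index(1992, 1))
  rec_id$death_age_months[1:2] <- 3L  # one death in each cluster
  jk0 <- jackknife_variance(rec_id, "A", 1992)
  expect_equal(jk0$logit_variance, 1e-6)

  expect_error(jackknife_variance(make_records(4), "A", 1990), "one cluster")
})

test_that("estimate_all equals the brute-force life table on small toys", {
  set.seed(14)
  checked <- 0
  for (rep in 1:4) {
    n <- 25
    # five fixed January births 1988-1992 keep every age band of the 1992
    # cell exposed; the 1990 cohort child dies at 30 months (in 1992) so at
    # least one cell per replicate has a nonzero, comparable estimate
    bm <- c(month_index(1988:1992, 1),
            month_index(1988, 1) + sample(0:54, n - 5, TRUE))
    rec <- make_records(n, cluster = sample(c("c1", "c2", "c3"), n, TRUE),
                        birth_month = bm,
                        interview = month_index(1997, 6))
    rec$death_age_months[3] <- 30L
    dies <- which(runif(n) < 0.25 & seq_len(n) > 5)
    rec$death_age_months[dies] <- sample(0:59, length(dies), TRUE)
    # keep deaths observable
    rec$death_age_months <- pmin(rec$death_age_months,
                                 rec$interview_month - rec$birth_month)
    est <- estimate_all(rec)
    for (r in seq_len(nrow(est))) {
      o <- oracle_cell_q5(rec, est$region[r], est$year[r])
      if (is.na(o) || o == 0 || o == 1000) next  # missing band or boundary cell
      expect_equal(est$u5mr_per_1000[r], o, tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})

test_that("estimate_all reports cardinality, missing cells and empty input", {
  e0 <- estimate_all(make_records(1)[0, ])
  expect_equal(nrow(e0), 0)
  expect_equal(attr(e0, "diagnostics")$note, "empty input")

  rec <- make_records(10, cluster = rep(c("c1", "c2"), 5),
                      birth_month = month_index(1995, 1))
  est <- estimate_all(rec, years = 1995:1999, regions = c("A", "Z"))
  expect_equal(nrow(est), 10)  # 2 regions x 5 years, missing rows retained
  expect_equal(attr(est, "diagnostics")$absent_regions, "Z")
  expect_true(all(is.na(est$u5mr_per_1000[est$region == "Z"])))
  # 1995 has no band >= 2y exposure for 1995 births: flagged missing, not zero
  expect_true(all(c("A", "Z") %in%
                    attr(est, "diagnostics")$missing_cells$region))
})
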