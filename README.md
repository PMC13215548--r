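# mortsmooth

Estimation, comparison and forecasting of **subnational under-five
mortality rates (U5MR)** from full-birth-history survey data.

National surveys such as the DHS record, for every interviewed woman, the
birth date and survival status of each of her children under a two-stage
stratified cluster design. Turning those records into annual region-level
mortality series — and then into defensible statements about regional
disparities and future trajectories — takes three linked analyses, all
implemented here:

1. **Direct estimation.** Design-weighted discrete hazards over the six DHS
   age bands (0, 1–11, 12–23, 24–35, 36–47, 48–59 months), combined by the
   synthetic-cohort life table
   `q5 = 1 − Π_a (1 − h_a)^{n_a}`, with logit transform and
   delete-one-cluster jackknife variances.
2. **Functional ANOVA.** Each region's trajectory becomes a penalized
   B-spline curve; a one-way functional ANOVA with a permutation F-test
   (pointwise and global max-statistic critical values) asks when and
   whether regional curves differ.
3. **Bayesian space-time smoothing.** Logit-scale estimates `y_it ~
   N(η_it, v_it)` with known design variances feed the hierarchical model
   `η_it = μ + α_t + γ_t + θ_i + φ_i + δ_it` — iid and random-walk (RW1 or
   RW2) temporal terms, iid and ICAR spatial terms, iid interaction,
   Gamma(0.5, 0.001) precision priors — fitted by a fully conjugate Gibbs
   sampler with joint block updates. Models are compared by DIC and the log
   conditional predictive ordinate (LCPO), variance is decomposed by
   component, and U5MR is forecast by propagating the random-walk recursion,
   e.g. against the SDG target of 25 deaths per 1,000 live births.

A synthetic-data module generates ground-truth mortality surfaces and
DHS-style two-stage cluster samples from them (about 65,000 child records
at its default national scale), so the whole pipeline is testable against
known truth without restricted microdata.

## Worked example

Simulate a national-scale survey from a known truth, estimate, fit both
candidate models, and compare:

```r
library(mortsmooth)

graph   <- load_adjacency()                       # 8-division fixture
truth   <- simulate_truth(truth_spec(seed = 1))   # logit-scale surface
records <- simulate_birth_histories(truth, survey_design(), seed = 2)
nrow(records)
#> [1] 64648

est <- estimate_all(records, years = truth$years,
                    regions = graph$region_names)
head(est, 3)
#>       region year u5mr_per_1000 logit_mean logit_variance n_clusters_contributing
#> 1   Barishal 1990     118.71085  -2.004695     0.03712463                      84
#> 2 Chattogram 1990     110.96425  -2.080929     0.06125041                      84
#> 3      Dhaka 1990      99.46801  -2.203150     0.04980281                      84

cells   <- est[!is.na(est$logit_mean), ]
fit_rw1 <- gibbs_fit(cells, graph, model_spec(temporal_order = 1,
             n_iter = 6000, n_burn = 1000, thin = 5, seed = 3))
fit_rw2 <- gibbs_fit(cells, graph, model_spec(temporal_order = 2,
             n_iter = 6000, n_burn = 1000, thin = 5, seed = 3))
compare_models(fit_rw1, fit_rw2)
#> Model comparison (rule: lower DIC preferred; LCPO reported (higher = better) )
#>   Model I (RW1)    DIC =   179.22  (pD =  31.33)   LCPO =   -88.70
#>   Model II (RW2)   DIC =   178.83  (pD =  29.48)   LCPO =   -88.55
#>   selected: Model II (RW2)
```

The first rows are the raw 1990 estimates: about 100–119 deaths per 1,000
with design variances on the logit scale near 0.04–0.06 from 84 clusters
per division. The smoother with the second-order random-walk trend (Model
II) attains both the lower DIC and the higher LCPO, so it is the one to
forecast with: `forecast(fit_rw2, H = 8, seed = 4)` returns per-division
posterior medians and 95% intervals on the per-1,000 scale through 2030,
with intervals that widen as the horizon grows.
`variance_decomposition(fit_rw2)` apportions the fitted variation among the
five components (the structured temporal term dominates whenever mortality
declines steadily, since the fitted trend lives in it).

The same analysis runs end-to-end from a YAML config, writing every table,
figure and a hashed manifest:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "mortsmooth"),
             output_dir = "demo_out")
```

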