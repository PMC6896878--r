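test_that("IID fit collapses to plain Poisson regression without cluster variation", {
  cfg <- simulation_config(n_clusters = 16, households_per_cluster_mean = 60,
                           study_extent = c(12000, 8000),
                           baseline_expected_mean = 0.4, sigma_cluster = 0,
                           spillover_per_100m = 0, seed = 14)
  sim <- suppressMessages(simulate_trial(cfg))
  f <- fit_smr_model(sim$trial, model_spec("iid"))
  g <- glm(observed ~ arm, poisson(), data = sim$trial$households,
           offset = log(expected))
  expect_lt(f$varcomp$sigma_u, 0.05)
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"],
               coef(g)[["arm"]], tolerance = 0.01)
})

test_that("IID fit agrees with the independent glmer implementation", {
  cfg <- simulation_config(n_clusters = 16, households_per_cluster_mean = 60,
                           study_extent = c(12000, 8000),
                           baseline_expected_mean = 0.4, seed = 15)
  sim <- suppressMessages(simulate_trial(cfg))
  hh <- sim$trial$households
  hh$d100 <- hh$d_discordant / 100
  f <- suppressMessages(spillover_fit(sim$trial, model_spec("iid")))
  g <- lme4::glmer(observed ~ arm + d100 + (1 | cluster_id),
                   offset = log(expected), family = poisson, data = hh)
  fe <- lme4::fixef(g)
  co <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(co[["x"]], fe[["arm"]], tolerance = 2e-3)
  expect_equal(co[["d100"]], fe[["d100"]], tolerance = 2e-3)
  expect_equal(f$varcomp$sigma_u,
               attr(lme4::VarCorr(g)$cluster_id, "stddev")[[1]],
               tolerance = 0.02)
})

test_that("offset rescaling shifts only the intercept", {
  sim <- small_sim()
  f1 <- suppressMessages(spillover_fit(sim$trial, model_spec("iid")))
  tr2 <- sim$trial
  tr2$households$expected <- tr2$households$expected * 7
  f2 <- suppressMessages(spillover_fit(tr2, model_spec("iid")))
  e1 <- setNames(f1$coefficients$estimate, f1$coefficients$term)
  e2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  expect_equal(e1[["(Intercept)"]] - e2[["(Intercept)"]], log(7),
               tolerance = 1e-4)
  expect_equal(e1[["x"]], e2[["x"]], tolerance = 1e-5)
  expect_equal(e1[["d100"]], e2[["d100"]], tolerance = 1e-6)
})

test_that("swapping arm labels negates the intervention estimate", {
  sim <- small_sim()
  f1 <- fit_smr_model(sim$trial, model_spec("iid"))
  tr2 <- sim$trial
  tr2$households$arm <- 1L - tr2$households$arm
  tr2$clusters$arm <- 1L - tr2$clusters$arm
  f2 <- fit_smr_model(tr2, model_spec("iid"))
  b1 <- f1$coefficients$estimate[f1$coefficients$term == "x"]
  b2 <- f2$coefficients$estimate[f2$coefficients$term == "x"]
  expect_equal(b1, -b2, tolerance = 1e-5)
})

test_that("cluster totals are sufficient for the cluster-constant model", {
  sim <- small_sim()
  hh <- sim$trial$households
  f_agg <- fit_smr_model(sim$trial, model_spec("iid"))  # aggregates internally
  expect_identical(f_agg$data_level, "cluster")
  # explicit household-level fit through the engine
  cl_ids <- sort(unique(hh$cluster_id))
  st <- netspill:::structure_iid(hh$cluster_id, cl_ids)
  X <- cbind("(Intercept)" = rep(1, nrow(hh)), x = hh$arm)
  f_hh <- netspill:::laplace_fit(hh$observed, hh$expected, X, st)
  expect_equal(f_agg$coefficients$estimate,
               unname(f_hh$beta), tolerance = 1e-6)
  expect_equal(f_agg$varcomp$sigma_u, f_hh$varcomp$sigma_u, tolerance = 1e-4)
})

test_that("a two-cluster intrinsic CAR is forced to mirrored effects", {
  tr <- toy_trial(obs = c(3L, 2L, 1L, 1L), exp_d = c(1, 1, 1, 1))
  adj <- structure(list(cluster_ids = tr$clusters$cluster_id,
                        W = matrix(c(0L, 1L, 1L, 0L), 2,
                                   dimnames = list(tr$clusters$cluster_id,
                                                   tr$clusters$cluster_id))),
                   class = "queen_adjacency")
  f <- fit_smr_model(tr, model_spec("car"), adj)
  v <- f$random_effects$v
  expect_equal(unname(v[1] + v[2]), 0, tolerance = 1e-10)
})

test_that("smr tables are exp transforms with ordered intervals", {
  sim <- small_sim()
  adj <- queen_adjacency(sim$trial)
  for (m in c("iid", "car", "bym")) {
    f <- fit_smr_model(sim$trial, model_spec(m), adj)
    expect_equal(f$smr_table$smr, exp(f$coefficients$estimate))
    expect_equal(f$smr_table$lower95, exp(f$coefficients$lower95))
    expect_true(all(f$coefficients$lower95 <= f$coefficients$estimate &
                    f$coefficients$estimate <= f$coefficients$upper95))
    expect_true(f$diagnostics$converged)
  }
})

test_that("the GP kernel has variance sigma^2 at 0 and exp(-1) decay at the range", {
  expect_equal(exp_covariance(0, 1.3, 500), 1.3^2)
  expect_equal(exp_covariance(500, 1.3, 500), exp(-1) * 1.3^2)
  expect_equal(exp_covariance(c(0, 250, 500), 2, 250),
               4 * exp(-c(0, 1, 2)))
})

test_that("unsupported inference engines are refused clearly", {
  sim <- small_sim()
  expect_error(fit_smr_model(sim$trial, model_spec("iid",
                                                   inference = "bayes_mcmc")),
               "laplace_map")
})

test_that("households with zero expected deaths are excluded with a message", {
  sim <- small_sim()
  tr <- sim$trial
  tr$households$expected[1:5] <- 0
  tr$households$observed[1:5] <- 0L
  expect_message(f <- fit_smr_model(tr, model_spec("iid")), "5 household")
  expect_equal(f$n_excluded_zero_expected, 5L)
  expect_true(all(is.na(f$fitted[1:5])))
  expect_true(all(!is.na(f$fitted[-(1:5)])))
})

test_that("interaction analysis lays out reference strata at exactly 1", {
  sim <- small_sim()
  ia <- suppressMessages(interaction_analysis(sim$trial, threshold_m = 400))
  tab <- ia$table
  expect_equal(nrow(tab), 8)
  refs <- tab[tab$group %in% c("bed nets") |
              (tab$conditioning == "arm" & grepl("further", tab$group)), ]
  expect_true(all(refs$smr == 1))
  expect_true(ia$interaction_p >= 0 && ia$interaction_p <= 1)
  # contrasts are internally consistent: near/far control contrast equals
  # exp(-gamma) from the full fit
  co <- setNames(ia$fit_full$coefficients$estimate,
                 ia$fit_full$coefficients$term)
  near_ctl <- tab$smr[tab$conditioning == "arm" &
                      tab$stratum == "no bed nets" & grepl("nearer", tab$group)]
  expect_equal(near_ctl, exp(-co[["far"]]), ignore_attr = TRUE)
  # a threshold beyond every distance leaves the far stratum empty
  expect_error(suppressMessages(interaction_analysis(sim$trial,
                                                     threshold_m = 1e9)),
               "empty stratum")
})

test_that("the parametric bootstrap recenters on the base fit and is reproducible", {
  cfg <- simulation_config(n_clusters = 12, households_per_cluster_mean = 40,
                           study_extent = c(12000, 8000),
                           baseline_expected_mean = 0.3,
                           spillover_form = "linear", seed = 31)
  sim <- suppressMessages(simulate_trial(cfg))
  spec <- model_spec("iid", distance = TRUE)
  b1 <- suppressMessages(parametric_bootstrap(sim$trial, spec, n_boot = 60,
                                              seed = 9))
  b2 <- suppressMessages(parametric_bootstrap(sim$trial, spec, n_boot = 60,
                                              seed = 9))
  expect_identical(b1$draws, b2$draws)
  expect_equal(b1$term, "d100")
  expect_lt(b1$n_failed, 3)
  # mean of the bootstrap draws sits near the base estimate
  se_mc <- sd(b1$draws, na.rm = TRUE) / sqrt(sum(!is.na(b1$draws)))
  expect_lt(abs(b1$boot_mean - b1$base_estimate), 4 * se_mc + 1e-4)
  expect_true(b1$smr_ci[1] < b1$smr_ci[2])
  expect_false(b1$flagged)
})
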