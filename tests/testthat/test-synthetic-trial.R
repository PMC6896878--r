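test_that("geography generation is deterministic and tiles the rectangle", {
  cfg <- simulation_config(n_clusters = 4, households_per_cluster_mean = 10,
                           study_extent = c(2000, 1000), seed = 1)
  g1 <- generate_geography(cfg)
  g2 <- generate_geography(cfg)
  expect_identical(g1$households, g2$households)
  expect_identical(g1$geometry, g2$geometry)
  areas <- vapply(g1$geometry, netspill:::polygon_area, numeric(1))
  expect_equal(sum(areas), 2000 * 1000, tolerance = 1e-6)
  # households lie inside their polygons
  expect_silent(validate_trial_data(g1, snap_tol = 1e-6))
})

test_that("balanced 1:1 randomization allocates 48 of 96 clusters to each arm", {
  cfg <- simulation_config(n_clusters = 96, households_per_cluster_mean = 2,
                           seed = 3)
  g <- generate_geography(cfg)
  expect_equal(sum(g$clusters$arm == 1L), 48L)
  expect_equal(sum(g$clusters$arm == 0L), 48L)
})

test_that("null generator gives SMR near 1 and the ground truth is exact", {
  cfg <- simulation_config(n_clusters = 24, households_per_cluster_mean = 80,
                           study_extent = c(15000, 10000),
                           baseline_control_smr = 1, sigma_cluster = 0,
                           log_intervention_effect = 0, spillover_per_100m = 0,
                           seed = 11)
  sim <- simulate_trial(cfg)
  hh <- sim$trial$households
  E <- sum(hh$expected)
  expect_lt(abs(sum(hh$observed) / E - 1), 4 / sqrt(E))  # Monte Carlo band
  # conservation: stored linear predictors reproduce every Poisson mean
  th <- sim$truth
  eta <- th$alpha + th$beta * hh$arm + th$u[hh$cluster_id] + th$s + th$spill
  expect_equal(unname(eta), th$eta)
  expect_equal(hh$expected * exp(th$eta), th$mu)
})

test_that("intervention effect and spillover appear at their configured size", {
  cfg <- simulation_config(n_clusters = 48, households_per_cluster_mean = 120,
                           spillover_per_100m = 0, sigma_cluster = 0,
                           study_extent = c(21000, 14000), seed = 21)
  sim <- simulate_trial(cfg)
  hh <- sim$trial$households
  r1 <- sum(hh$observed[hh$arm == 1]) / sum(hh$expected[hh$arm == 1])
  r0 <- sum(hh$observed[hh$arm == 0]) / sum(hh$expected[hh$arm == 0])
  se <- sqrt(1 / sum(hh$observed[hh$arm == 1]) + 1 / sum(hh$observed[hh$arm == 0]))
  expect_lt(abs(log(r1 / r0) - log(0.83)), 3.5 * se)

  # closed form on the capped spillover: control Poisson-mean multiplier at
  # d = 400 vs d = 100 is exp(3 * psi)
  sim2 <- small_sim()
  th <- sim2$truth
  hh2 <- sim2$trial$households
  ctl <- hh2$arm == 0
  expect_equal(th$spill[ctl],
               th$psi * pmin(hh2$d_discordant[ctl], 400) / 100)
  expect_equal(exp(th$psi * 400 / 100) / exp(th$psi * 100 / 100),
               exp(3 * th$psi))
  # intervention households sit at the range plateau
  expect_true(all(th$spill[!ctl] == th$psi * 4))
})

test_that("scenario grid is tidy, carries the truth, and records failures", {
  cfg <- simulation_config(n_clusters = 8, households_per_cluster_mean = 30,
                           study_extent = c(8000, 6000), seed = 5)
  tab <- suppressMessages(scenario_grid(cfg, n_replicates = 1))
  expect_s3_class(tab, "data.frame")
  expect_setequal(unique(tab$model), c("iid", "iid_distance"))
  expect_equal(unique(tab$truth[tab$term == "x"]), log(0.83))
  expect_equal(unique(tab$truth[tab$term == "d100"]), log(1.017))
  expect_equal(tab$bias, tab$estimate - tab$truth)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$lower95 <= tab$estimate & tab$estimate <= tab$upper95))
})
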