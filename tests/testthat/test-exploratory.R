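test_that("join counts respect closed forms on grids", {
  adj <- rook_grid_adj(3, 3)
  lab <- checkerboard(3, 3)
  jc <- join_counts(adj, lab)
  expect_equal(unname(jc), c(0, 0, 12))  # alternation: all joins discordant
  expect_equal(sum(jc), sum(adj$W) / 2)
  all1 <- setNames(rep(1, 9), adj$cluster_ids)
  expect_equal(unname(join_counts(adj, all1)), c(12, 0, 0))
  expect_error(join_counts(adj, all1[-1]), "missing")
})

test_that("join-count permutation null matches the nonfree-sampling expectation", {
  adj <- rook_grid_adj(3, 3)
  lab <- setNames(c(rep(1, 5), rep(0, 4)), adj$cluster_ids)
  res <- join_count_test(adj, lab, color = 1, n_sim = 2000, seed = 7)
  # E[BB] = J * nB(nB-1) / (n(n-1)) = 12 * 20 / 72
  expect_equal(mean(res$null_draws), 12 * 20 / 72, tolerance = 0.05)
  expect_equal(res$p_value,
               (1 + sum(res$null_draws >= res$observed)) / (1 + res$n_sim))
})

test_that("join-count test separates clustered from alternating patterns", {
  adj <- rook_grid_adj(4, 4)
  ids <- adj$cluster_ids
  half <- setNames(as.numeric(seq_along(ids) <= 8), ids)  # solid half plane
  res <- join_count_test(adj, half, color = 1, n_sim = 999, seed = 2)
  expect_lte(res$p_value, 0.05)
  expect_equal(res$observed, 10)  # 4x2 block has 10 internal rook joins
  chk <- checkerboard(4, 4)
  res2 <- join_count_test(adj, chk, color = 1, n_sim = 999, seed = 2)
  expect_gt(res2$p_value, 0.9)   # BB = 0: no same-color clustering
  expect_error(join_count_test(adj, half, color = 3), "absent")
})

test_that("Moran's I hits closed forms and the brute-force double sum", {
  adj <- rook_grid_adj(4, 4)
  chk <- 2 * checkerboard(4, 4) - 1
  expect_equal(morans_i(adj, chk), -1)  # perfect negative autocorrelation
  expect_error(morans_i(adj, rep(1, 16)), "zero variance")

  sim <- small_sim()
  vadj <- queen_adjacency(sim$trial)
  set.seed(31)
  for (r in 1:20) {
    v <- rnorm(length(vadj$cluster_ids))
    z <- v - mean(v)
    n <- length(z)
    bf <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      bf <- bf + vadj$W[i, j] * z[i] * z[j]
    bf <- (n / sum(vadj$W)) * bf / sum(z^2)
    expect_equal(morans_i(vadj, v), bf, tolerance = 1e-12)
  }
})

test_that("Moran permutation null has mean -1/(n-1) and honors direction", {
  adj <- rook_grid_adj(4, 4)
  set.seed(5)
  v <- rnorm(16)
  res <- morans_i_test(adj, v, n_sim = 2000, seed = 13)
  expect_lt(abs(mean(res$null_draws) - (-1 / 15)), 0.012)  # ~3 MC SEs
  expect_true(res$p_value > 0 && res$p_value <= 1)
  chk <- 2 * checkerboard(4, 4) - 1
  res2 <- morans_i_test(adj, chk, n_sim = 499, seed = 13)
  expect_gt(res2$p_value, 0.95)  # checkerboard under 'greater'
  res3 <- morans_i_test(adj, chk, n_sim = 499, seed = 13,
                        alternative = "less")
  expect_equal(res3$p_value, 1 / 500)  # beats every permutation
})

test_that("a cluster-level spatial field is detected in the cluster SMRs", {
  cfg <- simulation_config(n_clusters = 30, households_per_cluster_mean = 100,
                           study_extent = c(18000, 12000),
                           baseline_expected_mean = 0.4,
                           spatial_field = "icar", icar_sd = 1.0,
                           spillover_per_100m = 0, seed = 701)
  sim <- suppressMessages(simulate_trial(cfg))
  adj <- suppressMessages(queen_adjacency(sim$trial))
  s <- summarize_trial(sim$trial)$smr
  cl_smr <- setNames(s$smr[s$scope == "cluster"], s$label[s$scope == "cluster"])
  res <- morans_i_test(adj, cl_smr[adj$cluster_ids], n_sim = 999, seed = 4)
  expect_lte(res$p_value, 0.01)
  # residual Moran after the IID fit is valid and reproducible; its power
  # against cluster-level fields is limited by design, since the fitted
  # cluster intercepts absorb most of the field (see the methods vignette)
  fit <- suppressMessages(fit_smr_model(sim$trial, model_spec("iid")))
  r1 <- residual_morans(sim$trial, fit, adj, n_sim = 299, seed = 5)
  r2 <- residual_morans(sim$trial, fit, adj, n_sim = 299, seed = 5)
  expect_identical(r1$null_draws, r2$null_draws)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_equal(r1$p_value,
               (1 + sum(r1$null_draws >= r1$observed)) / (1 + r1$n_sim))
})

test_that("GWR reduces to the global Poisson fit at infinite bandwidth", {
  sim <- small_sim()
  tr <- sim$trial
  hh <- tr$households
  gfit <- glm(observed ~ arm, poisson(), data = hh, offset = log(expected))
  surf <- gwr_poisson(tr, bandwidth_m = 1e9, kernel = "uniform")
  expect_true(all(surf$surface$defined))
  expect_equal(surf$surface$estimate,
               rep(exp(coef(gfit)[["arm"]]), nrow(surf$surface)),
               tolerance = 1e-8)
  expect_equal(surf$summary$median, exp(coef(gfit)[["arm"]]),
               tolerance = 1e-8)
})

test_that("a two-cluster neighborhood returns the ratio of cluster SMRs", {
  tr <- toy_trial(obs = c(2L, 2L, 1L, 1L), exp_d = c(1, 1, 1, 1))
  surf <- gwr_poisson(tr, bandwidth_m = 1e6, kernel = "uniform",
                      min_neighbors = 2L)
  # saturated two-group Poisson: exp(beta) = SMR_int / SMR_ctl = (2/2)/(4/2)
  expect_equal(surf$surface$estimate, rep(0.5, 2), tolerance = 1e-9)
})

test_that("gwr_bandwidth is the smallest radius covering both arms everywhere", {
  sim <- small_sim()
  bw <- gwr_bandwidth(sim$trial, min_neighbors = 5L)
  surf <- gwr_poisson(sim$trial, bw, min_neighbors = 5L)
  expect_true(all(surf$surface$defined))
  shrunk <- gwr_poisson(sim$trial, bw * 0.7, min_neighbors = 5L)
  expect_true(any(!shrunk$surface$defined))
})
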