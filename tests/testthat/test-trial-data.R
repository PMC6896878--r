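test_that("smr is observed over expected with a guarded domain", {
  expect_equal(smr(5, 4), 1.25)
  expect_equal(smr(0, 4), 0)
  expect_error(smr(3, 0), "expected_total")
  # consistency with the motivating trial's scale: 861 deaths at SMR 1.24
  expect_equal(smr(861, 694.35), 1.24, tolerance = 1e-4)
})

test_that("validation names the offending record", {
  tr <- toy_trial()
  bad <- tr
  bad$households$arm[1] <- 1L   # control cluster, intervention household
  expect_error(trial_data(bad$households, bad$clusters, bad$geometry), "h1")
  bad <- tr
  bad$households$household_id[2] <- "h1"
  expect_error(trial_data(bad$households, bad$clusters, bad$geometry),
               "duplicate household_id: h1")
  bad <- tr
  bad$households$cluster_id[3] <- "nope"
  expect_error(trial_data(bad$households, bad$clusters, bad$geometry),
               "unknown cluster_id nope")
  bad <- tr
  bad$households$observed[4] <- -1L
  expect_error(trial_data(bad$households, bad$clusters, bad$geometry),
               "nonnegative")
  bad <- tr
  bad$households$expected[1] <- 0
  expect_error(trial_data(bad$households, bad$clusters, bad$geometry),
               "observed > 0 with expected = 0")
  # households far outside their polygon warn rather than error
  odd <- tr$households
  odd$x[1] <- 5000
  expect_warning(trial_data(odd, tr$clusters, tr$geometry), "outside")
})

test_that("discordant distance matches geometry and the brute-force oracle", {
  hh <- data.frame(household_id = c("a", "b"), x = c(0, 300), y = c(0, 400),
                   cluster_id = c("g0101", "g0201"), arm = c(0L, 1L),
                   observed = c(0L, 0L), expected = c(1, 1))
  tr <- trial_data(hh, data.frame(cluster_id = c("g0101", "g0201"),
                                  arm = c(0L, 1L)),
                   grid_geoms(2, 1, size = 500), snap_tol = 1000)
  tr <- distance_to_discordant(tr)
  expect_equal(tr$households$d_discordant, c(500, 500))  # 3-4-5 triangle

  # coincident opposite-arm households give zero
  hh2 <- hh; hh2$x <- c(10, 10); hh2$y <- c(10, 10)
  tr2 <- trial_data(hh2, data.frame(cluster_id = c("g0101", "g0201"),
                                    arm = c(0L, 1L)),
                    grid_geoms(2, 1, size = 500), snap_tol = 1000)
  expect_equal(distance_to_discordant(tr2)$households$d_discordant, c(0, 0))

  # exhaustive pairwise oracle on 200 random households
  set.seed(99)
  n <- 200
  hh3 <- data.frame(household_id = sprintf("h%03d", 1:n),
                    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                    cluster_id = sample(c("g0101", "g0201"), n, TRUE),
                    observed = 0L, expected = 1)
  hh3$arm <- ifelse(hh3$cluster_id == "g0101", 0L, 1L)
  tr3 <- trial_data(hh3, data.frame(cluster_id = c("g0101", "g0201"),
                                    arm = c(0L, 1L)),
                    grid_geoms(2, 1, size = 1000), snap_tol = Inf)
  tr3 <- distance_to_discordant(tr3)
  D <- as.matrix(dist(cbind(hh3$x, hh3$y)))
  oracle <- sapply(seq_len(n), function(i)
    min(D[i, hh3$arm != hh3$arm[i]]))
  expect_identical(tr3$households$d_discordant, oracle)

  one_arm <- tr3
  one_arm$households$arm <- 1L
  expect_error(distance_to_discordant(one_arm), "both arms")
})

test_that("summaries reproduce hand-computed ratios and conserve the overall SMR", {
  tr <- toy_trial(obs = c(2L, 2L, 1L, 1L), exp_d = c(1, 1, 1, 1))
  s <- suppressMessages(summarize_trial(tr))$smr
  expect_equal(s$smr[s$scope == "overall"], 6 / 4)
  expect_equal(s$smr[s$label == "control"], 2 * s$smr[s$label == "intervention"])

  sim <- small_sim()
  s2 <- summarize_trial(sim$trial)$smr
  hh <- sim$trial$households
  expect_equal(s2$smr[s2$label == "intervention"],
               sum(hh$observed[hh$arm == 1]) / sum(hh$expected[hh$arm == 1]))
  # conservation: overall SMR is the expected-death-weighted cluster mix
  cl <- s2[s2$scope == "cluster", ]
  expect_equal(s2$smr[s2$scope == "overall"],
               sum(cl$smr * cl$expected) / sum(cl$expected))
  # distance quartiles are ordered and positive
  dq <- summarize_trial(sim$trial)$distance
  expect_true(all(dq$q25 < dq$median & dq$median < dq$q75))
})

test_that("write then read round-trips a 500-household synthetic trial", {
  sim <- small_sim()
  tr <- sim$trial
  hp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".geojson")
  write_trial(tr, hp, cp)
  back <- read_trial(hp, cp)
  expect_equal(back$households$household_id, tr$households$household_id)
  expect_equal(back$households$x, tr$households$x, tolerance = 1e-9)
  expect_equal(back$households$y, tr$households$y, tolerance = 1e-9)
  expect_identical(back$households$observed, tr$households$observed)
  expect_equal(back$households$expected, tr$households$expected,
               tolerance = 1e-9)
  expect_identical(back$households$arm, tr$households$arm)
  expect_equal(back$clusters[order(back$clusters$cluster_id), ],
               tr$clusters[order(tr$clusters$cluster_id), ],
               tolerance = 1e-9, ignore_attr = TRUE)
  for (id in names(tr$geometry))
    expect_equal(back$geometry[[id]][[1]], tr$geometry[[id]][[1]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(read_trial(cp, cp), "missing columns|FeatureCollection")
})
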