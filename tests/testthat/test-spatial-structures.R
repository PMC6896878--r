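test_that("queen adjacency counts corner touches and respects strips", {
  adj22 <- queen_adjacency(grid_geoms(2, 2))
  expect_equal(sum(adj22$W) / 2, 6)  # all pairs, including the diagonals
  adj13 <- queen_adjacency(grid_geoms(3, 1))
  expect_equal(sum(adj13$W) / 2, 2)  # strip ends are not adjacent
  expect_true(all(adj13$W == t(adj13$W)))
  expect_true(all(diag(adj13$W) == 0))
})

test_that("queen adjacency is invariant to translation and vertex order", {
  sim <- small_sim()
  adj <- queen_adjacency(sim$trial)
  shifted <- lapply(sim$trial$geometry, function(g)
    lapply(g, function(r) sweep(r, 2, c(1e5, -2e4), "+")))
  expect_identical(queen_adjacency(shifted)$W, adj$W)
  rotated <- lapply(sim$trial$geometry, function(g)
    lapply(g, function(r) r[c(2:nrow(r), 1), , drop = FALSE]))
  expect_identical(queen_adjacency(rotated)$W, adj$W)
})

test_that("Voronoi adjacency matches the brute-force shared-point oracle", {
  sim <- small_sim()
  geoms <- sim$trial$geometry
  adj <- queen_adjacency(sim$trial)
  ids <- names(geoms)
  # oracle: polygons share a boundary point iff they share a vertex after
  # rounding (Voronoi cells meet at whole edges or vertices)
  key <- lapply(geoms, function(g)
    unique(apply(round(g[[1]], 6), 1, paste, collapse = ",")))
  W2 <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && length(intersect(key[[i]], key[[j]])))
      W2[i, j] <- W2[j, i] <- 1L
  }
  expect_identical(adj$W, W2)
})

test_that("subsetting induces the subgraph and matches recomputation", {
  sim <- small_sim()
  adj <- queen_adjacency(sim$trial)
  expect_identical(subset_adjacency(adj, adj$cluster_ids)$W, adj$W)
  # two non-neighbors give the zero matrix
  nz <- which(adj$W == 0 & upper.tri(adj$W), arr.ind = TRUE)[1, ]
  pair <- adj$cluster_ids[nz]
  expect_true(all(subset_adjacency(adj, pair)$W == 0))
  expect_error(subset_adjacency(adj, "zzz"), "unknown cluster")
  set.seed(8)
  for (rep in 1:5) {
    keep <- sample(adj$cluster_ids, 6)
    sub <- subset_adjacency(adj, keep)
    rec <- suppressMessages(queen_adjacency(sim$trial$geometry[sub$cluster_ids]))
    expect_identical(sub$W, rec$W)
  }
})

test_that("dilation reassignment is an identity at buffer 0 and exhausts at huge buffers", {
  sim <- small_sim()
  tr <- sim$trial
  da0 <- dilate_and_reassign(tr, 1L, 0)
  expect_identical(da0$assignment$assigned_arm, tr$households$arm)
  expect_length(da0$reassigned_ids, 0)
  expect_false(da0$degenerate)
  daBig <- dilate_and_reassign(tr, 1L, 1e6)
  expect_true(daBig$degenerate)
  expect_setequal(daBig$reassigned_ids,
                  tr$households$household_id[tr$households$arm == 0L])
  expect_error(apply_reassignment(tr, daBig), "degenerate")
})

test_that("reassignment equals the point-to-union-distance rule and is monotone", {
  sim <- small_sim()
  tr <- sim$trial
  dil_ids <- tr$clusters$cluster_id[tr$clusters$arm == 1L]
  opp <- tr$households[tr$households$arm == 0L, ]
  opp <- opp[seq_len(min(nrow(opp), 400)), ]
  # independent brute-force distance of each control household to the union
  bf <- vapply(seq_len(nrow(opp)), function(i)
    min(vapply(dil_ids, function(id)
      bf_point_poly_dist(opp$x[i], opp$y[i], tr$geometry[[id]]),
      numeric(1))), numeric(1))
  prev <- character(0)
  for (b in c(100, 250, 500, 900)) {
    da <- dilate_and_reassign(tr, 1L, b)
    expect_setequal(intersect(da$reassigned_ids, opp$household_id),
                    opp$household_id[bf <= b])
    expect_true(all(prev %in% da$reassigned_ids))  # monotone in buffer
    prev <- da$reassigned_ids
  }
})

test_that("reassigned households join pseudo-clusters of the dilated arm", {
  sim <- small_sim()
  da <- dilate_and_reassign(sim$trial, 0L, 300)
  tr2 <- apply_reassignment(sim$trial, da)
  moved <- tr2$households[tr2$households$household_id %in% da$reassigned_ids, ]
  expect_true(all(moved$arm == 0L))
  expect_true(all(grepl("^realloc_0_300_", moved$cluster_id)))
  expect_true(all(moved$cluster_id %in% tr2$clusters$cluster_id))
  # untouched households keep everything
  keep <- !tr2$households$household_id %in% da$reassigned_ids
  expect_identical(tr2$households$cluster_id[keep],
                   sim$trial$households$cluster_id[keep])
  # serialization round-trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_assignment(da, p)
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(sim$trial$households))
  expect_equal(sum(back$original_arm != back$assigned_arm),
               length(da$reassigned_ids))
})
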