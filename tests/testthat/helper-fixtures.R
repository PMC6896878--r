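# Shared fixtures, all built in code.

# named list of axis-aligned square polygon geometries laid out on a grid
grid_geoms <- function(nx, ny, size = 1, origin = c(0, 0)) {
  geoms <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      x0 <- origin[1] + (i - 1) * size
      y0 <- origin[2] + (j - 1) * size
      ring <- matrix(c(x0, y0, x0 + size, y0,
                       x0 + size, y0 + size, x0, y0 + size),
                     ncol = 2, byrow = TRUE)
      geoms[[sprintf("g%02d%02d", i, j)]] <- list(ring)
    }
  }
  geoms
}

# rook-adjacency object on an nx x ny grid (edge-sharing neighbors only),
# in the same cluster order as grid_geoms
rook_grid_adj <- function(nx, ny) {
  ids <- as.vector(outer(seq_len(nx), seq_len(ny),
                         function(i, j) sprintf("g%02d%02d", i, j)))
  k <- nx * ny
  W <- matrix(0L, k, k, dimnames = list(ids, ids))
  idx <- function(i, j) (j - 1) * nx + i
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) W[idx(i, j), idx(i + 1, j)] <- W[idx(i + 1, j), idx(i, j)] <- 1L
    if (j < ny) W[idx(i, j), idx(i, j + 1)] <- W[idx(i, j + 1), idx(i, j)] <- 1L
  }
  structure(list(cluster_ids = ids, W = W), class = "queen_adjacency")
}

# checkerboard 0/1 labels for an nx x ny grid, in grid_geoms order
checkerboard <- function(nx, ny) {
  lab <- as.vector(outer(seq_len(nx), seq_len(ny), function(i, j) (i + j) %% 2))
  names(lab) <- as.vector(outer(seq_len(nx), seq_len(ny),
                                function(i, j) sprintf("g%02d%02d", i, j)))
  lab
}

# minimal valid two-cluster trial
toy_trial <- function(obs = c(2L, 1L, 3L, 1L), exp_d = c(1, 1, 1, 1)) {
  geoms <- grid_geoms(2, 1, size = 100)
  hh <- data.frame(
    household_id = c("h1", "h2", "h3", "h4"),
    x = c(25, 75, 125, 175), y = c(50, 50, 50, 50),
    cluster_id = rep(names(geoms), each = 2),
    arm = rep(c(0L, 1L), each = 2),
    observed = obs, expected = exp_d)
  trial_data(hh, data.frame(cluster_id = names(geoms), arm = c(0L, 1L)),
             geoms)
}

# small synthetic trial reused across test files (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(simulate_trial(simulation_config(
        n_clusters = 12, households_per_cluster_mean = 50,
        study_extent = c(12000, 8000), seed = 424)))
    cache
  }
})

# brute-force point-to-polygon distance (independent of the package's
# segment kernels): dense sampling of the boundary plus inside test by
# winding of sampled rays is avoided; uses direct segment projection math
# written differently from the C++ implementation
bf_point_poly_dist <- function(px, py, geom) {
  inside <- FALSE
  for (ring in geom) {
    n <- nrow(ring)
    xi <- ring[, 1]; yi <- ring[, 2]
    j <- c(n, seq_len(n - 1))
    cross <- ((yi > py) != (yi[j] > py)) &
      (px < (ring[j, 1] - xi) * (py - yi) / (yi[j] - yi) + xi)
    if (sum(cross) %% 2 == 1) inside <- !inside
  }
  if (inside) return(0)
  best <- Inf
  for (ring in geom) {
    n <- nrow(ring)
    for (s in seq_len(n)) {
      a <- ring[s, ]; b <- ring[if (s == n) 1 else s + 1, ]
      ab <- b - a
      t <- sum((c(px, py) - a) * ab) / sum(ab * ab)
      t <- min(max(t, 0), 1)
      best <- min(best, sum((c(px, py) - a - t * ab)^2))
    }
  }
  sqrt(best)
}
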