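# Exploratory spatial statistics on the cluster contiguity graph: join
# counts and Moran's I with Monte Carlo permutation inference, Moran's I on
# model residuals, and geographically weighted Poisson regression.

# permutation machinery shared by join-count and Moran tests
#' @keywords internal
permutation_result <- function(statistic_name, observed, null_draws,
                               alternative, seed) {
  n_sim <- length(null_draws)
  p_greater <- (1 + sum(null_draws >= observed)) / (1 + n_sim)
  p_less <- (1 + sum(null_draws <= observed)) / (1 + n_sim)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(statistic_name = statistic_name, observed = observed,
                 n_sim = n_sim, null_draws = null_draws, p_value = p,
                 alternative = alternative, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, Monte Carlo p = %.4g (%s, %d permutations)\n",
              x$statistic_name, x$observed, x$p_value, x$alternative, x$n_sim))
  invisible(x)
}

#' Join counts of a binary labeling on the contiguity graph
#'
#' Counts the unordered pairs of adjacent clusters by label combination:
#' both 1 ("BB"), both 0 ("WW"), discordant ("BW"). The three counts always
#' sum to the number of adjacent pairs.
#'
#' @param adj a `queen_adjacency` object.
#' @param labels binary vector, named by cluster id or in `adj` order.
#' @return named numeric vector `c(BB, WW, BW)`.
#' @export
join_counts <- function(adj, labels) {
  labels <- align_cluster_values(adj, labels, "labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  idx <- which(upper.tri(adj$W) & adj$W == 1L, arr.ind = TRUE)
  a <- labels[idx[, 1L]]; b <- labels[idx[, 2L]]
  c(BB = sum(a == 1 & b == 1), WW = sum(a == 0 & b == 0), BW = sum(a != b))
}

#' @keywords internal
align_cluster_values <- function(adj, values, what = "values") {
  if (!is.null(names(values))) {
    miss <- setdiff(adj$cluster_ids, names(values))
    if (length(miss))
      stop(what, " missing for cluster(s): ", paste(miss, collapse = ", "))
    values <- values[adj$cluster_ids]
  } else if (length(values) != length(adj$cluster_ids)) {
    stop(what, " must cover all ", length(adj$cluster_ids), " clusters")
  }
  unname(values)
}

#' Monte Carlo join-count test for clustering of one color
#'
#' The statistic is the same-color join count for the requested color; the
#' null distribution comes from random permutations of the labels over the
#' clusters (nonfree sampling). The default one-sided "greater" alternative
#' asks whether same-color neighbors occur more often than random allocation
#' would produce.
#'
#' @inheritParams join_counts
#' @param color 0 or 1: which color's same-color joins to test.
#' @param n_sim number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return a `permutation_test` object; `p_value` follows the
#'   `(1 + exceedances) / (1 + n_sim)` convention.
#' @export
join_count_test <- function(adj, labels, color, n_sim = 999, seed = 1L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_sim >= 99)
  labels <- align_cluster_values(adj, labels, "labels")
  if (!any(labels == color))
    stop("color ", color, " absent from labels")
  same_count <- function(l) {
    jc <- join_counts(adj, l)
    if (color == 1) jc[["BB"]] else jc[["WW"]]
  }
  obs <- same_count(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_sim), function(i) same_count(sample(labels)),
                 numeric(1))
  permutation_result(paste0("join count (color ", color, ")"), obs, null,
                     alternative, seed)
}

#' Moran's I over a binary contiguity matrix
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the sum of the weights. The weight matrix is binary, not
#' row-standardized. Clusters without neighbors contribute to the denominator
#' only (a message notes them).
#'
#' @param adj a `queen_adjacency` object.
#' @param values numeric per-cluster values (named or in `adj` order) with
#'   positive variance.
#' @return Moran's I.
#' @export
morans_i <- function(adj, values) {
  z <- align_cluster_values(adj, values)
  if (stats::var(z) == 0)
    stop("Moran's I undefined: values have zero variance")
  n <- length(z)
  S0 <- sum(adj$W)
  if (S0 <= 0) stop("Moran's I undefined: no adjacent pairs")
  if (any(rowSums(adj$W) == 0L))
    message(sum(rowSums(adj$W) == 0L),
            " cluster(s) without neighbors enter the denominator only")
  z <- z - mean(z)
  (n / S0) * drop(z %*% adj$W %*% z) / sum(z^2)
}

#' Monte Carlo permutation test for Moran's I
#'
#' Null draws recompute Moran's I after shuffling the cluster values to
#' different locations; under this null the expectation of I is
#' `-1 / (n - 1)`.
#'
#' @inheritParams morans_i
#' @inheritParams join_count_test
#' @return a `permutation_test` object.
#' @export
morans_i_test <- function(adj, values, n_sim = 999, seed = 1L,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_sim >= 99)
  z <- align_cluster_values(adj, values)
  obs <- morans_i(adj, z)
  set.seed(seed)
  null <- vapply(seq_len(n_sim),
                 function(i) suppressMessages(morans_i(adj, sample(z))),
                 numeric(1))
  permutation_result("Moran's I", obs, null, alternative, seed)
}

#' Moran's I on cluster-aggregated Pearson residuals of an SMR model
#'
#' Household Pearson residuals `(observed - fitted) / sqrt(fitted)` from a
#' fitted model are averaged within clusters and tested for spatial
#' autocorrelation, giving a Moran test adjusted for the intervention effect
#' and the cluster structure.
#'
#' @param trial the `trial_data` the model was fitted to.
#' @param fit an `smr_fit` with per-household fitted means (e.g. the IID
#'   model).
#' @param adj a `queen_adjacency` over the trial clusters.
#' @inheritParams join_count_test
#' @return a `permutation_test` object.
#' @export
residual_morans <- function(trial, fit, adj, n_sim = 999, seed = 1L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  hh <- trial$households
  mu <- fit$fitted[hh$household_id]
  keep <- !is.na(mu)
  if (any(mu[keep] <= 0)) stop("nonpositive fitted mean encountered")
  r <- (hh$observed[keep] - mu[keep]) / sqrt(mu[keep])
  cl <- hh$cluster_id[keep]
  rbar <- tapply(r, cl, mean)
  morans_i_test(adj, rbar[adj$cluster_ids], n_sim = n_sim, seed = seed,
                alternative = alternative)
}

#' Geographically weighted Poisson regression of the intervention effect
#'
#' At each cluster centroid, a kernel-weighted Poisson regression of observed
#' deaths on the intervention indicator (offset: log expected deaths, no
#' cluster random effect) is fitted over the households within the bandwidth
#' radius, giving one local intervention SMR per focal cluster. Focal
#' clusters with fewer than `min_neighbors` households in either arm inside
#' the radius are flagged undefined.
#'
#' @param trial a `trial_data` object.
#' @param bandwidth_m fixed kernel radius in meters (see [gwr_bandwidth()]
#'   for a data-driven choice).
#' @param kernel `"bisquare"` (default) `(1 - (d/h)^2)^2` inside the radius,
#'   or `"uniform"`.
#' @param min_neighbors minimum households per arm within the radius.
#' @return object of class `gwr_surface`: `surface` data.frame
#'   (`cluster_id`, `x`, `y`, `estimate`, `n_local`, `defined`), the
#'   bandwidth and kernel, and `summary` (median, quartiles, number defined,
#'   number of estimates above 1).
#' @export
gwr_poisson <- function(trial, bandwidth_m,
                        kernel = c("bisquare", "uniform"),
                        min_neighbors = 10L) {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth_m > 0)
  hh <- trial$households[trial$households$expected > 0, ]
  cl <- trial$clusters
  est <- rep(NA_real_, nrow(cl)); nloc <- integer(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    d <- sqrt((hh$x - cl$centroid_x[i])^2 + (hh$y - cl$centroid_y[i])^2)
    sel <- d < bandwidth_m
    nloc[i] <- sum(sel)
    if (min(tabulate(hh$arm[sel] + 1L, 2L)) < min_neighbors) next
    w <- if (kernel == "bisquare") (1 - (d[sel] / bandwidth_m)^2)^2
         else rep(1, sum(sel))
    f <- suppressWarnings(stats::glm(
      observed ~ arm, family = stats::poisson(),
      offset = log(expected), weights = w, data = hh[sel, ]))
    est[i] <- exp(stats::coef(f)[["arm"]])
  }
  if (all(is.na(est))) stop("no focal cluster has both arms represented")
  q <- stats::quantile(est, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
  structure(list(
    surface = data.frame(cluster_id = cl$cluster_id, x = cl$centroid_x,
                         y = cl$centroid_y, estimate = est, n_local = nloc,
                         defined = !is.na(est)),
    bandwidth_m = bandwidth_m, kernel = kernel,
    summary = list(median = q[2L], q25 = q[1L], q75 = q[3L],
                   n_defined = sum(!is.na(est)),
                   n_above_1 = sum(est > 1, na.rm = TRUE))),
    class = "gwr_surface")
}

#' @export
print.gwr_surface <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("GWR Poisson surface (%s kernel, bandwidth %g m): ",
                     "%d/%d focal clusters defined\n",
                     "  local intervention SMR median %.3f (IQR %.3f-%.3f); ",
                     "%d estimates > 1\n"),
              x$kernel, x$bandwidth_m, s$n_defined, nrow(x$surface),
              s$median, s$q25, s$q75, s$n_above_1))
  invisible(x)
}

#' Smallest bandwidth giving every focal cluster both arms
#'
#' Returns the smallest radius at which every cluster centroid has at least
#' `min_neighbors` households of each arm within it (plus a hair of slack so
#' the strict `<` radius comparison includes the determining household).
#'
#' @inheritParams gwr_poisson
#' @return bandwidth in meters.
#' @export
gwr_bandwidth <- function(trial, min_neighbors = 10L) {
  hh <- trial$households[trial$households$expected > 0, ]
  cl <- trial$clusters
  per_focal <- vapply(seq_len(nrow(cl)), function(i) {
    d <- sqrt((hh$x - cl$centroid_x[i])^2 + (hh$y - cl$centroid_y[i])^2)
    max(sort(d[hh$arm == 0L])[min_neighbors],
        sort(d[hh$arm == 1L])[min_neighbors])
  }, numeric(1))
  if (anyNA(per_focal)) stop("an arm has fewer than min_neighbors households")
  max(per_focal) * (1 + 1e-9)
}

#' Serialize a GWR surface as CSV
#'
#' @param surface a `gwr_surface`.
#' @param path output CSV path (`cluster_id,x,y,estimate,n_local`).
#' @return invisibly, the path.
#' @export
write_gwr_surface <- function(surface, path) {
  utils::write.csv(surface$surface[, c("cluster_id", "x", "y", "estimate",
                                       "n_local")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
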