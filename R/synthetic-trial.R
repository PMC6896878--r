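# Synthetic cluster-randomized-trial generator: Voronoi cluster geography,
# 1:1 cluster randomization, Gamma household expected deaths, and Poisson
# deaths with intervention, cluster, optional spatial-field and
# distance-decaying spillover effects on the log-SMR scale.

#' Configuration for a synthetic bed-net-style CRT
#'
#' Defaults emulate the motivating trial: 96 contiguous clusters with ~124
#' households each (~12,000 households) over a 30 x 20 km region, balanced
#' 1:1 cluster randomization, an intervention effect of SMR 0.83, a spillover
#' of SMR 1.017 per 100 m of distance to the nearest discordant household
#' attenuating at 400 m, a control-arm baseline SMR of 1.37, and an IID
#' cluster effect with SD 0.2 on the log scale.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param households_per_cluster_mean Poisson mean household count per cluster
#'   (at least one household is placed in every cluster).
#' @param study_extent `c(width, height)` of the rectangular study region, m.
#' @param baseline_expected_mean mean expected deaths per household.
#' @param expected_dispersion Gamma shape for household expected deaths
#'   (larger = less dispersed; the mean is `baseline_expected_mean`).
#' @param baseline_control_smr marginal SMR of control households at the
#'   spillover reference distance (the intercept is calibrated to it,
#'   including the lognormal correction for the cluster effect).
#' @param log_intervention_effect log SMR of intervention vs control beyond
#'   the spillover range (default `log(0.83)`).
#' @param spillover_per_100m log SMR increase per 100 m of discordant
#'   distance (default `log(1.017)`).
#' @param spillover_range_m distance at which the spillover plateaus, m.
#' @param spillover_form `"capped_asymmetric"` (default): control households
#'   get `psi * min(d, R) / 100`, intervention households sit at the plateau
#'   `psi * R / 100`, so the two arms differ by exactly the intervention
#'   effect at and beyond the range and control mortality rises with distance
#'   from the nearest bed net while intervention mortality is flat in
#'   distance. `"linear"`: `psi * d / 100` for every household, no cap — the
#'   generative truth matching the linear-in-distance regression model.
#' @param sigma_cluster SD of the IID Normal cluster effect, log scale.
#' @param spatial_field `"off"`, `"icar"` (cluster-level intrinsic CAR field)
#'   or `"gp"` (household-level exponential-covariance Gaussian field).
#' @param icar_sd marginal-scale SD used to scale the ICAR field.
#' @param gp_sigma,gp_range SD and exponential correlation range (m) of the
#'   Gaussian field (generation is limited to 5,000 households).
#' @param seed integer master seed; all stages derive their streams from it.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_clusters = 96L,
                              households_per_cluster_mean = 124,
                              study_extent = c(30000, 20000),
                              baseline_expected_mean = 0.06,
                              expected_dispersion = 2,
                              baseline_control_smr = 1.37,
                              log_intervention_effect = log(0.83),
                              spillover_per_100m = log(1.017),
                              spillover_range_m = 400,
                              spillover_form = c("capped_asymmetric", "linear"),
                              sigma_cluster = 0.2,
                              spatial_field = c("off", "icar", "gp"),
                              icar_sd = 0.3, gp_sigma = 0.3, gp_range = 1000,
                              seed = 1L) {
  spillover_form <- match.arg(spillover_form)
  spatial_field <- match.arg(spatial_field)
  stopifnot(n_clusters >= 2L, households_per_cluster_mean > 0,
            spillover_range_m >= 0, sigma_cluster >= 0,
            baseline_expected_mean > 0, expected_dispersion > 0,
            icar_sd >= 0, gp_sigma >= 0, gp_range > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 households_per_cluster_mean = households_per_cluster_mean,
                 study_extent = study_extent,
                 baseline_expected_mean = baseline_expected_mean,
                 expected_dispersion = expected_dispersion,
                 baseline_control_smr = baseline_control_smr,
                 log_intervention_effect = log_intervention_effect,
                 spillover_per_100m = spillover_per_100m,
                 spillover_range_m = spillover_range_m,
                 spillover_form = spillover_form,
                 sigma_cluster = sigma_cluster,
                 spatial_field = spatial_field,
                 icar_sd = icar_sd, gp_sigma = gp_sigma, gp_range = gp_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# derived per-stage seeds so adding a stage never perturbs earlier streams
#' @keywords internal
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + offset * 10007) %% 2147483629)
}

#' Generate the cluster geography of a synthetic trial
#'
#' Cluster polygons are the Voronoi tessellation of `n_clusters` random seed
#' points, clipped to the study rectangle — contiguous and space-filling by
#' construction. Household counts are Poisson around the configured mean
#' (minimum one), household locations uniform within their polygon, and arms
#' are a random balanced 1:1 permutation over clusters. Deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `trial_data` object with `observed`/`expected` set to zero
#'   (outcomes are added by [generate_outcomes()]).
#' @export
generate_geography <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  k <- config$n_clusters
  W <- config$study_extent[1L]; H <- config$study_extent[2L]
  pts <- cbind(stats::runif(k, 0, W), stats::runif(k, 0, H))
  # guard against (vanishingly unlikely) coincident seeds
  for (tries in 1:100) {
    d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
    bad <- unique(which(apply(d, 1L, min) < 1e-6))
    if (!length(bad)) break
    pts[bad, ] <- cbind(stats::runif(length(bad), 0, W),
                        stats::runif(length(bad), 0, H))
    message("reseeded ", length(bad), " coincident Voronoi seed(s)")
  }
  cells <- voronoi_cells(pts, c(0, 0, W, H))
  ids <- sprintf("c%03d", seq_len(k))
  names(cells) <- ids
  arm <- sample(rep_len(c(1L, 0L), k))
  counts <- pmax(1L, stats::rpois(k, config$households_per_cluster_mean))
  hh <- do.call(rbind, lapply(seq_len(k), function(i) {
    ring <- cells[[i]][[1L]]
    bb <- c(min(ring[, 1L]), min(ring[, 2L]), max(ring[, 1L]), max(ring[, 2L]))
    n <- counts[i]
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      need <- n - length(xs)
      cx <- stats::runif(2L * need + 10L, bb[1L], bb[3L])
      cy <- stats::runif(2L * need + 10L, bb[2L], bb[4L])
      keep <- points_in_polygon(cx, cy, cells[[i]])
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)],
               cluster_id = ids[i], arm = arm[i])
  }))
  hh <- data.frame(household_id = sprintf("h%05d", seq_len(nrow(hh))), hh,
                   observed = 0L, expected = 0)
  trial_data(hh, data.frame(cluster_id = ids, arm = arm), cells,
             crs_note = "synthetic planar meters", validate = FALSE)
}

#' Generate outcomes for a synthetic trial
#'
#' Household expected deaths are Gamma; the log-linear predictor is
#' `alpha + beta * x_j + u_j + s_h + spill_h` with `u_j` an IID Normal
#' cluster effect, `s_h` an optional spatial field and `spill_h` the
#' configured spillover term in the distance to the nearest discordant
#' household; observed deaths are Poisson with the expected deaths as
#' multiplicative offset. The intercept is calibrated so the control-arm
#' marginal SMR at the spillover reference distance equals
#' `baseline_control_smr`. Deterministic given the config seed.
#'
#' @param trial geography from [generate_geography()].
#' @param config the same [simulation_config()].
#' @return list with `trial` (outcomes filled, `d_discordant` computed) and
#'   `truth` (a `ground_truth` list with every realized parameter and the
#'   per-household linear predictors and Poisson means).
#' @export
generate_outcomes <- function(trial, config) {
  set.seed(derive_seed(config$seed, 2))
  trial <- distance_to_discordant(trial)
  hh <- trial$households
  n <- nrow(hh)
  k <- nrow(trial$clusters)
  shape <- config$expected_dispersion
  expected <- stats::rgamma(n, shape = shape,
                            scale = config$baseline_expected_mean / shape)
  u <- stats::rnorm(k, 0, config$sigma_cluster)
  names(u) <- trial$clusters$cluster_id
  s <- simulate_spatial_field(trial, config)
  psi <- config$spillover_per_100m
  R <- config$spillover_range_m
  beta <- config$log_intervention_effect
  d <- hh$d_discordant
  if (config$spillover_form == "capped_asymmetric") {
    spill <- ifelse(hh$arm == 1L, psi * R / 100, psi * pmin(d, R) / 100)
    ref <- psi * R / 100           # control reference: at/beyond the range
  } else {
    spill <- psi * d / 100
    ref <- 0                       # control reference: distance zero
  }
  alpha <- log(config$baseline_control_smr) - ref - config$sigma_cluster^2 / 2
  eta <- alpha + beta * hh$arm + unname(u[hh$cluster_id]) + s + spill
  mu <- expected * exp(eta)
  trial$households$expected <- expected
  trial$households$observed <- stats::rpois(n, mu)
  truth <- structure(list(alpha = alpha, beta = beta, psi = psi,
                          spillover_range_m = R,
                          spillover_form = config$spillover_form,
                          u = u, s = s, spill = spill,
                          eta = eta, mu = mu, seed = config$seed,
                          config = unclass(config)),
                     class = "ground_truth")
  list(trial = trial, truth = truth)
}

# optional spatial field: cluster-level ICAR (mapped to households) or a
# household-level exponential-covariance Gaussian field
#' @keywords internal
simulate_spatial_field <- function(trial, config) {
  n <- nrow(trial$households)
  if (config$spatial_field == "off") return(numeric(n))
  if (config$spatial_field == "icar") {
    adj <- queen_adjacency(trial)
    L <- diag(rowSums(adj$W)) - adj$W
    e <- eigen(L, symmetric = TRUE)
    pos <- e$values > 1e-8
    z <- stats::rnorm(sum(pos))
    v <- e$vectors[, pos, drop = FALSE] %*% (z / sqrt(e$values[pos]))
    v <- drop(v)
    v <- v / stats::sd(v) * config$icar_sd      # fix the realized scale
    names(v) <- adj$cluster_ids
    return(unname(v[trial$households$cluster_id]))
  }
  if (n > 5000)
    stop("Gaussian-field generation is limited to 5,000 households; ",
         "use a smaller trial or the icar field")
  D <- as.matrix(stats::dist(cbind(trial$households$x, trial$households$y)))
  S <- config$gp_sigma^2 * exp(-D / config$gp_range)
  drop(chol(S + diag(1e-10, n)) %*% stats::rnorm(n))
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper: geography, discordant distances, outcomes.
#'
#' @param config a [simulation_config()].
#' @return list with `trial` and `truth` (see [generate_outcomes()]).
#' @export
simulate_trial <- function(config = simulation_config()) {
  generate_outcomes(generate_geography(config), config)
}

#' Write the realized ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = I(10))
  invisible(path)
}

#' Run a grid of simulation scenarios with model refits
#'
#' For each scenario and replicate: generate a trial, fit the requested SMR
#' models, and collect a tidy row per fitted model and term with the
#' estimate, 95% interval, generative truth, bias and an interval-coverage
#' flag. Individual fit failures are recorded in the table, not fatal.
#'
#' @param configs list of [simulation_config()] objects (a single config is
#'   accepted).
#' @param n_replicates replicates per scenario; replicate seeds are derived
#'   from each scenario's seed.
#' @param specs list of [model_spec()] objects to fit (default: the IID model
#'   and the IID model with the linear discordant-distance term).
#' @return data.frame with columns `scenario`, `replicate`, `model`, `term`,
#'   `estimate`, `lower95`, `upper95`, `truth`, `bias`, `covered`, `error`.
#' @export
scenario_grid <- function(configs, n_replicates = 1L, specs = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L)
  if (is.null(specs))
    specs <- list(iid = model_spec("iid"),
                  iid_distance = model_spec("iid", distance = TRUE))
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$random_structure, "")
  rows <- list()
  for (sc in seq_along(configs)) {
    cfg <- configs[[sc]]
    for (rep in seq_len(n_replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- derive_seed(cfg$seed, 100 + rep)
      sim <- simulate_trial(cfg_r)
      truth_of <- function(term)
        switch(term, x = cfg$log_intervention_effect,
               d100 = cfg$spillover_per_100m, NA_real_)
      for (m in names(specs)) {
        spec <- specs[[m]]
        spec$seed <- cfg_r$seed
        res <- tryCatch(fit_smr_model(sim$trial, spec), error = identity)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc, replicate = rep, model = m, term = NA_character_,
            estimate = NA_real_, lower95 = NA_real_, upper95 = NA_real_,
            truth = NA_real_, bias = NA_real_, covered = NA,
            error = conditionMessage(res))
          next
        }
        co <- res$coefficients
        co <- co[co$term != "(Intercept)", , drop = FALSE]
        for (i in seq_len(nrow(co))) {
          tr <- truth_of(co$term[i])
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc, replicate = rep, model = m, term = co$term[i],
            estimate = co$estimate[i], lower95 = co$lower95[i],
            upper95 = co$upper95[i], truth = tr, bias = co$estimate[i] - tr,
            covered = !is.na(tr) & co$lower95[i] <= tr & tr <= co$upper95[i],
            error = NA_character_)
        }
      }
    }
  }
  do.call(rbind, rows)
}
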