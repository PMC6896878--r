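# Data model for a geographic cluster randomized trial with SMR outcomes:
# one record per household/compound (planar coordinates, cluster membership,
# arm, observed and expected deaths) plus one polygon per cluster.

#' Construct and validate a trial data object
#'
#' The central container for a spatially referenced cluster randomized trial.
#' Households carry planar coordinates in meters, their cluster, the trial arm
#' (1 = intervention, 0 = control), observed deaths and expected deaths (the
#' Poisson offset on the SMR scale). Clusters carry a simple polygon and the
#' arm assigned by randomization.
#'
#' @param households data.frame with columns `household_id`, `x`, `y`,
#'   `cluster_id`, `arm`, `observed`, `expected` and optionally
#'   `d_discordant`.
#' @param clusters data.frame with columns `cluster_id`, `arm`.
#' @param geometry named list (by `cluster_id`) of polygon geometries: each a
#'   list of rings, each ring an n x 2 vertex matrix in meters.
#' @param crs_note free-text note on the coordinate system; coordinates are
#'   assumed planar meters throughout.
#' @param snap_tol tolerance in meters for the household-inside-cluster check;
#'   households further than this from their cluster polygon raise a warning,
#'   not an error (real trial geographies have gaps between clusters).
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return an object of class `trial_data` with elements `households`,
#'   `clusters` (including centroid columns), `geometry` and `crs_note`.
#' @export
trial_data <- function(households, clusters, geometry,
                       crs_note = "planar meters (UTM-like)",
                       snap_tol = 1, validate = TRUE) {
  households <- as.data.frame(households)
  clusters <- as.data.frame(clusters)
  if (!"d_discordant" %in% names(households))
    households$d_discordant <- NA_real_
  households$household_id <- as.character(households$household_id)
  households$cluster_id <- as.character(households$cluster_id)
  clusters$cluster_id <- as.character(clusters$cluster_id)
  cent <- t(vapply(geometry, polygon_centroid, numeric(2)))
  clusters$centroid_x <- cent[match(clusters$cluster_id, names(geometry)), 1L]
  clusters$centroid_y <- cent[match(clusters$cluster_id, names(geometry)), 2L]
  obj <- structure(list(households = households, clusters = clusters,
                        geometry = geometry, crs_note = crs_note),
                   class = "trial_data")
  if (validate) validate_trial_data(obj, snap_tol = snap_tol)
  obj
}

#' @export
print.trial_data <- function(x, ...) {
  hh <- x$households
  cat(sprintf("trial_data: %d households in %d clusters (%d intervention, %d control)\n",
              nrow(hh), nrow(x$clusters),
              sum(x$clusters$arm == 1L), sum(x$clusters$arm == 0L)))
  cat(sprintf("  deaths observed %d / expected %.1f (SMR %.3f); %s\n",
              sum(hh$observed), sum(hh$expected),
              sum(hh$observed) / sum(hh$expected), x$crs_note))
  invisible(x)
}

#' Check the invariants of a trial data object
#'
#' Errors name the first offending record. Household-outside-polygon beyond
#' `snap_tol` is a warning (trial geographies are imperfect); an intervention
#' household inside a control cluster (or vice versa) is an error.
#'
#' @inheritParams trial_data
#' @param trial a `trial_data` object.
#' @return the object, invisibly.
#' @export
validate_trial_data <- function(trial, snap_tol = 1) {
  hh <- trial$households
  cl <- trial$clusters
  need <- c("household_id", "x", "y", "cluster_id", "arm", "observed", "expected")
  miss <- setdiff(need, names(hh))
  if (length(miss))
    stop("households table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(hh$household_id))
    stop("duplicate household_id: ", hh$household_id[duplicated(hh$household_id)][1L])
  if (anyDuplicated(cl$cluster_id))
    stop("duplicate cluster_id: ", cl$cluster_id[duplicated(cl$cluster_id)][1L])
  unknown <- !hh$cluster_id %in% cl$cluster_id
  if (any(unknown))
    stop("household ", hh$household_id[unknown][1L],
         " references unknown cluster_id ", hh$cluster_id[unknown][1L])
  if (!all(cl$arm %in% c(0L, 1L)))
    stop("cluster arm must be 0 or 1 (cluster ",
         cl$cluster_id[!cl$arm %in% c(0L, 1L)][1L], ")")
  if (length(unique(cl$arm)) < 2L)
    stop("both arms must be non-empty at the cluster level")
  arm_of <- cl$arm[match(hh$cluster_id, cl$cluster_id)]
  bad_arm <- hh$arm != arm_of
  if (any(bad_arm))
    stop("household ", hh$household_id[bad_arm][1L],
         " has arm ", hh$arm[bad_arm][1L],
         " but its cluster ", hh$cluster_id[bad_arm][1L],
         " has arm ", arm_of[bad_arm][1L])
  if (any(hh$observed < 0) || any(hh$observed != round(hh$observed)))
    stop("observed deaths must be nonnegative integers (household ",
         hh$household_id[hh$observed < 0 | hh$observed != round(hh$observed)][1L], ")")
  if (any(hh$expected < 0))
    stop("expected deaths must be nonnegative (household ",
         hh$household_id[hh$expected < 0][1L], ")")
  bad_zero <- hh$expected == 0 & hh$observed > 0
  if (any(bad_zero))
    stop("household ", hh$household_id[bad_zero][1L],
         " has observed > 0 with expected = 0")
  if (!setequal(names(trial$geometry), cl$cluster_id))
    stop("geometry list must be named by exactly the cluster ids")
  for (id in cl$cluster_id) {
    g <- trial$geometry[[id]]
    if (polygon_area(g) <= 0)
      stop("cluster ", id, " polygon has nonpositive area")
    if (!ring_is_simple(g[[1L]]))
      stop("cluster ", id, " polygon is self-intersecting")
  }
  # containment check, warning only beyond snap tolerance
  for (id in cl$cluster_id) {
    sel <- hh$cluster_id == id
    if (!any(sel)) next
    d <- points_to_geoms_dist(hh$x[sel], hh$y[sel],
                              trial$geometry[id])$dist
    out <- d > snap_tol
    if (any(out))
      warning(sum(out), " household(s) in cluster ", id,
              " lie further than ", snap_tol,
              " m outside its polygon (first: ",
              hh$household_id[sel][out][1L], ")", call. = FALSE)
  }
  invisible(trial)
}

#' Standardized mortality ratio
#'
#' Observed deaths divided by expected deaths.
#'
#' @param observed_total nonnegative death count.
#' @param expected_total positive expected deaths.
#' @return `observed_total / expected_total`.
#' @examples
#' smr(5, 4)   # 1.25
#' @export
smr <- function(observed_total, expected_total) {
  if (any(expected_total <= 0))
    stop("SMR undefined: expected_total must be > 0")
  observed_total / expected_total
}

#' Distance to the nearest discordant household
#'
#' For every household, the Euclidean distance to the nearest household of
#' the opposite trial arm (the "discordant pair" distance): intervention to
#' nearest control and vice versa.
#'
#' @param trial a `trial_data` object with both arms non-empty.
#' @return the trial with the `d_discordant` household column filled.
#' @export
distance_to_discordant <- function(trial) {
  hh <- trial$households
  a1 <- hh$arm == 1L
  if (!any(a1) || all(a1))
    stop("distance to discordant pair requires both arms non-empty")
  d <- numeric(nrow(hh))
  d[a1] <- cpp_nearest_cross_dist(hh$x[a1], hh$y[a1], hh$x[!a1], hh$y[!a1])
  d[!a1] <- cpp_nearest_cross_dist(hh$x[!a1], hh$y[!a1], hh$x[a1], hh$y[a1])
  trial$households$d_discordant <- d
  trial
}

#' Trial summaries: SMRs by scope and discordant-distance quartiles
#'
#' Computes the standardized mortality ratio overall, per arm and per
#' cluster, plus the median and interquartile range of the distance to the
#' nearest discordant household (overall and among control households).
#' Scopes whose expected deaths are zero are flagged with `NA` SMR rather
#' than dropped.
#'
#' @param trial a `trial_data` object (distances are computed on the fly if
#'   absent).
#' @return list with `smr` (data.frame `scope`, `label`, `observed`,
#'   `expected`, `smr`) and `distance` (data.frame `scope`, `median`, `q25`,
#'   `q75`, meters).
#' @export
summarize_trial <- function(trial) {
  hh <- trial$households
  if (all(is.na(hh$d_discordant)))
    hh$d_discordant <- distance_to_discordant(trial)$households$d_discordant
  one <- function(scope, label, sel) {
    o <- sum(hh$observed[sel]); e <- sum(hh$expected[sel])
    data.frame(scope = scope, label = label, observed = o, expected = e,
               smr = if (e > 0) o / e else NA_real_)
  }
  res <- rbind(
    one("overall", "all", rep(TRUE, nrow(hh))),
    one("arm", "intervention", hh$arm == 1L),
    one("arm", "control", hh$arm == 0L),
    do.call(rbind, lapply(trial$clusters$cluster_id, function(id)
      one("cluster", id, hh$cluster_id == id))))
  if (anyNA(res$smr))
    warning("SMR undefined (expected = 0) for: ",
            paste(res$label[is.na(res$smr)], collapse = ", "), call. = FALSE)
  qs <- function(scope, d) {
    q <- stats::quantile(d, c(.25, .5, .75), names = FALSE)
    data.frame(scope = scope, median = q[2L], q25 = q[1L], q75 = q[3L])
  }
  list(smr = res,
       distance = rbind(qs("overall", hh$d_discordant),
                        qs("control", hh$d_discordant[hh$arm == 0L])))
}

# ---- readers / writers ------------------------------------------------------

#' Read a trial from a households CSV and a clusters GeoJSON
#'
#' The households file must have exactly the header
#' `household_id,x,y,cluster_id,arm,observed,expected` (an optional
#' `d_discordant` column is accepted on re-import). The clusters file is a
#' GeoJSON FeatureCollection of Polygon/MultiPolygon features with properties
#' `cluster_id` and `arm`. Coordinates are planar meters.
#'
#' @param households_path path to the households CSV.
#' @param clusters_path path to the clusters GeoJSON.
#' @param snap_tol containment tolerance in meters (see [trial_data()]).
#' @return a validated `trial_data` object.
#' @export
read_trial <- function(households_path, clusters_path, snap_tol = 1) {
  head1 <- utils::read.csv(households_path, nrows = 1)
  need <- c("household_id", "x", "y", "cluster_id", "arm", "observed", "expected")
  miss <- setdiff(need, names(head1))
  if (length(miss))
    stop("households CSV missing columns: ", paste(miss, collapse = ", "))
  hh <- utils::read.csv(households_path, colClasses = c(
    household_id = "character", cluster_id = "character"))
  gj <- jsonlite::fromJSON(clusters_path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("clusters file is not a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- character(length(feats)); arms <- integer(length(feats))
  geometry <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$properties$cluster_id) || is.null(f$properties$arm))
      stop("GeoJSON feature ", i, " lacks cluster_id/arm properties")
    ids[i] <- as.character(f$properties$cluster_id)
    arms[i] <- as.integer(f$properties$arm)
    geometry[[i]] <- geojson_to_geom(f$geometry)
  }
  names(geometry) <- ids
  trial_data(hh, data.frame(cluster_id = ids, arm = arms),
             geometry, snap_tol = snap_tol)
}

#' Write a trial to a households CSV and a clusters GeoJSON
#'
#' Inverse of [read_trial()]; coordinates round-trip at micrometer precision.
#'
#' @param trial a `trial_data` object.
#' @inheritParams read_trial
#' @return invisibly, the two paths.
#' @export
write_trial <- function(trial, households_path, clusters_path) {
  cols <- c("household_id", "x", "y", "cluster_id", "arm", "observed",
            "expected", "d_discordant")
  utils::write.csv(trial$households[, cols], households_path,
                   row.names = FALSE, quote = FALSE)
  feats <- lapply(trial$clusters$cluster_id, function(id) {
    arm <- trial$clusters$arm[trial$clusters$cluster_id == id]
    list(type = "Feature",
         properties = list(cluster_id = id, arm = as.integer(arm)),
         geometry = geom_to_geojson(trial$geometry[[id]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       clusters_path, auto_unbox = TRUE, digits = I(10))
  invisible(c(households_path, clusters_path))
}

# GeoJSON geometry <-> internal ring list
#' @keywords internal
geojson_to_geom <- function(g) {
  ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    # GeoJSON closes rings; drop the repeated last vertex
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  if (g$type == "Polygon") {
    lapply(g$coordinates, ring)
  } else if (g$type == "MultiPolygon") {
    # flatten parts; even-odd semantics keep disjoint parts and holes correct
    unlist(lapply(g$coordinates, function(part) lapply(part, ring)),
           recursive = FALSE)
  } else stop("unsupported GeoJSON geometry type: ", g$type)
}

#' @keywords internal
geom_to_geojson <- function(geom) {
  list(type = "Polygon",
       coordinates = lapply(geom, function(r) {
         r <- rbind(r, r[1L, ])
         lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
       }))
}

#' Write trial summaries as CSV and JSON
#'
#' @param summaries result of [summarize_trial()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the summaries.
#' @export
write_summaries <- function(summaries, csv_path = NULL, json_path = NULL) {
  tab <- summaries$smr
  names(tab) <- c("scope", "label", "observed", "expected", "smr")
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(summaries, json_path, auto_unbox = TRUE,
                         digits = I(10), dataframe = "rows")
  invisible(summaries)
}
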