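# Cluster contiguity and the dilation geometry behind the reallocation
# diagnostic. Adjacency is Queen's case: two clusters are neighbors if their
# polygons share at least one boundary point (within a snap tolerance).

#' Queen's-case contiguity matrix of the trial clusters
#'
#' Two clusters are adjacent if their polygon boundaries come within
#' `snap_tol` of each other (sharing an edge or a single vertex both count).
#' Polygons are assumed non-overlapping (a tessellation-like geography).
#'
#' @param x a `trial_data` object, or a named list of polygon geometries.
#' @param snap_tol shared-boundary tolerance in meters; the default suits
#'   exact synthetic geometries, raise it for imported ones.
#' @return object of class `queen_adjacency`: list with `cluster_ids` and the
#'   binary symmetric zero-diagonal matrix `W` (dimnames = cluster ids).
#' @export
queen_adjacency <- function(x, snap_tol = 1e-6) {
  geoms <- if (inherits(x, "trial_data")) x$geometry else x
  if (length(geoms) < 2L) stop("need at least 2 clusters")
  ids <- names(geoms)
  k <- length(geoms)
  segs <- lapply(geoms, function(g) do.call(rbind, lapply(g, ring_segments)))
  bbox <- t(vapply(geoms, function(g) {
    v <- do.call(rbind, g)
    c(min(v[, 1L]), min(v[, 2L]), max(v[, 1L]), max(v[, 2L]))
  }, numeric(4)))
  W <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      # bounding-box prefilter (expanded by the tolerance)
      if (bbox[i, 1L] > bbox[j, 3L] + snap_tol ||
          bbox[j, 1L] > bbox[i, 3L] + snap_tol ||
          bbox[i, 2L] > bbox[j, 4L] + snap_tol ||
          bbox[j, 2L] > bbox[i, 4L] + snap_tol) next
      d <- cpp_min_segset_dist(segs[[i]][, 1L], segs[[i]][, 2L],
                               segs[[i]][, 3L], segs[[i]][, 4L],
                               segs[[j]][, 1L], segs[[j]][, 2L],
                               segs[[j]][, 3L], segs[[j]][, 4L])
      if (d <= snap_tol) W[i, j] <- W[j, i] <- 1L
    }
  }
  iso <- ids[rowSums(W) == 0L]
  if (length(iso))
    message("isolated cluster(s) with no neighbors: ",
            paste(iso, collapse = ", "))
  structure(list(cluster_ids = ids, W = W), class = "queen_adjacency")
}

#' @export
print.queen_adjacency <- function(x, ...) {
  cat(sprintf("queen_adjacency: %d clusters, %d adjacent pairs\n",
              length(x$cluster_ids), sum(x$W) / 2))
  invisible(x)
}

#' Restrict an adjacency matrix to a subset of clusters
#'
#' Returns the induced subgraph: contiguity is never re-established through
#' removed clusters.
#'
#' @param adj a `queen_adjacency` object.
#' @param keep character vector of cluster ids to retain.
#' @return a `queen_adjacency` over `keep` (in `adj`'s order).
#' @export
subset_adjacency <- function(adj, keep) {
  unknown <- setdiff(keep, adj$cluster_ids)
  if (length(unknown))
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  ids <- adj$cluster_ids[adj$cluster_ids %in% keep]
  structure(list(cluster_ids = ids, W = adj$W[ids, ids, drop = FALSE]),
            class = "queen_adjacency")
}

#' Adjacency as an edge list
#'
#' @param adj a `queen_adjacency` object.
#' @param path optional CSV output path (`cluster_a,cluster_b`).
#' @return data.frame of unordered adjacent pairs.
#' @export
adjacency_edges <- function(adj, path = NULL) {
  idx <- which(upper.tri(adj$W) & adj$W == 1L, arr.ind = TRUE)
  out <- data.frame(cluster_a = adj$cluster_ids[idx[, 1L]],
                    cluster_b = adj$cluster_ids[idx[, 2L]])
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Dilate one arm's clusters and reassign engulfed households
#'
#' The union of the dilated arm's polygons is expanded outward by `buffer_m`
#' (Euclidean dilation with round joins, which makes membership of the
#' buffered union identical to "point-to-union distance at most the buffer");
#' every opposite-arm household inside the expanded union is reassigned to
#' the dilated arm. Households of the dilated arm never change, and the
#' reassigned set grows monotonically with the buffer. At buffer 0 the
#' original assignment is returned unchanged.
#'
#' Reassigned households are grouped under pseudo-clusters named
#' `realloc_<arm>_<buffer>_<nearest cluster>` after the nearest original
#' cluster of the dilated arm, so cluster random effects stay definable
#' after reallocation.
#'
#' @param trial a `trial_data` object.
#' @param dilated_arm 0 or 1: the arm whose clusters are dilated.
#' @param buffer_m nonnegative dilation distance in meters.
#' @return object of class `dilated_assignment`: list with `buffer_m`,
#'   `dilated_arm`, `reassigned_ids`, `degenerate` (TRUE when an arm is
#'   emptied) and `assignment`, a data.frame with columns `household_id`,
#'   `original_arm`, `assigned_arm`, `cluster_after`, `buffer_m`.
#' @export
dilate_and_reassign <- function(trial, dilated_arm, buffer_m) {
  stopifnot(buffer_m >= 0, dilated_arm %in% c(0L, 1L))
  hh <- trial$households
  out <- data.frame(household_id = hh$household_id,
                    original_arm = hh$arm,
                    assigned_arm = hh$arm,
                    cluster_after = hh$cluster_id,
                    buffer_m = buffer_m)
  reassigned <- character(0)
  if (buffer_m > 0) {
    dil_ids <- trial$clusters$cluster_id[trial$clusters$arm == dilated_arm]
    opp <- hh$arm != dilated_arm
    pd <- points_to_geoms_dist(hh$x[opp], hh$y[opp],
                               trial$geometry[dil_ids])
    inside <- pd$dist <= buffer_m
    if (any(inside)) {
      idx <- which(opp)[inside]
      nearest <- dil_ids[pd$which[inside]]
      out$assigned_arm[idx] <- dilated_arm
      out$cluster_after[idx] <- sprintf("realloc_%d_%g_%s", dilated_arm,
                                        buffer_m, nearest)
      reassigned <- hh$household_id[idx]
    }
  }
  degenerate <- length(unique(out$assigned_arm)) < 2L
  structure(list(buffer_m = buffer_m, dilated_arm = as.integer(dilated_arm),
                 reassigned_ids = reassigned, degenerate = degenerate,
                 assignment = out),
            class = "dilated_assignment")
}

#' Apply a dilated assignment to a trial
#'
#' Builds the reallocated trial used for refitting: households take their
#' post-dilation arm and (pseudo-)cluster; pseudo-clusters inherit the arm of
#' the dilated side and the geometry of their parent cluster.
#'
#' @param trial the original `trial_data`.
#' @param da a `dilated_assignment` from [dilate_and_reassign()].
#' @return a `trial_data` object (not re-validated: reassigned households
#'   intentionally lie outside their pseudo-cluster's parent polygon).
#' @export
apply_reassignment <- function(trial, da) {
  if (da$degenerate)
    stop("degenerate assignment: one arm is empty after reallocation")
  hh <- trial$households
  asg <- da$assignment
  stopifnot(identical(hh$household_id, asg$household_id))
  hh$arm <- asg$assigned_arm
  hh$cluster_id <- asg$cluster_after
  cl <- trial$clusters[, c("cluster_id", "arm")]
  new_ids <- setdiff(unique(asg$cluster_after), cl$cluster_id)
  geom <- trial$geometry
  if (length(new_ids)) {
    parent <- sub("^realloc_[01]_[^_]*_", "", new_ids)
    cl <- rbind(cl, data.frame(cluster_id = new_ids,
                               arm = as.integer(da$dilated_arm)))
    for (i in seq_along(new_ids)) geom[[new_ids[i]]] <- geom[[parent[i]]]
  }
  trial_data(hh, cl, geom, crs_note = trial$crs_note, validate = FALSE)
}

#' Serialize a dilated assignment as CSV
#'
#' @param da a `dilated_assignment`.
#' @param path output CSV path
#'   (`household_id,original_arm,assigned_arm,buffer_m`).
#' @return invisibly, the path.
#' @export
write_assignment <- function(da, path) {
  utils::write.csv(da$assignment[, c("household_id", "original_arm",
                                     "assigned_arm", "buffer_m")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
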