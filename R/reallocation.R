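# The cluster-reallocation diagnostic: dilate one arm's cluster boundaries
# stepwise, reassign the opposite-arm households that fall inside, refit the
# trial model at every step, and read spillover off the estimate-vs-buffer
# curve. Without spillover the estimates should attenuate toward the null as
# the arms are diluted; with spillover, dilating the intervention arm should
# strengthen the estimate over the functional distance of the spillover.

#' Reallocation sweep over dilation buffers
#'
#' For each arm and buffer: dilate that arm's cluster polygons, reassign the
#' engulfed opposite-arm households (grouping them under pseudo-clusters by
#' their nearest dilated cluster so the cluster random effect stays
#' defined), refit the model, and record the intervention SMR with its 95%
#' interval and the post-reassignment arm sizes. The buffer-0 rows reproduce
#' the base fit exactly. Steps that leave either arm below `min_arm`
#' households are flagged degenerate and not fitted.
#'
#' @param trial a `trial_data` object.
#' @param spec the [model_spec()] used for the base fit and every refit.
#' @param buffers dilation grid in meters (default 0 to 1,000 by 100).
#' @param arms which arms to dilate (default both, independently).
#' @param min_arm minimum households per arm for a refit.
#' @param adj optional `queen_adjacency` (only relevant for car/bym specs;
#'   pseudo-clusters make those refits ill-defined, so the iid spec is the
#'   intended companion).
#' @return object of class `reallocation_curve`: a data.frame with columns
#'   `dilated_arm`, `buffer_m`, `n_intervention`, `n_control`,
#'   `n_reassigned`, `smr`, `lower95`, `upper95`, `degenerate`; the spec and
#'   base fit are attached as attributes.
#' @export
reallocation_sweep <- function(trial, spec = model_spec(),
                               buffers = seq(0, 1000, by = 100),
                               arms = c(0L, 1L), min_arm = 30L, adj = NULL) {
  stopifnot(all(buffers >= 0))
  base <- fit_smr_model(trial, spec, adj)
  if (!base$diagnostics$converged)
    stop("base fit did not converge; aborting the sweep")
  base_row <- base$smr_table[base$smr_table$term == "x", ]
  rows <- list()
  for (arm in arms) {
    for (b in sort(buffers)) {
      if (b == 0) {
        n1 <- sum(trial$households$arm == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          dilated_arm = arm, buffer_m = 0,
          n_intervention = n1,
          n_control = nrow(trial$households) - n1, n_reassigned = 0L,
          smr = base_row$smr, lower95 = base_row$lower95,
          upper95 = base_row$upper95, degenerate = FALSE)
        next
      }
      da <- dilate_and_reassign(trial, arm, b)
      n1 <- sum(da$assignment$assigned_arm == 1L)
      n0 <- sum(da$assignment$assigned_arm == 0L)
      degenerate <- da$degenerate || min(n1, n0) < min_arm
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          dilated_arm = arm, buffer_m = b, n_intervention = n1,
          n_control = n0, n_reassigned = length(da$reassigned_ids),
          smr = NA_real_, lower95 = NA_real_, upper95 = NA_real_,
          degenerate = TRUE)
        next
      }
      refit <- fit_smr_model(apply_reassignment(trial, da), spec)
      r <- refit$smr_table[refit$smr_table$term == "x", ]
      rows[[length(rows) + 1L]] <- data.frame(
        dilated_arm = arm, buffer_m = b, n_intervention = n1,
        n_control = n0, n_reassigned = length(da$reassigned_ids),
        smr = r$smr, lower95 = r$lower95, upper95 = r$upper95,
        degenerate = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  structure(curve, class = c("reallocation_curve", "data.frame"),
            spec = spec, base_fit = base)
}

#' Summarize a reallocation curve
#'
#' Per dilated arm: the mean, minimum and maximum of the intervention SMR
#' estimates over the non-degenerate buffers greater than zero, next to the
#' buffer-0 (original cluster definition) estimate.
#'
#' @param curve a `reallocation_curve`.
#' @return data.frame with columns `dilated_arm`, `buffer0`, `mean`, `min`,
#'   `max`, `n_steps`.
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "reallocation_curve") || is.data.frame(curve))
  out <- lapply(sort(unique(curve$dilated_arm)), function(arm) {
    sub <- curve[curve$dilated_arm == arm, ]
    est <- sub$smr[sub$buffer_m > 0 & !sub$degenerate]
    if (!length(est))
      stop("all positive-buffer steps degenerate for dilated arm ", arm)
    b0 <- sub$smr[sub$buffer_m == 0]
    data.frame(dilated_arm = arm,
               buffer0 = if (length(b0)) b0[1L] else NA_real_,
               mean = mean(est), min = min(est), max = max(est),
               n_steps = length(est))
  })
  do.call(rbind, out)
}

#' @export
print.reallocation_curve <- function(x, ...) {
  cat("reallocation curve:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a reallocation curve
#'
#' Intervention SMR (with per-refit 95% intervals) against the dilation
#' buffer, one panel line per dilated arm.
#'
#' @param x a `reallocation_curve`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the curve.
#' @export
plot.reallocation_curve <- function(x, ...) {
  ok <- !x$degenerate
  ylim <- range(x$lower95[ok], x$upper95[ok], 1, na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$buffer_m), ylim = ylim,
                 xlab = "dilation buffer (m)", ylab = "intervention SMR", ...)
  graphics::abline(h = 1, lty = 3)
  cols <- c(`0` = "#1b6ca8", `1` = "#c0392b")
  for (arm in unique(x$dilated_arm)) {
    sub <- x[x$dilated_arm == arm & !x$degenerate, ]
    graphics::lines(sub$buffer_m, sub$smr, type = "b", pch = 16,
                    col = cols[as.character(arm)])
    graphics::arrows(sub$buffer_m, sub$lower95, sub$buffer_m, sub$upper95,
                     angle = 90, code = 3, length = 0.03,
                     col = cols[as.character(arm)])
  }
  graphics::legend("topleft", bty = "n", lty = 1, pch = 16, col = cols,
                   legend = c("control dilated", "intervention dilated"))
  invisible(x)
}

#' Serialize a reallocation curve as CSV
#'
#' @param curve a `reallocation_curve`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_curve <- function(curve, path) {
  cols <- c("dilated_arm", "buffer_m", "n_intervention", "n_control",
            "smr", "lower95", "upper95", "degenerate")
  utils::write.csv(as.data.frame(curve)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
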