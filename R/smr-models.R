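# Poisson SMR models of the trial: IID, intrinsic CAR, BYM and Gaussian-
# process random structures, optionally with discordant-distance terms;
# the spillover interaction analysis; and the parametric bootstrap.

#' Specify an SMR model
#'
#' The linear predictor on the log-SMR scale is
#' `alpha + beta * x [+ psi * d/100] [+ psi2 * (d/100)^2] [+ gamma * far]
#' [+ delta * x * far]` plus the chosen random structure, where `x` is the
#' intervention indicator, `d` the distance to the nearest discordant
#' household and `far = 1[d > threshold_m]`.
#'
#' @param random_structure `"iid"` (Normal cluster intercept), `"car"`
#'   (intrinsic CAR on the cluster contiguity graph; fitted to
#'   cluster-aggregated counts), `"bym"` (IID + intrinsic CAR) or `"gp"`
#'   (IID cluster effect plus a household-level exponential-covariance
#'   Gaussian field, evaluated densely).
#' @param intervention include the intervention fixed effect (default TRUE).
#' @param distance include the linear discordant-distance term (per 100 m).
#' @param distance_quadratic also include the squared term (same scaling).
#' @param threshold_m if non-NULL, include the binary far-side indicator
#'   `1[d > threshold_m]` (the spillover attenuation threshold, typically
#'   400 m).
#' @param interaction include the intervention x far-side interaction
#'   (requires `threshold_m`).
#' @param inference `"laplace_map"`: joint-mode Newton plus Laplace marginal
#'   maximization with Wald 95% intervals (the package's engine).
#' @param gp_cap maximum households entering a dense GP fit; larger trials
#'   are subsampled reproducibly.
#' @param seed integer seed (used for the GP subsample).
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(random_structure = c("iid", "car", "bym", "gp"),
                       intervention = TRUE, distance = FALSE,
                       distance_quadratic = FALSE, threshold_m = NULL,
                       interaction = FALSE,
                       inference = c("laplace_map", "bayes_mcmc"),
                       gp_cap = 3000L, seed = 1L) {
  random_structure <- match.arg(random_structure)
  inference <- match.arg(inference)
  if (interaction && is.null(threshold_m))
    stop("interaction requires threshold_m")
  if (distance_quadratic && !distance)
    stop("distance_quadratic requires distance")
  structure(list(random_structure = random_structure,
                 intervention = intervention, distance = distance,
                 distance_quadratic = distance_quadratic,
                 threshold_m = threshold_m, interaction = interaction,
                 inference = inference, gp_cap = as.integer(gp_cap),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @keywords internal
needs_distance <- function(spec)
  spec$distance || spec$distance_quadratic || !is.null(spec$threshold_m)

# fixed-effects design matrix for a household table under a spec
#' @keywords internal
build_design <- function(hh, spec) {
  X <- cbind("(Intercept)" = rep(1, nrow(hh)))
  if (spec$intervention) X <- cbind(X, x = hh$arm)
  if (spec$distance) X <- cbind(X, d100 = hh$d_discordant / 100)
  if (spec$distance_quadratic)
    X <- cbind(X, d100_sq = (hh$d_discordant / 100)^2)
  if (!is.null(spec$threshold_m)) {
    far <- as.numeric(hh$d_discordant > spec$threshold_m)
    X <- cbind(X, far = far)
    if (spec$interaction) X <- cbind(X, "x:far" = hh$arm * far)
  }
  X
}

#' Fit an SMR model to a trial
#'
#' Poisson likelihood with the household expected deaths as offset, fitted
#' with the Laplace/penalized-likelihood engine. Households with zero
#' expected deaths are excluded from the likelihood (a message gives the
#' count). The CAR model is fitted to cluster-aggregated counts (one
#' observation per area); models without household-level covariates are also
#' aggregated to clusters, which leaves the likelihood — and hence the
#' estimates — unchanged. GP fits beyond `gp_cap` households use a seeded
#' subsample.
#'
#' @param trial a `trial_data` object; discordant distances are computed on
#'   demand when a distance term is requested.
#' @param spec a [model_spec()].
#' @param adj a `queen_adjacency`, required by `car`/`bym`; computed from the
#'   trial geometry when omitted.
#' @return object of class `smr_fit`: `coefficients` (log scale, with Wald
#'   95% intervals), `smr_table` (exp-transformed), `varcomp`, per-household
#'   `fitted` means, `random_effects`, `loglik_laplace`, `vcov_fixed`,
#'   `diagnostics` (with a `converged` flag — non-convergence is flagged,
#'   not silent) and bookkeeping fields.
#' @export
fit_smr_model <- function(trial, spec = model_spec(), adj = NULL) {
  if (spec$inference == "bayes_mcmc")
    stop("inference = 'bayes_mcmc' is not provided by this package; ",
         "use the 'laplace_map' engine")
  hh_all <- trial$households
  if (needs_distance(spec) && anyNA(hh_all$d_discordant)) {
    trial <- distance_to_discordant(trial)
    hh_all <- trial$households
  }
  excl <- hh_all$expected <= 0
  if (any(excl))
    message(sum(excl), " household(s) with expected = 0 excluded from the likelihood")
  hh <- hh_all[!excl, , drop = FALSE]
  if (length(unique(hh$arm)) < 2L)
    stop("degenerate arm assignment: refusing to fit with a single arm")
  cl_ids <- sort(unique(hh$cluster_id))

  struct <- spec$random_structure
  if (struct %in% c("car", "bym")) {
    if (is.null(adj)) {
      if (!setequal(names(trial$geometry), cl_ids))
        stop("'", struct, "' needs an adjacency matrix over the data clusters")
      adj <- queen_adjacency(trial)
    }
    if (!setequal(adj$cluster_ids, cl_ids))
      stop("adjacency clusters do not match the trial clusters")
    adj <- subset_adjacency(adj, cl_ids)  # fixes ordering
    cl_ids <- adj$cluster_ids
  }

  household_covars <- needs_distance(spec)
  aggregate <- struct == "car" || (!household_covars && struct != "gp")
  data_level <- if (aggregate) "cluster" else "household"
  if (aggregate) {
    agg <- aggregate_households(hh, cl_ids, spec)
    y <- agg$y; E <- agg$E; X <- agg$X; cluster <- agg$cluster
  } else {
    y <- hh$observed; E <- hh$expected
    X <- build_design(hh, spec); cluster <- hh$cluster_id
  }

  sub_idx <- NULL
  if (struct == "gp" && length(y) > spec$gp_cap) {
    set.seed(derive_seed(spec$seed, 77))
    sub_idx <- sort(sample.int(length(y), spec$gp_cap))
    message("GP fit subsampled to ", spec$gp_cap, " of ", length(y),
            " households")
    y <- y[sub_idx]; E <- E[sub_idx]
    X <- X[sub_idx, , drop = FALSE]; cluster <- cluster[sub_idx]
    cl_ids <- sort(unique(cluster))
  }

  structure_obj <- switch(struct,
    iid = structure_iid(cluster, cl_ids),
    car = structure_car(cluster, cl_ids, adj),
    bym = structure_bym(cluster, cl_ids, adj),
    gp = {
      rows <- if (aggregate) stop("gp is household-level") else hh
      if (!is.null(sub_idx)) rows <- rows[sub_idx, , drop = FALSE]
      structure_gp(cluster, cl_ids, cbind(rows$x, rows$y))
    })

  fit <- laplace_fit(y, E, X, structure_obj)
  if (!fit$converged)
    warning("model fit flagged as non-converged (grad_norm = ",
            signif(fit$diagnostics$grad_norm, 3), ")", call. = FALSE)

  est <- fit$beta; se <- fit$se_beta
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      lower95 = unname(est - 1.96 * se),
                      upper95 = unname(est + 1.96 * se))
  smr_tab <- data.frame(term = coefs$term, smr = exp(coefs$estimate),
                        lower95 = exp(coefs$lower95),
                        upper95 = exp(coefs$upper95))
  re <- structure_obj$map_effects(fit$b)

  fitted <- fitted_household_means(hh_all, excl, spec, est, re, struct,
                                   if (!aggregate) sub_idx else NULL,
                                   fit, hh)

  structure(list(spec = spec, coefficients = coefs, smr_table = smr_tab,
                 varcomp = fit$varcomp, fitted = fitted,
                 random_effects = re, theta = fit$theta,
                 loglik_laplace = fit$loglik_laplace,
                 vcov_fixed = fit$vcov_beta,
                 diagnostics = c(fit$diagnostics,
                                 list(converged = fit$converged)),
                 data_level = data_level, n_used = length(y),
                 n_excluded_zero_expected = sum(excl),
                 engine = spec$inference, seed = spec$seed),
            class = "smr_fit")
}

# cluster aggregation; household covariates (distance terms) use expected-
# death-weighted cluster means (exact sufficiency holds only without them)
#' @keywords internal
aggregate_households <- function(hh, cl_ids, spec) {
  Xh <- build_design(hh, spec)
  y <- as.numeric(tapply(hh$observed, hh$cluster_id, sum)[cl_ids])
  E <- as.numeric(tapply(hh$expected, hh$cluster_id, sum)[cl_ids])
  X <- do.call(rbind, lapply(cl_ids, function(id) {
    sel <- hh$cluster_id == id
    w <- hh$expected[sel] / sum(hh$expected[sel])
    colSums(Xh[sel, , drop = FALSE] * w)
  }))
  colnames(X) <- colnames(Xh)
  list(y = y, E = E, X = X, cluster = cl_ids)
}

# per-household fitted Poisson means on the original table (NA where not
# computable: zero-expected rows, or households outside a GP subsample)
#' @keywords internal
fitted_household_means <- function(hh_all, excl, spec, est, re, struct,
                                   sub_idx, fit, hh) {
  fitted <- rep(NA_real_, nrow(hh_all))
  names(fitted) <- hh_all$household_id
  if (struct == "gp") {
    rows <- if (is.null(sub_idx)) hh else hh[sub_idx, , drop = FALSE]
    fitted[rows$household_id] <- fit$mu
    return(fitted)
  }
  ok <- !excl
  Xh <- build_design(hh_all[ok, , drop = FALSE], spec)
  eta <- as.numeric(Xh %*% est)
  cl <- hh_all$cluster_id[ok]
  if (!is.null(re$u)) eta <- eta + re$u[cl]
  if (!is.null(re$v)) eta <- eta + re$v[cl]
  fitted[hh_all$household_id[ok]] <- hh_all$expected[ok] * exp(eta)
  fitted
}

#' @export
print.smr_fit <- function(x, ...) {
  cat(sprintf("SMR model (%s, %s engine, %s-level, n = %d)%s\n",
              x$spec$random_structure, x$engine, x$data_level, x$n_used,
              if (x$diagnostics$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$smr_table
  tab$smr <- sprintf("%.3f", tab$smr)
  tab$ci <- sprintf("(%.3f-%.3f)", x$smr_table$lower95, x$smr_table$upper95)
  print(tab[, c("term", "smr", "ci")], row.names = FALSE)
  vc <- unlist(x$varcomp)
  cat("variance components:",
      paste(names(vc), signif(vc, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fit as a flat CSV row set and JSON
#'
#' @param fit an `smr_fit`.
#' @param csv_path,json_path output paths (`NULL` to skip). The CSV has
#'   columns `model,term,smr,lower95,upper95`.
#' @param model_label label for the CSV `model` column.
#' @return invisibly, the fit.
#' @export
write_fit <- function(fit, csv_path = NULL, json_path = NULL,
                      model_label = fit$spec$random_structure) {
  if (!is.null(csv_path)) {
    tab <- cbind(model = model_label, fit$smr_table)
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(
      list(model = model_label, coefficients = fit$coefficients,
           smr_table = fit$smr_table, varcomp = fit$varcomp,
           diagnostics = fit$diagnostics, seed = fit$seed),
      json_path, auto_unbox = TRUE, digits = I(10), dataframe = "rows")
  invisible(fit)
}

#' Spillover model: SMR model with the discordant-distance term
#'
#' Thin wrapper over [fit_smr_model()] that switches on the linear (and
#' optionally quadratic) distance-per-100 m term, so the reported
#' `exp(psi)` is the SMR multiplier per additional 100 m of distance to the
#' nearest discordant household.
#'
#' @inheritParams fit_smr_model
#' @param quadratic also include the squared distance term.
#' @return an `smr_fit`.
#' @export
spillover_fit <- function(trial, spec = model_spec(), adj = NULL,
                          quadratic = FALSE) {
  spec$distance <- TRUE
  if (quadratic) spec$distance_quadratic <- TRUE
  fit_smr_model(trial, spec, adj)
}

#' Interaction of the intervention with the distance threshold
#'
#' Fits the IID model with the intervention indicator, the binary far-side
#' indicator `1[d > threshold]` and their interaction, tests the interaction
#' globally with a likelihood-ratio test (on the Laplace marginal
#' likelihood), and lays out the four stratum-specific SMR contrasts in both
#' directions of conditioning, with reference categories at SMR 1.00 by
#' construction.
#'
#' @param trial a `trial_data` object.
#' @param threshold_m distance threshold in meters (default 400, where the
#'   spillover appears to attenuate).
#' @param spec base [model_spec()] (its distance flags are overridden).
#' @return object of class `stratum_smr`: `table` (columns `conditioning`,
#'   `stratum`, `group`, `smr`, `lower95`, `upper95`), `interaction_p`,
#'   `threshold_m`, and the underlying full/reduced fits.
#' @export
interaction_analysis <- function(trial, threshold_m = 400,
                                 spec = model_spec()) {
  spec$distance <- FALSE; spec$distance_quadratic <- FALSE
  spec$threshold_m <- threshold_m
  if (anyNA(trial$households$d_discordant))
    trial <- distance_to_discordant(trial)
  d <- trial$households$d_discordant[trial$households$expected > 0]
  x <- trial$households$arm[trial$households$expected > 0]
  far <- d > threshold_m
  strata_n <- table(factor(x, c(0, 1)), factor(far, c(FALSE, TRUE)))
  if (any(strata_n == 0))
    stop("empty stratum: arm ", rownames(strata_n)[which(strata_n == 0,
         arr.ind = TRUE)[1L, 1L]], ", far = ",
         colnames(strata_n)[which(strata_n == 0, arr.ind = TRUE)[1L, 2L]])
  spec_red <- spec; spec_red$interaction <- FALSE
  spec_full <- spec; spec_full$interaction <- TRUE
  fit_red <- fit_smr_model(trial, spec_red)
  fit_full <- fit_smr_model(trial, spec_full)
  lrt <- 2 * (fit_full$loglik_laplace - fit_red$loglik_laplace)
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)

  be <- fit_full$coefficients$estimate
  names(be) <- fit_full$coefficients$term
  V <- fit_full$vcov_fixed
  contrast <- function(w) {
    est <- -sum(w * be[names(w)])
    se <- sqrt(drop(t(w) %*% V[names(w), names(w)] %*% w))
    c(exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se))
  }
  ref <- c(1, NA, NA)
  rows <- rbind(
    # conditioning on distance stratum, contrasting arms (bed nets = ref)
    c400_bn   = ref,
    c400_none = contrast(c(x = 1)),
    cfar_bn   = ref,
    cfar_none = contrast(c(x = 1, "x:far" = 1)),
    # conditioning on arm, contrasting distance strata (further = ref)
    bn_far    = ref,
    bn_near   = contrast(c(far = 1, "x:far" = 1)),
    none_far  = ref,
    none_near = contrast(c(far = 1)))
  tab <- data.frame(
    conditioning = rep(c("distance", "arm"), each = 4L),
    stratum = c(sprintf("%g m or nearer", threshold_m),
                sprintf("%g m or nearer", threshold_m),
                sprintf("further than %g m", threshold_m),
                sprintf("further than %g m", threshold_m),
                "bed nets", "bed nets", "no bed nets", "no bed nets"),
    group = c("bed nets", "no bed nets", "bed nets", "no bed nets",
              sprintf("further than %g m", threshold_m),
              sprintf("%g m or nearer", threshold_m),
              sprintf("further than %g m", threshold_m),
              sprintf("%g m or nearer", threshold_m)),
    smr = rows[, 1L], lower95 = rows[, 2L], upper95 = rows[, 3L],
    row.names = NULL)
  structure(list(table = tab, interaction_p = p, threshold_m = threshold_m,
                 fit_full = fit_full, fit_reduced = fit_red),
            class = "stratum_smr")
}

#' @export
print.stratum_smr <- function(x, ...) {
  cat(sprintf("Stratum-specific SMRs (threshold %g m); global interaction P = %.3f\n",
              x$threshold_m, x$interaction_p))
  tab <- x$table
  tab$smr <- ifelse(is.na(tab$lower95), sprintf("%.2f", tab$smr),
                    sprintf("%.2f (%.2f-%.2f)", tab$smr, tab$lower95,
                            tab$upper95))
  print(tab[, c("conditioning", "stratum", "group", "smr")],
        row.names = FALSE)
  invisible(x)
}

#' Parametric bootstrap of a fitted SMR model
#'
#' Simulates outcome counts from the fitted model — Poisson means rebuilt
#' from the fixed-effect estimates with freshly re-drawn random effects from
#' their estimated distribution — refits the model to each sample, and
#' reports the percentile 95% interval of the chosen coefficient.
#'
#' @param trial the `trial_data` the base model was fitted to.
#' @param spec the [model_spec()] to fit (must converge on the base data).
#' @param n_boot bootstrap samples (2,000 for production; a few hundred is
#'   adequate for testing).
#' @param seed integer seed.
#' @param term coefficient to track (default the distance term when present,
#'   otherwise the intervention effect).
#' @param adj optional `queen_adjacency` passed through to the refits.
#' @return object of class `smr_bootstrap`: `draws` (log scale), `smr_ci`
#'   (percentile 95% on the SMR scale), `base_estimate`, failure counts and
#'   a `flagged` field (TRUE for degenerate zero-width intervals or > 5%
#'   refit failures).
#' @export
parametric_bootstrap <- function(trial, spec = model_spec(distance = TRUE),
                                 n_boot = 2000L, seed = 1L, term = NULL,
                                 adj = NULL) {
  if (needs_distance(spec) && anyNA(trial$households$d_discordant))
    trial <- distance_to_discordant(trial)
  base <- fit_smr_model(trial, spec, adj)
  if (!base$diagnostics$converged)
    stop("base fit did not converge; refusing to bootstrap")
  if (is.null(term)) term <- if (spec$distance) "d100" else "x"
  if (!term %in% base$coefficients$term)
    stop("term '", term, "' not in the fitted model")
  hh <- trial$households[trial$households$expected > 0, , drop = FALSE]
  est <- base$coefficients$estimate
  names(est) <- base$coefficients$term
  Xh <- build_design(hh, spec)
  eta_fix <- as.numeric(Xh %*% est[colnames(Xh)])
  cl_ids <- sort(unique(hh$cluster_id))
  sigma_u <- base$varcomp$sigma_u
  if (is.null(sigma_u))
    stop("parametric bootstrap requires a structure with an IID cluster ",
         "effect (iid, bym or gp)")
  draw_extra <- function() numeric(nrow(hh))
  if (!is.null(base$varcomp$tau_v) || !is.null(base$varcomp$gp_sigma))
    stop("parametric bootstrap is implemented for the iid structure")
  set.seed(derive_seed(seed, 3))
  draws <- rep(NA_real_, n_boot)
  n_failed <- 0L
  trial_b <- trial
  for (b in seq_len(n_boot)) {
    u <- stats::rnorm(length(cl_ids), 0, sigma_u)
    names(u) <- cl_ids
    mu <- hh$expected * exp(eta_fix + u[hh$cluster_id] + draw_extra())
    yb <- stats::rpois(nrow(hh), mu)
    hb <- trial$households
    hb$observed[match(hh$household_id, hb$household_id)] <- yb
    trial_b$households <- hb
    fb <- tryCatch(suppressMessages(fit_smr_model(trial_b, spec, adj)),
                   error = identity)
    if (inherits(fb, "error") || !fb$diagnostics$converged) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b] <- fb$coefficients$estimate[fb$coefficients$term == term]
  }
  ok <- draws[!is.na(draws)]
  ci <- stats::quantile(ok, c(.025, .975), names = FALSE)
  flagged <- n_failed > 0.05 * n_boot || diff(ci) <= 0
  if (flagged)
    warning("bootstrap flagged: ", n_failed, "/", n_boot,
            " refit failures or degenerate interval", call. = FALSE)
  structure(list(term = term, draws = draws,
                 base_estimate = unname(est[term]),
                 boot_mean = mean(ok),
                 smr_estimate = exp(mean(ok)),
                 smr_ci = exp(ci), n_boot = n_boot, n_failed = n_failed,
                 flagged = flagged, seed = seed),
            class = "smr_bootstrap")
}

#' @export
print.smr_bootstrap <- function(x, ...) {
  cat(sprintf("parametric bootstrap of '%s': SMR %.3f (95%% CI %.3f-%.3f), %d samples (%d failed)%s\n",
              x$term, x$smr_estimate, x$smr_ci[1L], x$smr_ci[2L],
              x$n_boot, x$n_failed, if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}
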