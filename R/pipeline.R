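# End-to-end orchestration of the three-part analysis: (1) exploratory
# spatial statistics, (2) spatial SMR models, (3) distance-based spillover
# and interaction — on either an imported trial or a synthetic one, with a
# deterministic seed per stage and a persisted report bundle.

#' Configuration for a full pipeline run
#'
#' Exactly one of (`households_path` + `clusters_path`) or `sim_config` must
#' be supplied. Stage seeds are derived from the master seed by fixed
#' offsets, so adding a stage never perturbs earlier stages' streams; the
#' resolved configuration (including every stage seed) is written alongside
#' the outputs as `config_resolved.json`.
#'
#' @param households_path,clusters_path input files (see [read_trial()]).
#' @param sim_config a [simulation_config()] for a synthetic run.
#' @param out_dir output directory (created if needed).
#' @param n_sim permutations for the Monte Carlo tests.
#' @param gwr_bandwidth_m GWR radius in meters; `NULL` picks the smallest
#'   radius giving every focal cluster both arms ([gwr_bandwidth()]).
#' @param realloc_buffers dilation grid for the reallocation sweep, meters.
#' @param threshold_m distance threshold of the interaction analysis.
#' @param n_boot parametric bootstrap samples.
#' @param gp_cap household cap for the dense GP fits.
#' @param models random structures fitted with and without the distance
#'   term for the model-comparison table.
#' @param seed master seed.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(households_path = NULL, clusters_path = NULL,
                            sim_config = NULL, out_dir = tempfile("netspill_"),
                            n_sim = 999L, gwr_bandwidth_m = NULL,
                            realloc_buffers = seq(0, 1000, by = 100),
                            threshold_m = 400, n_boot = 200L,
                            gp_cap = 1000L,
                            models = c("iid", "car", "bym", "gp"),
                            seed = 1L) {
  from_files <- !is.null(households_path) || !is.null(clusters_path)
  if (from_files == !is.null(sim_config))
    stop("supply exactly one of (households_path, clusters_path) or sim_config")
  if (from_files && (is.null(households_path) || is.null(clusters_path)))
    stop("both households_path and clusters_path are required")
  structure(list(households_path = households_path,
                 clusters_path = clusters_path, sim_config = sim_config,
                 out_dir = out_dir, n_sim = as.integer(n_sim),
                 gwr_bandwidth_m = gwr_bandwidth_m,
                 realloc_buffers = realloc_buffers,
                 threshold_m = threshold_m, n_boot = as.integer(n_boot),
                 gp_cap = as.integer(gp_cap), models = models,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# stage-seed offsets, fixed for the life of the pipeline layout
.stage_offsets <- c(simulate = 10, explore = 20, models = 30,
                    realloc = 40, spillover = 50)

#' Run the full three-part analysis pipeline
#'
#' Executes, in order: data load or simulation, trial summaries, the
#' exploratory table (join counts, Moran's I for the whole area / each arm /
#' model residuals, the GWR summary, the reallocation summary), the
#' model-comparison table (each requested random structure with and without
#' the discordant-distance term), and the spillover table (the distance
#' coefficient by model, its parametric bootstrap, the stratum-specific SMRs
#' and the global interaction test). Each stage is wrapped so a failure is
#' logged and later independent stages still run.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list of class `pipeline_result` with every computed
#'   object, the per-stage errors (if any), and the output paths. Writes
#'   `summary.csv`, `table2_exploratory.csv`, `table1_models.csv`,
#'   `table3_spillover.csv`, `reallocation_curve.csv`, `gwr_surface.csv`,
#'   `run.log` and `config_resolved.json` to `config$out_dir` (plus
#'   `households.csv`, `clusters.geojson` and `ground_truth.json` for
#'   synthetic runs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(line, log_con); message(line)
  }
  seeds <- vapply(.stage_offsets, function(o) derive_seed(config$seed, o),
                  integer(1))
  errors <- list()
  stage <- function(name, expr) {
    logmsg("stage ", name, " (seed ", seeds[[name]] %||% config$seed, ")")
    tryCatch(expr, error = function(e) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  logmsg("netspill ", as.character(utils::packageVersion("netspill")),
         ", R ", getRversion(), ", master seed ", config$seed)
  logmsg("analysis parts: 1) exploratory spatial analysis; ",
         "2) spatial modeling; 3) spillover and interaction")

  # ---- data ----------------------------------------------------------------
  truth <- NULL
  trial <- stage("simulate", {
    if (!is.null(config$sim_config)) {
      cfg <- config$sim_config
      cfg$seed <- seeds[["simulate"]]
      sim <- simulate_trial(cfg)
      truth <<- sim$truth
      write_trial(sim$trial, file.path(config$out_dir, "households.csv"),
                  file.path(config$out_dir, "clusters.geojson"))
      write_ground_truth(truth, file.path(config$out_dir, "ground_truth.json"))
      sim$trial
    } else {
      read_trial(config$households_path, config$clusters_path)
    }
  })
  if (is.null(trial)) stop("pipeline aborted: no trial data")
  trial <- distance_to_discordant(trial)
  summaries <- summarize_trial(trial)
  write_summaries(summaries, csv_path = file.path(config$out_dir, "summary.csv"))
  adj <- queen_adjacency(trial)

  # ---- part 1: exploratory spatial analysis --------------------------------
  explore <- stage("explore", {
    es <- seeds[["explore"]]
    cl <- trial$clusters
    arm <- stats::setNames(cl$arm, cl$cluster_id)
    sm <- summaries$smr
    cl_smr <- stats::setNames(sm$smr[sm$scope == "cluster"],
                              sm$label[sm$scope == "cluster"])
    jc_ctl <- join_count_test(adj, arm, color = 0, n_sim = config$n_sim,
                              seed = derive_seed(es, 1))
    jc_int <- join_count_test(adj, arm, color = 1, n_sim = config$n_sim,
                              seed = derive_seed(es, 2))
    mi_all <- morans_i_test(adj, cl_smr, n_sim = config$n_sim,
                            seed = derive_seed(es, 3))
    sub_test <- function(a) {
      ids <- cl$cluster_id[cl$arm == a]
      morans_i_test(subset_adjacency(adj, ids), cl_smr[ids],
                    n_sim = config$n_sim, seed = derive_seed(es, 4 + a))
    }
    mi_ctl <- sub_test(0L); mi_int <- sub_test(1L)
    fit_iid <- fit_smr_model(trial, model_spec("iid", seed = es))
    mi_res <- residual_morans(trial, fit_iid, adj, n_sim = config$n_sim,
                              seed = derive_seed(es, 6))
    bw <- config$gwr_bandwidth_m
    if (is.null(bw)) bw <- gwr_bandwidth(trial)
    gwr <- gwr_poisson(trial, bw)
    write_gwr_surface(gwr, file.path(config$out_dir, "gwr_surface.csv"))
    list(jc_ctl = jc_ctl, jc_int = jc_int, mi_all = mi_all, mi_ctl = mi_ctl,
         mi_int = mi_int, mi_res = mi_res, gwr = gwr, fit_iid = fit_iid)
  })

  # ---- reallocation (part of the exploratory block) ------------------------
  realloc <- stage("realloc", {
    spec <- model_spec("iid", seed = seeds[["realloc"]])
    curve <- reallocation_sweep(trial, spec, buffers = config$realloc_buffers)
    write_curve(curve, file.path(config$out_dir, "reallocation_curve.csv"))
    list(curve = curve, summary = curve_summary(curve))
  })

  # exploratory summary table
  t2 <- stage("explore", {
    rs <- realloc$summary
    fmt_realloc <- function(a) {
      r <- rs[rs$dilated_arm == a, ]
      if (!nrow(r)) return(NA_real_)
      r$mean
    }
    rows <- data.frame(
      method = c("join count - control", "join count - intervention",
                 "Moran's I - entire study area", "Moran's I - control",
                 "Moran's I - intervention", "Moran's I - residuals",
                 "GWR median local SMR", "GWR IQR lower", "GWR IQR upper",
                 "reallocation - original clusters",
                 "reallocation - controls larger (mean)",
                 "reallocation - intervention larger (mean)"),
      statistic = c(explore$jc_ctl$observed, explore$jc_int$observed,
                    explore$mi_all$observed, explore$mi_ctl$observed,
                    explore$mi_int$observed, explore$mi_res$observed,
                    explore$gwr$summary$median, explore$gwr$summary$q25,
                    explore$gwr$summary$q75,
                    if (!is.null(realloc)) rs$buffer0[1L] else NA,
                    fmt_realloc(0L), fmt_realloc(1L)),
      p_value = c(explore$jc_ctl$p_value, explore$jc_int$p_value,
                  explore$mi_all$p_value, explore$mi_ctl$p_value,
                  explore$mi_int$p_value, explore$mi_res$p_value,
                  NA, NA, NA, NA, NA, NA))
    utils::write.csv(rows, file.path(config$out_dir, "table2_exploratory.csv"),
                     row.names = FALSE, quote = FALSE)
    rows
  })

  # ---- part 2: spatial models ----------------------------------------------
  models <- stage("models", {
    ms <- seeds[["models"]]
    fits <- list()
    for (m in config$models)
      fits[[m]] <- fit_smr_model(
        trial, model_spec(m, gp_cap = config$gp_cap, seed = ms), adj)
    for (m in setdiff(config$models, "car"))   # distance variants
      fits[[paste0(m, "_distance")]] <- fit_smr_model(
        trial, model_spec(m, distance = TRUE, gp_cap = config$gp_cap,
                          seed = ms), adj)
    tab <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(model = nm, fits[[nm]]$smr_table)))
    utils::write.csv(tab, file.path(config$out_dir, "table1_models.csv"),
                     row.names = FALSE, quote = FALSE)
    fits
  })

  # ---- part 3: spillover and interaction -----------------------------------
  spill <- stage("spillover", {
    ss <- seeds[["spillover"]]
    rows <- list()
    take_psi <- function(nm) {
      f <- models[[paste0(nm, "_distance")]]
      if (is.null(f)) return(NULL)
      r <- f$smr_table[f$smr_table$term == "d100", ]
      data.frame(variable = "distance per 100 m", model = nm,
                 term = "d100", smr = r$smr, lower95 = r$lower95,
                 upper95 = r$upper95, p_value = NA_real_)
    }
    for (nm in setdiff(config$models, "car"))
      rows[[nm]] <- take_psi(nm)
    boot <- parametric_bootstrap(trial, model_spec("iid", distance = TRUE,
                                                   seed = ss),
                                 n_boot = config$n_boot, seed = ss)
    rows$boot <- data.frame(variable = "distance per 100 m",
                            model = "iid bootstrap", term = "d100",
                            smr = boot$smr_estimate,
                            lower95 = boot$smr_ci[1L],
                            upper95 = boot$smr_ci[2L], p_value = NA_real_)
    inter <- interaction_analysis(trial, threshold_m = config$threshold_m,
                                  spec = model_spec("iid", seed = ss))
    st <- inter$table
    rows$strata <- data.frame(
      variable = paste0("stratum (", st$conditioning, ": ", st$stratum, ")"),
      model = "iid interaction", term = st$group, smr = st$smr,
      lower95 = st$lower95, upper95 = st$upper95, p_value = NA_real_)
    rows$test <- data.frame(variable = "global interaction test",
                            model = "iid interaction", term = "x:far",
                            smr = NA_real_, lower95 = NA_real_,
                            upper95 = NA_real_,
                            p_value = inter$interaction_p)
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "table3_spillover.csv"),
                     row.names = FALSE, quote = FALSE)
    list(table = tab, bootstrap = boot, interaction = inter)
  })

  resolved <- list(config = unclass(config), stage_seeds = as.list(seeds),
                   n_households = nrow(trial$households),
                   n_clusters = nrow(trial$clusters),
                   errors = errors)
  resolved$config$sim_config <- if (!is.null(config$sim_config))
    unclass(config$sim_config)
  jsonlite::write_json(resolved,
                       file.path(config$out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = I(10), null = "null")
  logmsg("pipeline complete; ", length(errors), " stage error(s)")
  invisible(structure(list(trial = trial, truth = truth,
                           summaries = summaries, adjacency = adj,
                           explore = explore, table2 = t2, models = models,
                           realloc = realloc, spillover = spill,
                           errors = errors, out_dir = config$out_dir,
                           stage_seeds = seeds),
                      class = "pipeline_result"))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
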