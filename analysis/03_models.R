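#!/usr/bin/env Rscript
# Step 3 — spatial SMR models (second analysis part).
#
# Estimates the intervention effect under increasingly rich spatial
# assumptions: a multilevel Poisson model with an IID cluster intercept
# (the trial's standard analysis), an intrinsic CAR model on the cluster
# contiguity graph (cluster-aggregated), the BYM convolution of both, and a
# Gaussian-process model with a household-level exponential-covariance
# field — each also refitted with the discordant-distance term. The point
# of the table is robustness: if spillover or spatial correlation mattered
# for the primary contrast, the estimates would move.

suppressMessages(library(netspill))
out <- "results"
trial <- read_trial(file.path(out, "households.csv"),
                    file.path(out, "clusters.geojson"))
trial <- distance_to_discordant(trial)
adj <- queen_adjacency(trial)

fits <- list()
for (m in c("iid", "car", "bym", "gp"))
  fits[[m]] <- fit_smr_model(trial, model_spec(m, gp_cap = 1000), adj)
for (m in c("iid", "bym", "gp"))
  fits[[paste0(m, "_distance")]] <-
    fit_smr_model(trial, model_spec(m, distance = TRUE, gp_cap = 1000), adj)

tab <- do.call(rbind, lapply(names(fits), function(nm)
  cbind(model = nm, fits[[nm]]$smr_table)))
write.csv(tab, file.path(out, "model_estimates.csv"), row.names = FALSE)

x <- tab[tab$term == "x", ]
message("intervention SMR by model:")
print(x[, c("model", "smr", "lower95", "upper95")], row.names = FALSE,
      digits = 3)
spread <- diff(range(x$smr))
message("spread of intervention estimates across spatial structures: ",
        round(spread, 3),
        " - the trial conclusion is robust to the spatial specification ",
        "when this is small relative to the interval widths.")
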