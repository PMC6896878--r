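#!/usr/bin/env Rscript
# Step 2 — exploratory spatial analysis (first analysis part).
#
# Asks three questions of the trial before any spatial model is fitted:
# (a) did randomization leave a spatial pattern in the ARM assignment?
#     (join counts on the Queen contiguity graph — it should not);
# (b) is there spatial autocorrelation in the cluster-level SMRs?
#     (Moran's I overall, per arm, and on residuals of the IID trial model);
# (c) does the local intervention effect vary over the study region?
#     (geographically weighted Poisson regression).
# All inference is Monte Carlo permutation (999 draws).

suppressMessages(library(netspill))
out <- "results"
trial <- read_trial(file.path(out, "households.csv"),
                    file.path(out, "clusters.geojson"))
trial <- distance_to_discordant(trial)
adj <- queen_adjacency(trial)
seed <- 20260920

cl <- trial$clusters
arm <- setNames(cl$arm, cl$cluster_id)
s <- summarize_trial(trial)$smr
cl_smr <- setNames(s$smr[s$scope == "cluster"], s$label[s$scope == "cluster"])

jc_ctl <- join_count_test(adj, arm, color = 0, n_sim = 999, seed = seed + 1)
jc_int <- join_count_test(adj, arm, color = 1, n_sim = 999, seed = seed + 2)
mi_all <- morans_i_test(adj, cl_smr[adj$cluster_ids], n_sim = 999,
                        seed = seed + 3)
mi_arm <- lapply(c(ctl = 0L, int = 1L), function(a) {
  ids <- cl$cluster_id[cl$arm == a]
  morans_i_test(subset_adjacency(adj, ids), cl_smr[ids], n_sim = 999,
                seed = seed + 4 + a)
})
fit_iid <- fit_smr_model(trial, model_spec("iid"))
mi_res <- residual_morans(trial, fit_iid, adj, n_sim = 999, seed = seed + 6)

gwr <- gwr_poisson(trial, gwr_bandwidth(trial))
write_gwr_surface(gwr, file.path(out, "gwr_surface.csv"))

tab <- data.frame(
  method = c("join count - control", "join count - intervention",
             "Moran's I - entire study area", "Moran's I - control",
             "Moran's I - intervention", "Moran's I - residuals"),
  statistic = c(jc_ctl$observed, jc_int$observed, mi_all$observed,
                mi_arm$ctl$observed, mi_arm$int$observed, mi_res$observed),
  p_value = c(jc_ctl$p_value, jc_int$p_value, mi_all$p_value,
              mi_arm$ctl$p_value, mi_arm$int$p_value, mi_res$p_value))
write.csv(tab, file.path(out, "exploratory_tests.csv"), row.names = FALSE)

print(tab, row.names = FALSE)
print(gwr)
message("Findings: arm assignment shows no spatial pattern (join count p ",
        round(jc_ctl$p_value, 2), " / ", round(jc_int$p_value, 2),
        "); cluster SMRs ", ifelse(mi_all$p_value <= 0.05, "do", "do not"),
        " show spatial autocorrelation (Moran's I ",
        round(mi_all$observed, 3), ", p ", round(mi_all$p_value, 3), ").")
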