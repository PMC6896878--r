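#!/usr/bin/env Rscript
# Step 4 — cluster reallocation diagnostic.
#
# Dilates each arm's cluster polygons in 100 m steps to 1,000 m, reassigns
# the opposite-arm households engulfed by the buffer, and refits the IID
# trial model at every step. Without spillover the estimates drift toward
# the null as the arms are diluted; spillover strong enough to dominate
# that dilution shows up as a strengthening of the estimate when the
# intervention arm is dilated over the spillover's functional distance.

suppressMessages(library(netspill))
out <- "results"
trial <- read_trial(file.path(out, "households.csv"),
                    file.path(out, "clusters.geojson"))
trial <- distance_to_discordant(trial)

curve <- reallocation_sweep(trial, model_spec("iid"),
                            buffers = seq(0, 1000, by = 100))
write_curve(curve, file.path(out, "reallocation_curve.csv"))
summ <- curve_summary(curve)
write.csv(summ, file.path(out, "reallocation_summary.csv"), row.names = FALSE)

pdf(file.path(out, "reallocation_curve.pdf"), width = 7, height = 5)
plot(curve, main = "Cluster reallocation")
dev.off()

print(curve)
message("original estimate ", round(summ$buffer0[1], 3),
        "; control dilated mean ", round(summ$mean[summ$dilated_arm == 0], 3),
        " (", round(summ$min[summ$dilated_arm == 0], 3), "-",
        round(summ$max[summ$dilated_arm == 0], 3),
        "); intervention dilated mean ",
        round(summ$mean[summ$dilated_arm == 1], 3),
        " (", round(summ$min[summ$dilated_arm == 1], 3), "-",
        round(summ$max[summ$dilated_arm == 1], 3), ")")
message("Note: at the generator's default spillover (1.7% per 100 m) the ",
        "dilution effect dominates, so both sweeps attenuate toward the ",
        "null; see the methods vignette for the strength of spillover at ",
        "which intervention-side dilation strengthens the estimate instead.")
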