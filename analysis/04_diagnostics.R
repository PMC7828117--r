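#!/usr/bin/env Rscript
# Model evaluation: prediction-corrected visual predictive check and
# goodness-of-fit table for the PD model, at the design of the synthetic
# efficacy study (dropout endogenous in the simulated replicates).

suppressPackageStartupMessages(library(nanomsc))

seed <- 7
dir.create("results", showWarnings = FALSE)
params <- nanomsc_params()

study <- generate_pd_study(params, seed = seed)
m3 <- apply_modified_m3(study$observations, study$schedule)
fit <- fit_pd(m3, params, regimens = study$regimens)

v <- pcvpc(m3, fit$meta$params, study$regimens, n_sim = 200,
           dropout_threshold = study$dropout_threshold, seed = seed + 1)
write.csv(v$observed, "results/pcvpc_observed.csv", row.names = FALSE)
write.csv(v$simulated, "results/pcvpc_simulated.csv", row.names = FALSE)

med <- v$observed[v$observed$percentile == "p50", ]
sim <- v$simulated[v$simulated$percentile == "p50", ]
sim <- sim[match(paste(med$ARM, med$bin), paste(sim$ARM, sim$bin)), ]
message(sprintf("observed medians inside the simulated 95%% band: %.0f%% of bins",
                100 * mean(med$value >= sim$lo & med$value <= sim$hi)))

g <- gof_table(m3, fit)
write.csv(g, "results/gof_table.csv", row.names = FALSE)
r <- g$RES_PROP[!is.na(g$RES_PROP)]
message(sprintf("proportional residuals: mean %+.3f, sd %.3f (n = %d)",
                mean(r), sd(r), length(r)))
write_manifest("results/diagnostics_manifest.json", "diagnostics", seed,
               inputs = list(n_sim = 200))
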