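#!/usr/bin/env Rscript
# Build the synthetic world: spatially autocorrelated covariate fields,
# an ecoregion partition with species pools, and a biased plot survey
# whose richness follows a known power-law species-area relationship.

source(file.path("analysis", "_common.R"))

cfg <- world_cfg()
env <- generate_environment(cfg)
print(env)

plots <- sample_plots(env, cfg, n_plots = N_PLOTS)
cat(sprintf("sampled %d plots; richness 0-%d (median %d)\n",
            nrow(plots), max(plots$S_complete),
            median(plots$S_complete)))

write_env_grid(env, results_dir("env"))
write_plot_table(plots, file.path(results_dir(), "plots_raw.tsv"))
cat("wrote results/env/ and results/plots_raw.tsv\n")
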