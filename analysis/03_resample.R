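#!/usr/bin/env Rscript
# Stratified geographical resampling: up to 100 plots per realm x biome x
# formation x size-class stratum, repeated independently per iteration,
# with simulated survey incompleteness (rarefaction to woody-only tiers)
# in data-rich biomes.

source(file.path("analysis", "_common.R"))

plots <- read_plot_table(file.path("results", "plots_screened.tsv"))
strata <- build_strata(plots)
cat(sprintf("%d non-empty strata; largest holds %d plots\n",
            length(strata), max(lengths(strata))))

sets <- stratified_resample(strata, max_per_stratum = 100,
                            n_iter = N_MEMBERS, seed = ANALYSIS_SEED)
# desk-scale eligibility threshold: the synthetic biomes hold a few
# hundred complete plots each, not the >10,000 of a global database
sets <- lapply(sets, simulate_incompleteness, plots = plots,
               complete_threshold = 100)

tab <- do.call(rbind, lapply(sets, function(s)
  data.frame(iteration = s$iteration, plot_id = s$plot_id,
             rarefy_to = s$rarefy_to, seed = s$seed)))
write.table(tab, file.path(results_dir(), "resamples.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("%d sets of %d plots (%.0f%% rarefied on average); wrote results/resamples.tsv\n",
            length(sets), length(sets[[1]]$plot_id),
            100 * mean(sapply(sets, function(s)
              mean(s$rarefy_to != "none")))))
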