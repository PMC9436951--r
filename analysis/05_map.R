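#!/usr/bin/env Rscript
# Multi-grain mapping: per-member bias-corrected prediction grids at the
# forest and non-forest grains, reduced to median / IQR / relative
# uncertainty, hotspot and coldspot masks, the bivariate scaling-anomaly
# classification, and the ignorance (data-poor) mask.

source(file.path("analysis", "_common.R"))

cfg <- world_cfg()
env <- generate_environment(cfg)
plots <- read_plot_table(file.path("results", "plots_screened.tsv"))
transforms <- fit_covariate_pcas(env)
members <- load_ensemble(file.path("results", "models"))

maps_dir <- results_dir("maps")
medians <- list()
for (formation in c("forest", "non-forest")) {
  grains <- if (formation == "forest") FOREST_GRAINS else NONFOREST_GRAINS
  for (grain in grains) {
    st <- predict_grid(members, env, grain, formation, transforms)
    sm <- summarize_stack(st)
    stem <- sprintf("%s_%gm2", sub("-", "", formation), grain)
    write_ascii_grid(sm$median, file.path(maps_dir,
                                          paste0(stem, "_median.asc")),
                     env$cell_km)
    write_ascii_grid(sm$iqr, file.path(maps_dir, paste0(stem, "_iqr.asc")),
                     env$cell_km)
    hs <- hotspots(sm$median)
    write_ascii_grid(hs$hot + 0, file.path(maps_dir,
                                           paste0(stem, "_hotspots.asc")),
                     env$cell_km)
    write_ascii_grid(hs$cold + 0, file.path(maps_dir,
                                            paste0(stem, "_coldspots.asc")),
                     env$cell_km)
    medians[[paste(formation, grain)]] <- sm$median
    cat(sprintf("%-22s median %5.1f (IQR %4.1f), %d hot / %d cold pixels\n",
                stem, median(sm$median, na.rm = TRUE),
                median(sm$iqr, na.rm = TRUE),
                sum(hs$hot, na.rm = TRUE), sum(hs$cold, na.rm = TRUE)))
  }
}

# scaling anomalies: fine vs coarse grain per formation
for (formation in c("forest", "non-forest")) {
  grains <- if (formation == "forest") FOREST_GRAINS else NONFOREST_GRAINS
  an <- scaling_anomalies(medians[[paste(formation, grains[1])]],
                          medians[[paste(formation, grains[3])]])
  stem <- sub("-", "", formation)
  write_ascii_grid(an$class, file.path(maps_dir,
                                       paste0(stem, "_anomaly_class.asc")),
                   env$cell_km)
  cat(sprintf("%s scaling anomalies: %.1f%% fine-high/coarse-low, %.1f%% fine-low/coarse-high\n",
              formation, 100 * an$frac_fine_high_coarse_low,
              100 * an$frac_fine_low_coarse_high))
}

ig <- ignorance_mask(plots, env, max_dist_km = 30)
write_ascii_grid(ig + 0, file.path(maps_dir, "ignorance.asc"), env$cell_km)
cat(sprintf("data-poor pixels (>30 km from any plot): %.1f%%\n",
            100 * mean(ig)))
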