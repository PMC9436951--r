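#!/usr/bin/env Rscript
# Model validation: held-out correlation per member, variogram-based block
# sizing, spatially blocked vs random cross-validation, and residual
# variograms.

source(file.path("analysis", "_common.R"))

cfg <- world_cfg()
env <- generate_environment(cfg)
plots <- read_plot_table(file.path("results", "plots_screened.tsv"))
transforms <- fit_covariate_pcas(env)
members <- load_ensemble(file.path("results", "models"))

rs <- read.table(file.path("results", "resamples.tsv"), sep = "\t",
                 header = TRUE, stringsAsFactors = FALSE)
sets <- lapply(split(rs, rs$iteration), function(d)
  structure(list(iteration = d$iteration[1], plot_id = d$plot_id,
                 rarefy_to = d$rarefy_to, seed = d$seed[1]),
            class = "resample_set"))

# held-out correlation (plots not in each member's resample set)
ho <- mapply(function(s, m) {
  h <- holdout_correlation(s, plots, m, transforms, env)
  c(r = h$r, n = h$n)
}, sets, members)
cat(sprintf("held-out Pearson r: mean %.3f over %d members\n",
            mean(ho["r", ]), ncol(ho)))

# block size from the covariates' mean autocorrelation range
ac <- autocorrelation_range(env, n_samples = 1000, seed = ANALYSIS_SEED)
cat(sprintf("mean covariate autocorrelation range: %.0f km\n",
            ac$mean_range))

# cap the block size when the range estimate approaches the extent
extent <- min(diff(range(plots$x)), diff(range(plots$y)))
bl <- build_blocks(plots, block_km = min(ac$mean_range, extent / 3), k = 5,
                   n_assign = 99, seed = ANALYSIS_SEED)
cat(sprintf("%d blocks of %.0f km; evenest fold spread (sd of counts): %.1f\n",
            nrow(bl$blocks), bl$block_km, bl$evenness))

hp <- brt_hyperparams(learning_rates = members[[1]]$model$eta,
                      fixed_trees = members[[1]]$model$n_trees)
blocked <- block_cross_validate(plots, bl$fold, transforms, env, hp,
                                seed = ANALYSIS_SEED, per_biome = TRUE)
random <- block_cross_validate(plots,
                               random_folds(nrow(plots), 5, ANALYSIS_SEED),
                               transforms, env, hp, seed = ANALYSIS_SEED)
cat(sprintf("pooled r: blocked %.3f vs random folds %.3f\n",
            blocked$pooled_r, random$pooled_r))

# residual spatial structure for member 1
x <- assemble(plots, transforms, env)
kept <- attr(x, "kept")
pred <- apply_roe(predict(members[[1]]$model, x), members[[1]]$roe)
rv <- residual_variogram(plots$richness[kept], pred, plots$x[kept],
                         plots$y[kept])
print(rv)

report <- rbind(
  data.frame(statistic = "holdout_r_mean", value = mean(ho["r", ])),
  data.frame(statistic = "autocorrelation_range_km", value = ac$mean_range),
  data.frame(statistic = "n_blocks", value = nrow(bl$blocks)),
  data.frame(statistic = "blocked_pooled_r", value = blocked$pooled_r),
  data.frame(statistic = "random_pooled_r", value = random$pooled_r),
  data.frame(statistic = "residual_effective_range_km",
             value = rv$effective_range)
)
write.table(report, file.path(results_dir(), "validation.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(blocked$per_biome, file.path(results_dir(),
                                         "validation_per_biome.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/validation.tsv and results/validation_per_biome.tsv\n")
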