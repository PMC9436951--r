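# Shared synthetic fixtures, built once per test run.

# a small default-conditions world with screened plots
tiny_world <- local({
  cfg <- world_config(nrow = 50, ncol = 50, cell_km = 2, seed = 101)
  env <- generate_environment(cfg)
  plots <- sample_plots(env, cfg, n_plots = 1200)
  ing <- filter_plots(plots)
  list(cfg = cfg, env = env, raw = plots, plots = ing$plots,
       report = ing$report)
})

# light hyperparameters for fast unit-test fits
fast_hp <- function(...) {
  brt_hyperparams(learning_rates = 0.05, cv_folds = 4, max_trees = 300,
                  block = 25, patience = 2, ...)
}

# a single fitted member on the tiny world, reused across tests
tiny_member <- local({
  w <- tiny_world
  tr <- fit_covariate_pcas(w$env)
  strata <- build_strata(w$plots)
  sets <- stratified_resample(strata, n_iter = 1, seed = w$cfg$seed)
  mem <- fit_ensemble(sets, w$plots, tr, w$env, fast_hp(), seed = 11)[[1]]
  list(member = mem, transforms = tr, set = sets[[1]])
})
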