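# Shared configuration for the analysis workflow. Every script re-derives
# the synthetic world deterministically from this config, so the scripts
# can be run independently or in sequence; heavy artifacts are written
# under results/.

library(alphagrain)

ANALYSIS_SEED <- 42L

world_cfg <- function() {
  world_config(nrow = 100, ncol = 100, cell_km = 2, z = 0.25,
               seed = ANALYSIS_SEED)
}

N_PLOTS <- 4000      # survey size
N_MEMBERS <- 9       # resampled ensemble members at desk scale
FOREST_GRAINS <- c(400, 1000, 10000)     # m^2
NONFOREST_GRAINS <- c(10, 100, 1000)     # m^2

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

default_hp <- function() {
  brt_hyperparams(learning_rates = c(0.02, 0.06), cv_folds = 5,
                  max_trees = 400, block = 25, patience = 2)
}
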