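test_that("the semivariogram estimator matches brute-force all-pairs semivariance", {
  set.seed(6)
  n <- 150
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); v <- rnorm(n)
  vg <- empirical_variogram(x, y, v, n_bins = 8)
  # brute force: double loop over all pairs, same bin edges
  max_lag <- attr(vg, "max_lag")
  d <- g <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (dij > 0 && dij <= max_lag) {
      d <- c(d, dij); g <- c(g, (v[i] - v[j])^2 / 2)
    }
  }
  lo <- max(min(d), max_lag * 1e-4)
  edges <- exp(seq(log(lo), log(max_lag), length.out = 9)); edges[1] <- 0
  bin <- cut(d, edges, labels = FALSE, include.lowest = TRUE)
  expect_equal(vg$gamma, as.numeric(tapply(g, bin, mean)), tolerance = 1e-10)
  expect_equal(vg$lag, as.numeric(tapply(d, bin, mean)), tolerance = 1e-10)
  expect_equal(vg$n_pairs, as.integer(table(bin)))
})

test_that("duplicated covariates get identical range estimates", {
  cfg <- world_config(nrow = 60, ncol = 60, range_km = 30, n_climate = 1,
                      n_soil = 0, n_topo = 0, n_velocity = 0,
                      mask_fraction = 0, seed = 8)
  env <- generate_environment(cfg)
  layers <- list(a = env$layers[[1]], b = env$layers[[1]])
  ac <- autocorrelation_range(layers, n_samples = 600, seed = 4)
  expect_equal(ac$per_covariate$effective_range[1],
               ac$per_covariate$effective_range[2])
})

test_that("residual variograms distinguish white noise from smooth fields", {
  set.seed(9)
  n <- 400
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  obs <- rnorm(n)
  # white-noise residuals: flat variogram, nugget ~ sill
  rv <- residual_variogram(obs, rep(0, n), x, y)
  expect_true(isTRUE(rv$pure_nugget))
  # smooth spatial residuals: range well beyond one bin width
  cfg <- world_config(nrow = 100, ncol = 100, cell_km = 2, range_km = 60,
                      n_climate = 1, n_soil = 0, n_topo = 0, n_velocity = 0,
                      mask_fraction = 0, seed = 10)
  env <- generate_environment(cfg)
  rc <- cbind(sample(1:100, n, TRUE), sample(1:100, n, TRUE))
  smooth <- env$layers[[1]][rc]
  rv2 <- residual_variogram(smooth, rep(0, n), rc[, 2] * 2, rc[, 1] * 2)
  expect_true(rv2$converged)
  bin_width <- attr(rv2$variogram, "max_lag") / nrow(rv2$variogram)
  expect_gt(rv2$effective_range, 3 * bin_width)
  expect_false(isTRUE(rv2$pure_nugget))
  # all-zero residuals are degenerate, not fitted
  rv3 <- residual_variogram(obs, obs, x, y)
  expect_true(rv3$degenerate)
  expect_false(rv3$converged)
  expect_error(residual_variogram(obs[1:50], obs[1:50], x[1:50], y[1:50]),
               "100 points")
})

test_that("block tiling partitions plots and the assignment is the evenest tried", {
  plots <- data.frame(x = runif(200, 0, 10), y = runif(200, 0, 10))
  bl <- build_blocks(plots, block_km = 5, k = 2, n_assign = 30, seed = 6)
  expect_equal(nrow(bl$blocks), 4) # 10x10 extent, 5 km blocks
  expect_length(bl$fold, 200)
  expect_true(all(bl$fold %in% 1:2))
  expect_equal(bl$evenness, min(bl$candidate_spreads))
  # determinism
  bl2 <- build_blocks(plots, block_km = 5, k = 2, n_assign = 30, seed = 6)
  expect_identical(bl$fold, bl2$fold)
  expect_error(build_blocks(plots, block_km = 50, k = 5), "fewer non-empty")
  expect_error(build_blocks(plots, block_km = 0, k = 2), "positive")
})

test_that("noise-free richness is almost perfectly cross-validated", {
  cfg <- world_config(nrow = 50, ncol = 50, dispersion = Inf, gamma = 0.5,
                      pool_meanlog = log(2000), mask_fraction = 0, seed = 15)
  env <- generate_environment(cfg)
  plots <- sample_plots(env, cfg, n_plots = 700, prop_incomplete = 0,
                        prop_missing_area = 0, prop_anthropogenic = 0,
                        prop_aquatic = 0, prop_unresolved = 0)
  ing <- filter_plots(plots)
  tr <- fit_covariate_pcas(env)
  fold <- random_folds(nrow(ing$plots), k = 5, seed = 2)
  hp <- brt_hyperparams(learning_rates = 0.1, fixed_trees = 200)
  cv <- block_cross_validate(ing$plots, fold, tr, env, hp, seed = 3)
  expect_equal(nrow(cv$per_fold), 5)
  expect_gt(cv$pooled_r, 0.95)
  # folds partition the plots
  expect_equal(sum(cv$per_fold$n), nrow(ing$plots))
})

test_that("shuffling the response against predictors kills the correlation", {
  w <- tiny_world
  plots <- w$plots
  set.seed(99)
  plots$richness <- sample(plots$richness)
  tr <- tiny_member$transforms
  fold <- random_folds(nrow(plots), k = 4, seed = 5)
  hp <- brt_hyperparams(learning_rates = 0.05, fixed_trees = 100)
  cv <- block_cross_validate(plots, fold, tr, w$env, hp, seed = 7)
  expect_lt(abs(cv$pooled_r), 0.15)
})

test_that("held-out correlation is deterministic and close to training r on iid splits", {
  # strong-signal world: training and complement differ only by sampling
  cfg <- world_config(nrow = 50, ncol = 50, dispersion = 50, gamma = 0.5,
                      pool_meanlog = log(2000), mask_fraction = 0,
                      seed = 16)
  env <- generate_environment(cfg)
  raw <- sample_plots(env, cfg, n_plots = 900, prop_incomplete = 0,
                      prop_unresolved = 0)
  plots <- filter_plots(raw)$plots
  tr <- fit_covariate_pcas(env)
  set.seed(3)
  half <- sample(plots$plot_id, nrow(plots) %/% 2)
  set <- structure(list(iteration = 1, plot_id = half,
                        rarefy_to = rep("none", length(half)), seed = 1),
                   class = "resample_set")
  mem <- fit_ensemble(list(set), plots, tr, env, fast_hp(), seed = 8)[[1]]
  ho <- holdout_correlation(set, plots, mem, tr, env)
  ho2 <- holdout_correlation(set, plots, mem, tr, env)
  expect_identical(ho, ho2)
  expect_gt(ho$n, 0)
  train <- apply_rarefaction(set, plots)
  x <- assemble(train, tr, env)
  ytr <- train$richness[attr(x, "kept")]
  rtrain <- cor(ytr, apply_roe(predict(mem$model, x), mem$roe))
  expect_lt(abs(ho$r - rtrain), 0.1)
  # complement must be non-empty
  all_ids <- structure(list(iteration = 1, plot_id = plots$plot_id,
                            rarefy_to = rep("none", nrow(plots)),
                            seed = 1), class = "resample_set")
  expect_error(holdout_correlation(all_ids, plots, mem, tr, env),
               "fewer than 3")
})

test_that("small test folds are skipped with a warning", {
  w <- tiny_world
  tr <- tiny_member$transforms
  fold <- rep(1L, nrow(w$plots)); fold[1:2] <- 2L
  fold[3:((nrow(w$plots)) %/% 2)] <- 3L
  hp <- brt_hyperparams(learning_rates = 0.1, fixed_trees = 50)
  expect_warning(cv <- block_cross_validate(w$plots, fold, tr, w$env, hp,
                                            seed = 2),
                 "fewer than 3")
  expect_false(2 %in% cv$per_fold$fold)
})
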