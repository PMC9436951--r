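test_that("ROE coefficients come from observed-on-estimated least squares", {
  # identity calibration
  bc <- fit_roe(c(1, 5, 9), c(1, 5, 9))
  expect_equal(bc$a, 0, tolerance = 1e-10)
  expect_equal(bc$b, 1, tolerance = 1e-10)
  # two-point fit by hand: b = (7 - 5) / (10 - 2), a = 5 - b * 2
  expect_error(fit_roe(10, 5), "2 points")
  bc2 <- fit_roe(c(2, 10), c(5, 7))
  expect_equal(bc2$a, 4.5)
  expect_equal(bc2$b, 0.25)
  # exact linear case
  obs <- c(0, 2, 5, 11)
  bc3 <- fit_roe(obs, 2 * obs + 1)
  expect_equal(bc3$a, 1, tolerance = 1e-12)
  expect_equal(bc3$b, 2, tolerance = 1e-12)
  expect_error(fit_roe(rep(4, 5), rnorm(5)), "constant")
})

test_that("ROE correction inverts the fitted line with a zero floor", {
  bc <- structure(list(a = 4.5, b = 0.25), class = "bias_correction")
  expect_equal(apply_roe(c(5, 7), bc), c(2, 10))
  expect_equal(apply_roe(3, bc), 0) # (3 - 4.5) / 0.25 < 0
  id <- structure(list(a = 0, b = 1), class = "bias_correction")
  expect_equal(apply_roe(c(0, 3, 8), id), c(0, 3, 8))
  expect_error(apply_roe(1, structure(list(a = 0, b = 0),
                                      class = "bias_correction")), "zero")
})

test_that("ROE round trip is an algebraic identity when the floor is inactive", {
  set.seed(42)
  for (i in 1:5) {
    obs <- runif(60, 50, 150)
    fitted <- 30 + 0.6 * obs + rnorm(60, 0, 4) # shrunk toward the mean
    bc <- fit_roe(obs, fitted)
    corrected <- apply_roe(fitted, bc)
    expect_true(all((fitted - bc$a) / bc$b > 0)) # floor never active
    # identity: corrected = obs + resid / b with OLS residuals orthogonal
    # to obs, so the observed-on-estimated line of the corrected values
    # has slope 1 and intercept 0
    cf <- coef(lm(corrected ~ obs))
    expect_equal(unname(cf[1]), 0, tolerance = 1e-8)
    expect_equal(unname(cf[2]), 1, tolerance = 1e-8)
    expect_true(all(corrected >= 0))
  }
})

test_that("a constant response yields null-model predictions", {
  x <- data.frame(a = rnorm(80), b = rnorm(80))
  m <- fit_brt(x, rep(7, 80), fast_hp(), seed = 1)
  expect_equal(unname(predict(m, x)), rep(7, 80), tolerance = 1e-3)
})

test_that("training deviance is non-increasing in tree count", {
  set.seed(5)
  x <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- rpois(300, exp(1 + 0.8 * x$a))
  tr <- training_deviance_trace(x, y,
                                brt_hyperparams(learning_rates = 0.1,
                                                bag_fraction = 1),
                                n_trees = 80, seed = 2)
  expect_length(tr, 80)
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("the CV search picks a learning rate and fits a strong-signal model", {
  set.seed(9)
  n <- 800
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rpois(n, exp(1.2 + 0.9 * x$a - 0.5 * x$b))
  hp <- brt_hyperparams(learning_rates = c(0.01, 0.1), cv_folds = 4,
                        max_trees = 300, block = 25, patience = 2)
  m <- fit_brt(x, y, hp, seed = 3)
  expect_true(m$eta %in% c(0.01, 0.1))
  expect_gte(m$n_trees, 1)
  expect_gt(cor(predict(m, x), y), 0.7)
  # determinism
  m2 <- fit_brt(x, y, hp, seed = 3)
  expect_identical(predict(m, x), predict(m2, x))
})

test_that("relative influence normalizes to 100 and flags dominant predictors", {
  set.seed(11)
  n <- 600
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n))
  y <- rpois(n, exp(1 + 1.2 * x$x1)) # response from x1 only
  hp <- fast_hp()
  ms <- lapply(1:3, function(i) fit_brt(x, y, hp, seed = i))
  ri <- relative_influence(ms)
  per <- attr(ri, "per_member")
  expect_equal(unname(colSums(per)), rep(100, 3), tolerance = 1e-6)
  expect_equal(attr(ri, "relevance_threshold"), 100 / 4)
  expect_equal(ri$predictor[1], "x1")
  expect_true(all(ri$median[ri$predictor == "x1"] > ri$median[-1]))
  expect_true(all(per >= 0))
})

test_that("a single-predictor model concentrates all influence", {
  set.seed(12)
  x <- data.frame(only = rnorm(300))
  y <- rpois(300, exp(1 + 0.9 * x$only))
  m <- fit_brt(x, y, fast_hp(), seed = 4)
  ri <- relative_influence(list(m))
  expect_equal(ri$median, 100)
})

test_that("partial dependence is flat for an unused predictor and centred", {
  set.seed(13)
  x <- data.frame(sig = rnorm(400), dead = rep(1, 400))
  y <- rpois(400, exp(1 + 0.8 * x$sig))
  m <- fit_brt(x, y, fast_hp(), seed = 5)
  pd_dead <- partial_dependence(m, "dead", grid = c(0, 1, 2),
                                training_values = x$dead)
  expect_true(all(abs(pd_dead$fitted) < 1e-10))
  pd_sig <- partial_dependence(m, "sig", training_values = x$sig)
  # centring: mean over the training distribution of the predictor ~ 0
  at_train <- partial_dependence(m, "sig", grid = x$sig,
                                 training_values = x$sig)
  expect_equal(mean(at_train$fitted), 0, tolerance = 1e-8)
  expect_true(any(pd_sig$fitted != 0))
  # extrapolation flagging
  pd_out <- partial_dependence(m, "sig", grid = c(min(x$sig) - 10, 0),
                               training_values = x$sig)
  expect_equal(pd_out$extrapolated, c(TRUE, FALSE))
  expect_error(partial_dependence(m, "nope"), "unknown predictor")
})

test_that("ensemble members are one per set, independent, and reproducible", {
  w <- tiny_world
  tr <- tiny_member$transforms
  strata <- build_strata(w$plots)
  sets <- stratified_resample(strata, max_per_stratum = 50, n_iter = 2,
                              seed = 77)
  hp <- fast_hp()
  mem <- fit_ensemble(sets, w$plots, tr, w$env, hp, seed = 5)
  expect_length(mem, 2)
  expect_s3_class(mem[[1]], "ensemble_member")
  mem2 <- fit_ensemble(sets[1], w$plots, tr, w$env, hp, seed = 5)
  x <- assemble(apply_rarefaction(sets[[1]], w$plots), tr, w$env)
  expect_identical(predict(mem[[1]]$model, x), predict(mem2[[1]]$model, x))
  expect_equal(mem[[1]]$roe$a, mem2[[1]]$roe$a)
  # the correction is fitted on the member's own training pairs
  y <- apply_rarefaction(sets[[1]], w$plots)$richness[attr(x, "kept")]
  bc <- fit_roe(y, predict(mem[[1]]$model, x))
  expect_equal(bc$a, mem[[1]]$roe$a)
  expect_equal(bc$b, mem[[1]]$roe$b)
})
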