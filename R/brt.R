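#' Hyperparameters for boosted regression tree fitting
#'
#' Defaults follow common practice for richness modelling: tree complexity
#' (interaction depth) 5, bag fraction 0.5, a geometric learning-rate grid
#' spanning 0.00025-0.1, and 10-fold cross-validated selection of the tree
#' count. The stepwise tree-count search grows trees until the CV deviance
#' has not improved for `block * patience` trees.
#'
#' @param tree_complexity Maximum interaction depth.
#' @param bag_fraction Per-stage subsampling rate (0, 1\].
#' @param learning_rates Candidate learning rates (positive). Default: 7
#'   geometric steps from 0.00025 to 0.1.
#' @param cv_folds Folds for the staging CV (>= 2).
#' @param max_trees Ceiling on the number of trees.
#' @param block,patience Stepwise stopping: stop when `block * patience`
#'   consecutive trees bring no CV improvement.
#' @param family Loss family: `"poisson"` (count deviance, default) or
#'   `"gaussian"` (squared error).
#' @param fixed_trees Skip the CV search and fit exactly this many trees at
#'   the single learning rate given (used for cross-validation refits that
#'   reuse already-selected hyperparameters).
#' @return A `brt_hyperparams` list.
#' @export
brt_hyperparams <- function(tree_complexity = 5, bag_fraction = 0.5,
                            learning_rates = exp(seq(log(0.00025), log(0.1),
                                                     length.out = 7)),
                            cv_folds = 10, max_trees = 1000,
                            block = 50, patience = 3,
                            family = c("poisson", "gaussian"),
                            fixed_trees = NULL) {
  family <- match.arg(family)
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag fraction must lie in (0, 1]")
  if (any(learning_rates <= 0)) stop("learning rates must be positive")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(tree_complexity = tree_complexity,
                 bag_fraction = bag_fraction,
                 learning_rates = learning_rates, cv_folds = cv_folds,
                 max_trees = max_trees, block = block, patience = patience,
                 family = family, fixed_trees = fixed_trees),
            class = "brt_hyperparams")
}

xgb_params <- function(hp, eta) {
  obj <- if (hp$family == "poisson") "count:poisson" else "reg:squarederror"
  list(objective = obj, eta = eta, max_depth = hp$tree_complexity,
       subsample = hp$bag_fraction, nthread = 1)
}

xgb_metric <- function(hp) {
  if (hp$family == "poisson") "poisson-nloglik" else "rmse"
}

null_deviance <- function(y, hp) {
  mu <- mean(y)
  if (hp$family == "poisson") mean(mu - y * log(max(mu, 1e-12)) + lgamma(y + 1))
  else sqrt(mean((y - mu)^2))
}

#' Fit a boosted regression tree richness model
#'
#' For each candidate learning rate, trees are grown in stages with
#' bag-fraction subsampling while the cross-validated deviance is tracked;
#' growth stops once `block * patience` additional trees bring no CV
#' improvement. The (learning rate, tree count) pair minimizing CV deviance
#' is selected and the final model refitted on all rows at that setting.
#' Deterministic given `seed`.
#'
#' @param x Predictor matrix ([assemble()] output or a numeric data frame).
#' @param y Response richness counts (non-negative).
#' @param hp [brt_hyperparams()].
#' @param seed Integer seed.
#' @return A `brt_model`: the booster, selected learning rate and tree
#'   count, feature names, categorical encoding, training column means and
#'   response summary, and the CV trace per candidate.
#' @export
fit_brt <- function(x, y, hp = brt_hyperparams(), seed = 1L) {
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  if (nrow(xm) < 10 * hp$cv_folds && is.null(hp$fixed_trees))
    stop("need at least 10 rows per CV fold")
  if (hp$family == "poisson" && any(y < 0))
    stop("richness response must be non-negative")
  dtrain <- xgboost::xgb.DMatrix(xm, label = y)
  metric <- xgb_metric(hp)
  mcol <- paste0("test_", gsub("-", "_", metric), "_mean")

  best <- NULL
  trace <- list()
  if (stats::var(y) == 0) {
    # constant response: no split can improve; fit the null model (one
    # stage, which leaves predictions at the base score = the constant)
    best <- list(eta = hp$learning_rates[1], n_trees = 1L, dev = NA_real_)
  } else if (is.null(hp$fixed_trees)) {
    for (eta in hp$learning_rates) {
      set.seed(child_seed(seed, "brt_cv", round(1e6 * eta)))
      cv <- xgboost::xgb.cv(params = xgb_params(hp, eta), data = dtrain,
                            nrounds = hp$max_trees, nfold = hp$cv_folds,
                            metrics = metric,
                            early_stopping_rounds = hp$block * hp$patience,
                            verbose = 0)
      el <- as.data.frame(cv$evaluation_log)
      dev <- el[[mcol]]
      k <- which.min(dev)
      trace[[as.character(eta)]] <- dev
      if (is.null(best) || dev[k] < best$dev) {
        best <- list(eta = eta, n_trees = k, dev = dev[k])
      }
    }
    nd <- null_deviance(y, hp)
    if (best$dev > nd * (1 + 0.01))
      stop(sprintf(
        "no learning rate improved on the null model (best CV %s %.4f vs null %.4f)",
        metric, best$dev, nd))
  } else {
    best <- list(eta = hp$learning_rates[1], n_trees = hp$fixed_trees,
                 dev = NA_real_)
  }

  set.seed(child_seed(seed, "brt_fit"))
  booster <- xgboost::xgb.train(params = xgb_params(hp, best$eta),
                                data = dtrain, nrounds = best$n_trees,
                                verbose = 0)
  structure(list(booster = booster, eta = best$eta, n_trees = best$n_trees,
                 cv_deviance = best$dev, cv_trace = trace,
                 feature_names = colnames(xm),
                 encoding = attr(x, "encoding"),
                 col_means = colMeans(xm),
                 col_range = apply(xm, 2, range),
                 response_mean = mean(y), hp = hp),
            class = "brt_model")
}

#' Predict from a fitted BRT model
#'
#' @param object A `brt_model`.
#' @param newdata Predictor rows with the model's feature columns.
#' @param ... Unused.
#' @return Predicted richness on the response scale (uncorrected).
#' @export
predict.brt_model <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                         drop = FALSE])
  storage.mode(xm) <- "double"
  stats::predict(object$booster, xgboost::xgb.DMatrix(xm))
}

#' Training deviance trace at a fixed learning rate
#'
#' Boosting decreases training deviance monotonically in the number of
#' trees; this helper exposes the per-stage trace for diagnostics.
#'
#' @param x,y Training data as in [fit_brt()].
#' @param hp [brt_hyperparams()]; the first learning rate is used.
#' @param n_trees Number of stages to trace.
#' @param seed Seed.
#' @return Numeric vector of training deviance per stage.
#' @export
training_deviance_trace <- function(x, y, hp = brt_hyperparams(),
                                    n_trees = 100, seed = 1L) {
  xm <- as.matrix(as.data.frame(x)); storage.mode(xm) <- "double"
  d <- xgboost::xgb.DMatrix(xm, label = y)
  set.seed(child_seed(seed, "brt_trace"))
  params <- c(xgb_params(hp, hp$learning_rates[1]),
              list(eval_metric = xgb_metric(hp)))
  bst <- xgboost::xgb.train(params = params, data = d, nrounds = n_trees,
                            evals = list(train = d), verbose = 0)
  el <- as.data.frame(attributes(bst)$evaluation_log)
  as.numeric(el[[2]])
}

#' Relative influence of predictors across an ensemble
#'
#' Per member, the split-improvement-weighted influence of each predictor,
#' normalized to sum to 100; summarized across members by the median and
#' the 2.5/97.5 percentiles. A predictor is flagged relevant when its
#' median influence exceeds the uniform expectation `100 / p`.
#'
#' @param members List of `ensemble_member`s (or `brt_model`s).
#' @return Data frame: predictor, median, q2.5, q97.5, relevant; sorted by
#'   median influence, with the threshold in attribute
#'   `relevance_threshold`.
#' @export
relative_influence <- function(members) {
  if (length(members) == 0) stop("need at least one member")
  models <- lapply(members, function(m)
    if (inherits(m, "ensemble_member")) m$model else m)
  feats <- models[[1]]$feature_names
  infl_list <- lapply(models, function(m) {
    # split-improvement-weighted influence, aggregated from the tree dump
    dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = m$booster))
    dt <- dt[dt$Feature != "Leaf", , drop = FALSE]
    if (nrow(dt) == 0 || sum(dt$Gain) <= 0)
      stop("member with zero total split improvement")
    gain <- tapply(dt$Gain, dt$Feature, sum)
    v <- stats::setNames(rep(0, length(feats)), feats)
    v[names(gain)] <- gain
    100 * v / sum(v)
  })
  infl <- matrix(unlist(infl_list), nrow = length(feats),
                 dimnames = list(feats, NULL))
  thr <- 100 / length(feats)
  out <- data.frame(
    predictor = feats,
    median = apply(infl, 1, stats::median),
    q2.5 = apply(infl, 1, stats::quantile, probs = 0.025),
    q97.5 = apply(infl, 1, stats::quantile, probs = 0.975)
  )
  out$relevant <- out$median > thr
  out <- out[order(-out$median), ]
  rownames(out) <- NULL
  attr(out, "relevance_threshold") <- thr
  attr(out, "per_member") <- infl
  out
}

#' Partial dependence of the fitted richness function on one predictor
#'
#' Evaluates the model on rows where every other predictor is held at its
#' training mean (categoricals at their reference level) while the target
#' predictor sweeps a grid; returned as the deviation from the mean
#' response, where the mean is taken over the training distribution of the
#' swept predictor. Grid points outside the training support are flagged as
#' extrapolation.
#'
#' @param member An `ensemble_member` or `brt_model`.
#' @param predictor Predictor (column) name.
#' @param grid Evaluation grid; default 50 points spanning the training
#'   range.
#' @param plot_size Optional conditioning grain: the plot-size column is
#'   fixed at this value instead of its mean.
#' @param fixed Optional named vector of conditioning values for other
#'   predictors (e.g. `c(plants_recorded = 3)` to evaluate the curve for
#'   complete-vegetation surveys instead of the categorical reference
#'   level).
#' @param training_values Training values of the swept predictor, used to
#'   centre the curve; defaults to 200 quantile points implied by the
#'   stored training range (pass the real training column for exactness).
#' @param bias_correct Apply the member's ROE correction to the absolute
#'   predictions (only for `ensemble_member`s).
#' @return Data frame `value`, `fitted` (deviation from mean response),
#'   `absolute` (response-scale prediction), `extrapolated`.
#' @export
partial_dependence <- function(member, predictor, grid = NULL,
                               plot_size = NULL, training_values = NULL,
                               bias_correct = FALSE, fixed = NULL) {
  model <- if (inherits(member, "ensemble_member")) member$model else member
  if (!predictor %in% model$feature_names)
    stop("unknown predictor: ", predictor)
  rng <- model$col_range[, predictor]
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 50)
  base <- model$col_means
  cats <- c("realm", "biome", "plants_recorded")
  base[intersect(cats, names(base))] <- 1 # reference level
  if ("formation" %in% names(base)) base["formation"] <- 0
  if (!is.null(plot_size)) base["plot_size_m2"] <- plot_size
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  eval_at <- function(v) {
    nd <- matrix(rep(base, each = length(v)), nrow = length(v),
                 dimnames = list(NULL, names(base)))
    nd[, predictor] <- v
    p <- predict.brt_model(model, nd)
    if (bias_correct && inherits(member, "ensemble_member"))
      p <- apply_roe(p, member$roe)
    p
  }
  if (is.null(training_values))
    training_values <- seq(rng[1], rng[2], length.out = 200)
  centre <- mean(eval_at(training_values))
  abs_pred <- eval_at(grid)
  data.frame(value = grid, fitted = abs_pred - centre, absolute = abs_pred,
             extrapolated = grid < rng[1] | grid > rng[2])
}

#' Fit the ROE bias correction
#'
#' Regression of observed on estimated values: the least-squares fit
#' `S_fit = a + b * S_obs` of the model's fitted values on the observed
#' richness. The coefficients invert systematic shrinkage of ensemble
#' predictions toward the sample mean.
#'
#' @param observed Observed richness (>= 2 distinct values; two points give
#'   the exact interpolating line).
#' @param fitted Model predictions for the same plots.
#' @return A `bias_correction`: `a` (intercept), `b` (slope).
#' @export
fit_roe <- function(observed, fitted) {
  if (length(observed) < 2) stop("need at least 2 points")
  if (stats::var(observed) == 0) stop("observed richness is constant")
  cf <- stats::coef(stats::lm(fitted ~ observed))
  if (abs(cf[2]) < 1e-12) stop("degenerate ROE fit: slope is zero")
  structure(list(a = unname(cf[1]), b = unname(cf[2])),
            class = "bias_correction")
}

#' Apply the ROE bias correction
#'
#' Corrected predictions are `max((fitted - a) / b, 0)`: the fitted ROE
#' line is inverted and floored at zero.
#'
#' @param fitted Uncorrected predictions.
#' @param bc A [fit_roe()] `bias_correction`.
#' @return Bias-corrected predictions (>= 0).
#' @export
apply_roe <- function(fitted, bc) {
  if (abs(bc$b) < 1e-12) stop("ROE slope is zero")
  pmax((fitted - bc$a) / bc$b, 0)
}

#' Fit the resampled BRT ensemble
#'
#' One member per resample set: the set is materialized (rarefaction
#' applied), assembled into a predictor matrix, a BRT fitted, and the ROE
#' correction estimated on the member's own training observed/fitted pairs.
#' Members are independent given their child seeds.
#'
#' @param sets List of `resample_set`s.
#' @param plots Full screened plot table.
#' @param transforms Climate/soil PCA transforms.
#' @param env The `env_grid`.
#' @param hp [brt_hyperparams()].
#' @param seed Master seed; member i uses child `(seed, "ensemble", i)`.
#' @return List of `ensemble_member`s: `iteration`, `model`, `roe`.
#' @export
fit_ensemble <- function(sets, plots, transforms, env,
                         hp = brt_hyperparams(), seed = 1L) {
  if (length(sets) == 0) stop("need at least one resample set")
  failed <- character()
  members <- lapply(sets, function(set) {
    res <- tryCatch({
      train <- apply_rarefaction(set, plots)
      x <- assemble(train, transforms, env)
      y <- train$richness[attr(x, "kept")]
      model <- fit_brt(x, y, hp, seed = child_seed(seed, "ensemble",
                                                   set$iteration))
      roe <- fit_roe(y, predict.brt_model(model, x))
      structure(list(iteration = set$iteration, model = model, roe = roe),
                class = "ensemble_member")
    }, error = function(e) e)
    res
  })
  errs <- vapply(members, inherits, logical(1), "error")
  if (any(errs))
    stop("ensemble members failed for iterations ",
         paste(vapply(sets[errs], `[[`, 1L, "iteration"), collapse = ", "),
         ": ", conditionMessage(members[errs][[1]]))
  members
}
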