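#' Build spatial blocks and an even fold assignment
#'
#' Tiles the plots' bounding box with square blocks of the given size
#' (anchored at the box's lower-left corner), then draws `n_assign` random
#' block-to-fold assignments and keeps the one with the smallest spread
#' (standard deviation) of per-fold plot counts. Deterministic given
#' `seed`.
#'
#' @param plots Plot table with `x`, `y` (km).
#' @param block_km Block edge length in km (> 0); typically the mean
#'   autocorrelation range from [autocorrelation_range()].
#' @param k Number of folds (>= 2).
#' @param n_assign Candidate assignments tried (default 99).
#' @param seed Seed.
#' @return A `block_fold_assignment`: `blocks` (data frame with origin,
#'   size, fold), `fold` (per-plot fold), `evenness` (chosen spread),
#'   `candidate_spreads`, `seed`.
#' @export
build_blocks <- function(plots, block_km, k = 5, n_assign = 99, seed = 1L) {
  if (block_km <= 0) stop("block size must be positive")
  if (k < 2) stop("need at least 2 folds")
  x0 <- min(plots$x); y0 <- min(plots$y)
  bx <- floor((plots$x - x0) / block_km)
  by <- floor((plots$y - y0) / block_km)
  key <- paste(bx, by)
  blocks <- unique(data.frame(bx = bx, by = by, key = key,
                              stringsAsFactors = FALSE))
  nb <- nrow(blocks)
  if (nb < k) stop("fewer non-empty blocks (", nb, ") than folds (", k, ")")
  counts <- table(key)[blocks$key]
  set.seed(child_seed(seed, "blockcv"))
  best <- NULL
  spreads <- numeric(n_assign)
  for (i in seq_len(n_assign)) {
    f <- sample(rep_len(seq_len(k), nb))
    per_fold <- vapply(seq_len(k),
                       function(j) sum(counts[f == j]), numeric(1))
    spreads[i] <- stats::sd(per_fold)
    if (is.null(best) || spreads[i] < best$spread)
      best <- list(fold = f, spread = spreads[i])
  }
  blocks$fold <- best$fold
  blocks$x0 <- x0 + blocks$bx * block_km
  blocks$y0 <- y0 + blocks$by * block_km
  structure(list(blocks = blocks[c("x0", "y0", "fold", "key")],
                 block_km = block_km, k = k,
                 fold = blocks$fold[match(key, blocks$key)],
                 evenness = best$spread, candidate_spreads = spreads,
                 seed = seed),
            class = "block_fold_assignment")
}

#' Random (non-spatial) fold assignment
#'
#' Baseline for comparison with spatially blocked folds: plots are assigned
#' to `k` folds at random, balanced in size.
#'
#' @param n Number of plots.
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer fold vector (1..k).
#' @export
random_folds <- function(n, k = 5, seed = 1L) {
  set.seed(child_seed(seed, "randomcv"))
  sample(rep_len(seq_len(k), n))
}

#' Cross-validate the richness model over a fold assignment
#'
#' For each fold, the BRT + ROE pipeline is refitted on the remaining
#' folds, the held-out plots are predicted at their own plot size (with
#' bias correction), and Pearson's correlation between observed and
#' predicted richness is computed. The pooled value is the mean over
#' folds. Folds with fewer than 3 test plots are skipped with a warning.
#'
#' @param plots Model-ready plot table (e.g. [apply_rarefaction()]
#'   output).
#' @param fold Per-plot fold vector (from [build_blocks()] `$fold` or
#'   [random_folds()]).
#' @param transforms,env As in [fit_ensemble()].
#' @param hp [brt_hyperparams()]; pass `fixed_trees` to reuse
#'   hyperparameters selected on the full training data.
#' @param seed Seed (fold f refits with child `(seed, "cvfold", f)`).
#' @param per_biome Also compute r within each biome's held-out plots.
#' @return List: `per_fold` (data frame fold, r, n), `pooled_r`,
#'   and `per_biome` (data frame) when requested.
#' @export
block_cross_validate <- function(plots, fold, transforms, env,
                                 hp = brt_hyperparams(), seed = 1L,
                                 per_biome = FALSE) {
  stopifnot(length(fold) == nrow(plots))
  folds <- sort(unique(fold))
  rows <- list(); biome_rows <- list()
  for (f in folds) {
    test <- plots[fold == f, , drop = FALSE]
    if (nrow(test) < 3) {
      warning("fold ", f, " has fewer than 3 test plots; skipped")
      next
    }
    train <- plots[fold != f, , drop = FALSE]
    xtr <- assemble(train, transforms, env)
    ytr <- train$richness[attr(xtr, "kept")]
    model <- fit_brt(xtr, ytr, hp, seed = child_seed(seed, "cvfold", f))
    roe <- fit_roe(ytr, predict.brt_model(model, xtr))
    xte <- assemble(test, transforms, env)
    yte <- test$richness[attr(xte, "kept")]
    pred <- apply_roe(predict.brt_model(model, xte), roe)
    rows[[length(rows) + 1]] <- data.frame(
      fold = f, r = stats::cor(yte, pred), n = length(yte))
    if (per_biome) {
      bio <- test$biome[attr(xte, "kept")]
      for (b in unique(bio)) {
        sel <- bio == b
        if (sum(sel) >= 3 && stats::var(yte[sel]) > 0 &&
            stats::var(pred[sel]) > 0)
          biome_rows[[length(biome_rows) + 1]] <- data.frame(
            fold = f, biome = b, r = stats::cor(yte[sel], pred[sel]),
            n = sum(sel))
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  out <- list(per_fold = per_fold, pooled_r = mean(per_fold$r))
  if (per_biome) out$per_biome <- do.call(rbind, biome_rows)
  out
}

#' Held-out correlation for one ensemble member
#'
#' Predicts every plot *not* used in the member's resample set at its own
#' plot size (with the member's ROE correction) and returns Pearson's
#' correlation with observed richness.
#'
#' @param set The member's `resample_set`.
#' @param plots Full screened plot table.
#' @param member The fitted `ensemble_member`.
#' @param transforms,env As in [fit_ensemble()].
#' @return List: `r` (`NA` with a note when predictions are constant),
#'   `n`.
#' @export
holdout_correlation <- function(set, plots, member, transforms, env) {
  comp <- plots[!(plots$plot_id %in% set$plot_id), , drop = FALSE]
  if (nrow(comp) < 3) stop("complement has fewer than 3 plots")
  x <- assemble(comp, transforms, env)
  y <- comp$richness[attr(x, "kept")]
  pred <- apply_roe(predict.brt_model(member$model, x), member$roe)
  if (stats::var(pred) == 0)
    return(list(r = NA_real_, n = length(y), note = "constant predictions"))
  list(r = stats::cor(y, pred), n = length(y))
}
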