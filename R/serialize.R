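#' Save / load a fitted ensemble as a text bundle
#'
#' Writes one JSON booster file (the native boosted-tree text format) and
#' one JSON metadata sidecar (selected learning rate and tree count, ROE
#' coefficients, feature names, categorical encodings, training column
#' summaries) per member, plus a bundle manifest.
#'
#' @param members List of `ensemble_member`s.
#' @param dir Bundle directory (created if needed).
#' @export
save_ensemble <- function(members, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(members)) {
    m <- members[[i]]
    stem <- file.path(dir, sprintf("member_%03d", i))
    xgboost::xgb.save(m$model$booster, paste0(stem, ".model.json"))
    meta <- list(
      iteration = m$iteration, eta = m$model$eta,
      n_trees = m$model$n_trees, family = m$model$hp$family,
      feature_names = m$model$feature_names,
      col_means = as.list(m$model$col_means),
      col_range = lapply(as.data.frame(m$model$col_range), identity),
      response_mean = m$model$response_mean,
      encoding = m$model$encoding,
      roe = list(a = m$roe$a, b = m$roe$b))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               paste0(stem, ".meta.json"))
  }
  writeLines(jsonlite::toJSON(list(n_members = length(members),
                                   format = "alphagrain-ensemble-1"),
                              auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @return `load_ensemble`: the list of `ensemble_member`s.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  lapply(seq_len(manifest$n_members), function(i) {
    stem <- file.path(dir, sprintf("member_%03d", i))
    meta <- jsonlite::fromJSON(paste0(stem, ".meta.json"))
    booster <- xgboost::xgb.load(paste0(stem, ".model.json"))
    model <- structure(list(
      booster = booster, eta = meta$eta, n_trees = meta$n_trees,
      cv_deviance = NA_real_, cv_trace = list(),
      feature_names = meta$feature_names,
      encoding = meta$encoding,
      col_means = unlist(meta$col_means),
      col_range = vapply(meta$col_range, identity, numeric(2)),
      response_mean = meta$response_mean,
      hp = brt_hyperparams(family = meta$family)), class = "brt_model")
    structure(list(iteration = meta$iteration, model = model,
                   roe = structure(list(a = meta$roe$a, b = meta$roe$b),
                                   class = "bias_correction")),
              class = "ensemble_member")
  })
}
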