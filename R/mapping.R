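#' Gridded multi-grain richness prediction
#'
#' For every ensemble member, assembles the pixel predictor matrix (plants
#' recorded fixed to 'complete vegetation', formation flag as requested,
#' plot-size column set to the target grain), predicts, and applies that
#' member's ROE correction. Masked pixels carry `NA`. A grain outside the
#' training plot-size range triggers an extrapolation warning but
#' prediction proceeds.
#'
#' @param members List of `ensemble_member`s.
#' @param env The `env_grid`.
#' @param grain Target sampling grain in m^2 (> 0).
#' @param formation `"forest"` or `"non-forest"`.
#' @param transforms Climate/soil PCA transforms.
#' @param mask Optional extra logical matrix; combined (AND) with the
#'   grid's own validity mask.
#' @return A `prediction_stack`: `grain`, `formation`, `grids` (list of
#'   per-member matrices), `mask`.
#' @export
predict_grid <- function(members, env, grain, formation, transforms,
                         mask = NULL) {
  stopifnot(grain > 0, length(members) >= 1)
  m <- env$mask
  if (!is.null(mask)) m <- m & mask
  rng <- members[[1]]$model$col_range[, "plot_size_m2"]
  if (grain < rng[1] || grain > rng[2])
    warning(sprintf("grain %g m^2 outside the training size range [%g, %g]",
                    grain, rng[1], rng[2]))
  idx <- which(m)
  rc <- arrayInd(idx, dim(m))
  xy <- cell_center_xy(env, rc[, 1], rc[, 2])
  pix <- data.frame(x = xy[, 1], y = xy[, 2])
  X <- assemble(pix, transforms, env, grain = grain, formation = formation,
                plants_recorded = "complete vegetation")
  grids <- lapply(members, function(mem) {
    g <- matrix(NA_real_, nrow(m), ncol(m))
    g[idx] <- apply_roe(predict.brt_model(mem$model, X), mem$roe)
    g
  })
  structure(list(grain = grain, formation = formation, grids = grids,
                 mask = m), class = "prediction_stack")
}

#' Reduce a prediction stack to median, IQR and relative uncertainty
#'
#' Pixelwise across members: the median; the interquartile range (75th
#' minus 25th percentile, linear-interpolation percentiles); and relative
#' uncertainty IQR/median, with zero-median pixels set to `NA` and counted.
#'
#' @param stack A [predict_grid()] `prediction_stack`.
#' @return List of matrices `median`, `iqr`, `rel_uncertainty`, plus
#'   `n_zero_median`.
#' @export
summarize_stack <- function(stack) {
  grids <- stack$grids
  dm <- dim(grids[[1]])
  idx <- which(stack$mask)
  P <- sapply(grids, function(g) g[idx])
  if (!is.matrix(P)) P <- matrix(P, nrow = length(idx))
  med <- iqr <- matrix(NA_real_, dm[1], dm[2])
  med[idx] <- apply(P, 1, stats::median)
  q <- apply(P, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
             type = 7)
  iqr[idx] <- q[2, ] - q[1, ]
  rel <- iqr / med
  zero <- !is.na(med) & med == 0
  rel[zero] <- NA_real_
  list(median = med, iqr = iqr, rel_uncertainty = rel,
       n_zero_median = sum(zero))
}

#' Hotspot and coldspot masks
#'
#' Hotspots are pixels strictly above the global `upper` percentile of
#' valid pixels; coldspots strictly below the `lower` percentile.
#' Percentiles use linear interpolation between order statistics, so the
#' cut values are reproducible bit-exact. On an all-constant grid both
#' masks are empty (strict inequality) with a warning.
#'
#' @param med Median richness grid (matrix; `NA` = nodata).
#' @param upper,lower Percentile cuts (defaults 0.95 / 0.05).
#' @return List: `hot`, `cold` (logical matrices, `NA` on nodata),
#'   `cuts` (the two cut values).
#' @export
hotspots <- function(med, upper = 0.95, lower = 0.05) {
  v <- med[!is.na(med)]
  if (length(v) < 20) stop("need at least 20 valid pixels")
  cuts <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
  if (cuts[1] == cuts[2])
    warning("grid is constant across valid pixels: no hotspots or coldspots")
  hot <- med > cuts[2]
  cold <- med < cuts[1]
  list(hot = hot, cold = cold, cuts = c(lower = cuts[1], upper = cuts[2]))
}

#' Bivariate quartile classification of fine vs coarse grain richness
#'
#' Each grid is cut at its own quartiles (25/50/75th percentiles of valid
#' pixels); every pixel receives a (fine-quartile, coarse-quartile) class
#' in a 4x4 grid. Pixels on a boundary go to the lower bin (right-open
#' convention). Scaling-anomaly summaries report the fraction of valid
#' pixels in the two off-diagonal corners.
#'
#' @param fine,coarse Median richness grids at the fine and coarse grain
#'   (same shape and mask).
#' @return A `bivariate_class_map`: `class` (matrix, 1..16 =
#'   `(fine_bin - 1) * 4 + coarse_bin`), `fine_bin`, `coarse_bin`,
#'   `cuts_fine`, `cuts_coarse`, and anomaly fractions
#'   `frac_fine_high_coarse_low`, `frac_fine_low_coarse_high`.
#' @export
scaling_anomalies <- function(fine, coarse) {
  if (!identical(dim(fine), dim(coarse)))
    stop("fine and coarse grids must share shape")
  if (!identical(is.na(fine), is.na(coarse)))
    stop("fine and coarse grids must share mask")
  bin <- function(g) {
    cuts <- stats::quantile(g[!is.na(g)], c(0.25, 0.5, 0.75),
                            names = FALSE, type = 7)
    b <- 1L + (g > cuts[1]) + (g > cuts[2]) + (g > cuts[3])
    list(bin = b, cuts = cuts)
  }
  bf <- bin(fine); bc <- bin(coarse)
  cls <- (bf$bin - 1L) * 4L + bc$bin
  valid <- !is.na(cls)
  structure(list(
    class = cls, fine_bin = bf$bin, coarse_bin = bc$bin,
    cuts_fine = bf$cuts, cuts_coarse = bc$cuts,
    frac_fine_high_coarse_low = sum(bf$bin == 4 & bc$bin == 1, na.rm = TRUE) /
      sum(valid),
    frac_fine_low_coarse_high = sum(bf$bin == 1 & bc$bin == 4, na.rm = TRUE) /
      sum(valid)
  ), class = "bivariate_class_map")
}

#' Data-poor (ignorance) mask
#'
#' Flags every pixel whose centre lies farther than `max_dist_km` from the
#' nearest calibration plot. Distances are Euclidean in planar mode and
#' great-circle (haversine) in lon/lat mode.
#'
#' @param plots Plot table with `x`, `y` (km, planar) or `lon`, `lat`.
#' @param env The `env_grid`.
#' @param max_dist_km Distance threshold (default 500 km).
#' @return Logical matrix: `TRUE` = data-poor. All-`TRUE` with a warning
#'   when no plots are given.
#' @export
ignorance_mask <- function(plots, env, max_dist_km = 500) {
  nr <- nrow(env$mask); nc <- ncol(env$mask)
  if (nrow(plots) == 0) {
    warning("no plots: every pixel is data-poor")
    return(matrix(TRUE, nr, nc))
  }
  mode <- attr(plots, "coord_mode")
  if (!is.null(mode) && !identical(mode, env$coord_mode))
    stop("plot and grid coordinate modes differ")
  idx <- seq_len(nr * nc)
  rc <- arrayInd(idx, c(nr, nc))
  xy <- cell_center_xy(env, rc[, 1], rc[, 2])
  if (identical(env$coord_mode, "lonlat")) {
    d <- geosphere::distm(xy, cbind(plots$x, plots$y)) / 1000
    dmin <- apply(d, 1, min)
  } else {
    dmin <- rep(Inf, nr * nc)
    for (i in seq_len(nrow(plots))) {
      di <- sqrt((xy[, 1] - plots$x[i])^2 + (xy[, 2] - plots$y[i])^2)
      dmin <- pmin(dmin, di)
    }
  }
  matrix(dmin > max_dist_km, nr, nc)
}
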