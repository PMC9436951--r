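#' Empirical semivariogram from point data
#'
#' All-pairs estimator: for every point pair the squared difference of
#' values over two, averaged within lag bins. Bins are log-spaced (or
#' linear) up to `max_lag` (default: half the maximum pairwise distance).
#'
#' @param x,y Point coordinates (km in planar mode).
#' @param values Values at the points.
#' @param n_bins Number of lag bins (default 15).
#' @param max_lag Largest lag considered; default half the maximum
#'   pairwise distance.
#' @param log_bins Log-spaced bin edges (default `TRUE`).
#' @return Data frame: `lag` (mean pair distance in the bin), `gamma`
#'   (semivariance), `n_pairs`; attribute `max_lag`.
#' @export
empirical_variogram <- function(x, y, values, n_bins = 15, max_lag = NULL,
                                log_bins = TRUE) {
  n <- length(values)
  if (n < 2) stop("need at least 2 points")
  d <- stats::dist(cbind(x, y))
  g <- stats::dist(values)^2 / 2
  dmax <- max(d)
  if (is.null(max_lag)) max_lag <- dmax / 2
  keep <- d > 0 & d <= max_lag
  d <- d[keep]; g <- g[keep]
  lo <- max(min(d), max_lag * 1e-4)
  edges <- if (log_bins) exp(seq(log(lo), log(max_lag), length.out = n_bins + 1))
           else seq(0, max_lag, length.out = n_bins + 1)
  edges[1] <- 0
  bin <- cut(d, edges, labels = FALSE, include.lowest = TRUE)
  ok <- !is.na(bin)
  lag <- tapply(d[ok], bin[ok], mean)
  gam <- tapply(g[ok], bin[ok], mean)
  npair <- tapply(g[ok], bin[ok], length)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gam),
                    n_pairs = as.integer(npair))
  attr(out, "max_lag") <- max_lag
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget + partial-sill models by pair-count-weighted least squares
#' (`minpack.lm`). Exponential: `gamma(h) = nugget + psill (1 - exp(-h/r))`
#' with effective range `3 r` (the 95%-of-sill convention); spherical: the
#' standard form with its range parameter used directly as the effective
#' range.
#'
#' @param vg An [empirical_variogram()] data frame.
#' @param family `"exponential"` (default) or `"spherical"`.
#' @return A `variogram_fit`: family, nugget, psill, range parameter,
#'   `effective_range`, the binned variogram, `converged`, and
#'   `pure_nugget` (effective range within one bin width, i.e. no usable
#'   spatial structure).
#' @export
fit_variogram <- function(vg, family = c("exponential", "spherical")) {
  family <- match.arg(family)
  if (all(vg$gamma == 0))
    return(structure(list(family = family, nugget = 0, psill = 0,
                          range_par = NA_real_, effective_range = NA_real_,
                          variogram = vg, converged = FALSE,
                          pure_nugget = TRUE, degenerate = TRUE),
                     class = "variogram_fit"))
  # near-flat variogram: short-lag semivariance already at the sill level
  # (pair-weighted, so sparse first bins cannot dominate) -- no spatial
  # structure beyond one bin width
  n3 <- max(1L, nrow(vg) %/% 3L)
  short_idx <- seq_len(n3)
  long_idx <- seq.int(nrow(vg) - n3 + 1L, nrow(vg))
  g_short <- stats::weighted.mean(vg$gamma[short_idx], vg$n_pairs[short_idx])
  g_long <- stats::weighted.mean(vg$gamma[long_idx], vg$n_pairs[long_idx])
  if (g_short > 0.9 * g_long)
    return(structure(list(family = family, nugget = mean(vg$gamma),
                          psill = 0, range_par = 0, effective_range = 0,
                          variogram = vg, converged = TRUE,
                          pure_nugget = TRUE, degenerate = FALSE),
                     class = "variogram_fit"))
  sill0 <- max(mean(vg$gamma[vg$lag > stats::median(vg$lag)]), 1e-10)
  start <- list(nugget = max(min(vg$gamma), 1e-10),
                psill = max(sill0 - min(vg$gamma), 1e-10),
                r = max(vg$lag) / 6)
  model_fun <- if (family == "exponential") {
    function(h, nugget, psill, r) nugget + psill * (1 - exp(-h / r))
  } else {
    function(h, nugget, psill, r) {
      s <- pmin(h / r, 1)
      nugget + psill * (1.5 * s - 0.5 * s^3)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(gamma ~ model_fun(lag, nugget, psill, r), data = vg,
                      start = start, weights = vg$n_pairs,
                      lower = c(0, 0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(family = family, nugget = NA_real_,
                          psill = NA_real_, range_par = NA_real_,
                          effective_range = NA_real_, variogram = vg,
                          converged = FALSE, pure_nugget = NA,
                          degenerate = FALSE),
                     class = "variogram_fit"))
  cf <- stats::coef(fit)
  eff <- if (family == "exponential") 3 * cf[["r"]] else cf[["r"]]
  bin_width <- attr(vg, "max_lag") / nrow(vg)
  structure(list(family = family, nugget = cf[["nugget"]],
                 psill = cf[["psill"]], range_par = cf[["r"]],
                 effective_range = unname(eff), variogram = vg,
                 converged = TRUE,
                 pure_nugget = eff <= bin_width ||
                   cf[["psill"]] < 0.05 * (cf[["nugget"]] + cf[["psill"]]),
                 degenerate = FALSE),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("variogram (%s): nugget %.4g, psill %.4g, effective range %.4g%s\n",
              x$family, x$nugget, x$psill, x$effective_range,
              if (isTRUE(x$pure_nugget)) " [pure nugget]" else ""))
  invisible(x)
}

#' Mean spatial autocorrelation range of the quantitative covariates
#'
#' For each covariate, samples `n_samples` random points (cells of a grid,
#' or rows of a plot table), estimates the empirical semivariogram, fits
#' the variogram model and takes the effective range. Covariates whose fit
#' diverges are reported unfitted and excluded from the mean with a
#' warning.
#'
#' @param env An `env_grid` (its `layers` are used) or a named list of
#'   matrices.
#' @param n_samples Random sample size per covariate (default 5000).
#' @param seed Seed.
#' @param n_bins,family Passed to the variogram machinery.
#' @return List: `per_covariate` (data frame with `covariate`,
#'   `effective_range`, `converged`, `pure_nugget`), `mean_range` (over
#'   converged fits).
#' @export
autocorrelation_range <- function(env, n_samples = 5000, seed = 1L,
                                  n_bins = 15,
                                  family = c("exponential", "spherical")) {
  family <- match.arg(family)
  layers <- if (inherits(env, "env_grid")) env$layers else env
  cell_km <- if (inherits(env, "env_grid")) env$cell_km else 1
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  # one shared set of sample locations across covariates
  set.seed(child_seed(seed, "acrange"))
  idx <- sample.int(nr * nc, min(n_samples, nr * nc))
  rc <- arrayInd(idx, c(nr, nc))
  res <- lapply(names(layers), function(nm) {
    vg <- empirical_variogram(rc[, 2] * cell_km, (nr - rc[, 1]) * cell_km,
                              layers[[nm]][idx], n_bins = n_bins)
    fit_variogram(vg, family)
  })
  per <- data.frame(
    covariate = names(layers),
    effective_range = vapply(res, `[[`, numeric(1), "effective_range"),
    converged = vapply(res, `[[`, logical(1), "converged"),
    pure_nugget = vapply(res, function(f) isTRUE(f$pure_nugget), logical(1))
  )
  if (any(!per$converged))
    warning("variogram fit did not converge for: ",
            paste(per$covariate[!per$converged], collapse = ", "))
  list(per_covariate = per,
       mean_range = mean(per$effective_range[per$converged], na.rm = TRUE),
       fits = res)
}

#' Variogram of model residuals
#'
#' Spatial-autocorrelation diagnostic for (observed - predicted) richness,
#' using the same binning and fitting machinery as
#' [autocorrelation_range()]. All-zero residuals are flagged degenerate
#' and not fitted.
#'
#' @param observed,predicted Richness vectors.
#' @param x,y Plot coordinates.
#' @param n_bins,family As in [fit_variogram()].
#' @return A `variogram_fit`.
#' @export
residual_variogram <- function(observed, predicted, x, y, n_bins = 15,
                               family = c("exponential", "spherical")) {
  if (length(observed) < 100) stop("need at least 100 points")
  r <- observed - predicted
  vg <- empirical_variogram(x, y, r, n_bins = n_bins)
  fit_variogram(vg, match.arg(family))
}
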