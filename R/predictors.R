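#' Fit a standardizing principal component analysis
#'
#' Columns are centred and scaled to unit variance before decomposition.
#' The number of retained components is either fixed, or the smallest k
#' whose cumulative variance fraction reaches `var_threshold`.
#'
#' @param x Data frame or matrix of covariates (>= 2 rows; no constant
#'   columns).
#' @param var_threshold Cumulative variance fraction to reach (default
#'   0.90).
#' @param n_components Fixed number of components (overrides the
#'   threshold).
#' @return A `pca_transform`: covariate names, means, sds, loading matrix,
#'   per-component variance fractions, number retained.
#' @export
fit_pca <- function(x, var_threshold = 0.90, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 1) stop("need >= 2 rows and >= 1 column")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_components)) as.integer(n_components)
       else which(cumsum(var_frac) >= var_threshold)[1]
  structure(list(names = colnames(x), means = pc$center, sds = pc$scale,
                 rotation = pc$rotation, var_frac = var_frac,
                 n_retained = k),
            class = "pca_transform")
}

#' Project covariates through a fitted PCA
#'
#' @param transform A [fit_pca()] transform.
#' @param x New covariate rows (same columns as the training table).
#' @param all_components Keep all components instead of the retained ones.
#' @return Score matrix (rows x components).
#' @export
pca_project <- function(transform, x, all_components = FALSE) {
  x <- as.matrix(x)[, transform$names, drop = FALSE]
  z <- sweep(sweep(x, 2, transform$means), 2, transform$sds, "/")
  s <- z %*% transform$rotation
  if (all_components) s
  else s[, seq_len(transform$n_retained), drop = FALSE]
}

#' Fit the climate and soil PCAs on a grid's valid cells
#'
#' Convenience wrapper: extracts the covariate table over all valid cells
#' of the grid and fits one PCA for the climate block and one for the soil
#' block. Retained component counts default to 5 (climate) and 4 (soil),
#' the configuration used for the full predictor set; pass `NULL` to use
#' the variance threshold instead.
#'
#' @param env An `env_grid`.
#' @param n_climate,n_soil Fixed retained component counts (or `NULL`).
#' @param var_threshold Cumulative variance threshold when counts are
#'   `NULL`.
#' @return List with `climate` and `soil` [fit_pca()] transforms.
#' @export
fit_covariate_pcas <- function(env, n_climate = 5, n_soil = 4,
                               var_threshold = 0.90) {
  cells <- which(env$mask)
  tab <- sapply(env$layers, function(L) L[cells])
  clim <- tab[, names(env$roles)[env$roles == "climate"], drop = FALSE]
  soil <- tab[, names(env$roles)[env$roles == "soil"], drop = FALSE]
  list(climate = fit_pca(clim, var_threshold, n_climate),
       soil = fit_pca(soil, var_threshold, n_soil))
}

# documented level orders for ordinal-encoded categorical predictors;
# trees split on these, and splits are invariant to monotone recoding
PLANTS_LEVELS <- c("trees only", "trees and shrubs only",
                   "complete vegetation")

predictor_encoding <- function(env) {
  list(realm = env$realm_levels, biome = env$biome_levels,
       plants_recorded = PLANTS_LEVELS, formation = c("non-forest", "forest"))
}

#' Assemble the grain-aware predictor matrix
#'
#' Samples the environmental layers at each row's containing cell (no
#' interpolation), projects the climate and soil blocks through their PCAs,
#' passes topography/velocity layers through, adds the species pool, the
#' ordinal-encoded categorical predictors (realm, biome, plants recorded,
#' formation), and the plot-size column. Rows falling outside the grid or on
#' masked cells are dropped with a count stored in the `n_dropped`
#' attribute. Deterministic and order-preserving.
#'
#' @param rows Plot table (columns `x`, `y`, `area_m2`, `realm`, `biome`,
#'   `formation`, `plants_recorded`) or pixel table (`x`, `y` only, with
#'   overrides below).
#' @param transforms List with elements `climate` and `soil`
#'   ([fit_pca()] transforms).
#' @param env The `env_grid`.
#' @param grain Plot-size override in m^2 for prediction rows (otherwise
#'   each row's own `area_m2`).
#' @param formation Formation override (`"forest"`/`"non-forest"`) for
#'   prediction rows.
#' @param plants_recorded Completeness override for prediction rows
#'   (predictions are made for `"complete vegetation"`).
#' @return A numeric `predictor_matrix` (data frame) with attributes
#'   `encoding`, `quantitative` (column names treated as quantitative) and
#'   `n_dropped`.
#' @export
assemble <- function(rows, transforms, env, grain = NULL, formation = NULL,
                     plants_recorded = NULL) {
  rc <- locate_cell(env, rows$x, rows$y)
  ok <- !is.na(rc[, 1]) & env$mask[cbind(pmax(rc[, 1], 1L), pmax(rc[, 2], 1L))]
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) outside the grid or on masked cells dropped")
  rows <- rows[ok, , drop = FALSE]
  cell <- rc[ok, , drop = FALSE]

  cov_mat <- sapply(env$layers, function(L) L[cell])
  if (!is.matrix(cov_mat)) cov_mat <- matrix(cov_mat, nrow = 1,
                                             dimnames = list(NULL, names(env$layers)))
  clim <- pca_project(transforms$climate, cov_mat)
  soil <- pca_project(transforms$soil, cov_mat[, transforms$soil$names,
                                               drop = FALSE])
  colnames(clim) <- paste0("clim_PC", seq_len(ncol(clim)))
  colnames(soil) <- paste0("soil_PC", seq_len(ncol(soil)))
  pass <- cov_mat[, setdiff(colnames(cov_mat),
                            c(transforms$climate$names,
                              transforms$soil$names)), drop = FALSE]

  enc <- predictor_encoding(env)
  realm <- if (is.null(rows$realm)) env$realm_levels[env$realm[cell]]
           else rows$realm
  biome <- if (is.null(rows$biome)) env$biome_levels[env$biome[cell]]
           else rows$biome
  form <- if (!is.null(formation)) rep(formation, nrow(rows))
          else rows$formation
  pl <- if (!is.null(plants_recorded)) rep(plants_recorded, nrow(rows))
        else rows$plants_recorded
  size <- if (!is.null(grain)) rep(grain, nrow(rows)) else rows$area_m2

  out <- data.frame(clim, soil, pass,
                    realm = match(realm, enc$realm),
                    biome = match(biome, enc$biome),
                    species_pool = env$pool[cell],
                    formation = match(form, enc$formation) - 1L,
                    plants_recorded = match(pl, enc$plants_recorded),
                    plot_size_m2 = size)
  if (anyNA(out)) stop("predictor matrix contains missing values")
  attr(out, "encoding") <- enc
  attr(out, "quantitative") <- c(colnames(clim), colnames(soil),
                                 colnames(pass), "species_pool",
                                 "plot_size_m2")
  attr(out, "n_dropped") <- n_dropped
  attr(out, "kept") <- ok
  class(out) <- c("predictor_matrix", "data.frame")
  out
}

#' Maximum absolute pairwise correlation among quantitative predictors
#'
#' @param x A `predictor_matrix` (or any data frame; the `quantitative`
#'   attribute, when present, restricts the columns).
#' @return List: `max_abs_r`, `pair` (the offending column pair, `NULL`
#'   when fewer than two quantitative columns), `n_pairs`.
#' @export
collinearity_report <- function(x) {
  q <- attr(x, "quantitative")
  cols <- if (!is.null(q)) q else
    names(x)[vapply(x, is.numeric, logical(1))]
  m <- as.matrix(as.data.frame(x)[cols])
  if (ncol(m) < 2)
    return(list(max_abs_r = NA_real_, pair = NULL, n_pairs = 0L))
  r <- stats::cor(m)
  diag(r) <- 0
  i <- which.max(abs(r))
  rc <- arrayInd(i, dim(r))
  list(max_abs_r = abs(r[i]),
       pair = c(cols[rc[1, 1]], cols[rc[1, 2]]),
       n_pairs = (ncol(m) * (ncol(m) - 1L)) %/% 2L)
}
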