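#' Configuration of a synthetic plot-survey world
#'
#' Defines the landscape and sampling model used by the synthetic-world
#' generator: a rectangular grid of spatially autocorrelated environmental
#' covariates, a Voronoi partition into ecoregions each carrying a regional
#' species pool, and a power-law species-area relationship (SAR)
#' \eqn{S = c(x)\,(A/A_0)^z} whose local coefficient
#' \eqn{c(x) = \exp(\beta \cdot \mathrm{cov}(x) + \gamma \log \mathrm{pool}(x))}
#' is modulated by the covariates and the ecoregional pool.
#'
#' Covariates are generated in four blocks mirroring the predictor families
#' used for richness modelling: climate-like, soil-like, topography-like and
#' climate-velocity-like layers. The default block sizes (6, 5, 3, 2) allow a
#' 20-column predictor matrix (5 climate PCs + 4 soil PCs + 3 topography +
#' 2 velocity + realm + biome + species pool + formation + plants-recorded +
#' plot size) as used for the full analysis.
#'
#' @param nrow,ncol Grid dimensions (cells).
#' @param cell_km Cell edge length in km.
#' @param n_climate,n_soil,n_topo,n_velocity Number of covariate layers per
#'   block.
#' @param range_km Target effective autocorrelation range of the covariate
#'   fields in km (distance at which the semivariogram reaches ~95% of its
#'   sill). Recycled over layers.
#' @param n_ecoregions Number of ecoregions (Voronoi cells of random seeds).
#' @param n_realms Number of realm bands (west-east).
#' @param n_biomes Number of biome bands (north-south).
#' @param z SAR exponent (dimensionless, >= 0).
#' @param A0 Reference plot area in m^2.
#' @param beta Log-richness coefficients on the (standardized) covariates;
#'   recycled/zero-padded to the total number of covariate layers.
#' @param gamma Species-pool effect: coefficient on log(pool).
#' @param dispersion Negative-binomial size parameter of observation noise on
#'   richness counts; `Inf` switches noise off (counts = rounded expectation).
#' @param mask_fraction Fraction of cells masked invalid (contiguous blobs).
#' @param pool_meanlog,pool_sdlog Log-normal parameters of ecoregion species
#'   pools.
#' @param seed Master seed; all stochastic operations derive child seeds from
#'   it (see [child_seed()]).
#' @return An object of class `world_config` (a validated list).
#' @export
world_config <- function(nrow = 100, ncol = 100, cell_km = 2,
                         n_climate = 6, n_soil = 5, n_topo = 3, n_velocity = 2,
                         range_km = 40, n_ecoregions = 12,
                         n_realms = 2, n_biomes = 4,
                         z = 0.25, A0 = 100,
                         beta = c(0.35, -0.25, 0.2, 0.15, -0.1),
                         gamma = 0.3, dispersion = 10,
                         mask_fraction = 0.05,
                         pool_meanlog = log(500), pool_sdlog = 0.4,
                         seed = 1L) {
  if (nrow < 1 || ncol < 1) stop("grid shape must be positive")
  if (cell_km <= 0) stop("cell size must be positive")
  if (z < 0) stop("SAR exponent z must be >= 0")
  if (A0 <= 0) stop("reference area A0 must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  n_cov <- n_climate + n_soil + n_topo + n_velocity
  if (n_cov < 1) stop("at least one covariate layer is required")
  range_km <- rep_len(range_km, n_cov)
  if (any(range_km <= 0)) stop("autocorrelation range must be positive")
  beta <- rep_len(c(beta, rep(0, max(0, n_cov - length(beta)))), n_cov)
  structure(list(
    nrow = as.integer(nrow), ncol = as.integer(ncol), cell_km = cell_km,
    n_climate = as.integer(n_climate), n_soil = as.integer(n_soil),
    n_topo = as.integer(n_topo), n_velocity = as.integer(n_velocity),
    range_km = range_km, n_ecoregions = as.integer(n_ecoregions),
    n_realms = as.integer(n_realms), n_biomes = as.integer(n_biomes),
    z = z, A0 = A0, beta = beta, gamma = gamma, dispersion = dispersion,
    mask_fraction = mask_fraction,
    pool_meanlog = pool_meanlog, pool_sdlog = pool_sdlog,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Derive a reproducible child seed
#'
#' One master seed drives the whole pipeline; each stochastic operation
#' derives its own seed from (master, operation name, index) so that stages
#' are independently reproducible.
#'
#' @param master Master seed (integer).
#' @param op Operation name (character scalar).
#' @param index Iteration index (integer, default 0).
#' @return An integer seed in \[0, 2^31).
#' @export
child_seed <- function(master, op, index = 0L) {
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(master) * 97 + h * 131 + as.numeric(index) * 7919) %%
               2147483629)
}

# Effective range is reported downstream by fitting an exponential
# variogram (95%-of-sill at 3x its scale). A Gaussian-correlation field --
# which kernel smoothing produces -- is read by that estimator as having a
# longer range than its own 95%-decorrelation distance. The generator
# therefore calibrates the kernel bandwidth numerically: find sigma such
# that the theoretical variogram of the smoothed field, fitted with the
# same binning/weighting conventions as the estimator, returns the
# requested effective range.
calibrate_smoothing_sigma <- function(range_km, max_lag, n_bins = 15) {
  fitted_range <- function(sigma) {
    edges <- exp(seq(log(max_lag * 1e-3), log(max_lag),
                     length.out = n_bins + 1))
    h <- sqrt(edges[-1] * edges[-(n_bins + 1)])
    g <- 1 - exp(-h^2 / (4 * sigma^2))
    w <- h^2 # pair counts grow ~ h * bin width, and width ~ h for log bins
    f <- tryCatch(
      minpack.lm::nlsLM(g ~ n + p * (1 - exp(-h / r)),
                        start = list(n = 1e-3, p = 1, r = sigma),
                        weights = w, lower = c(0, 0, 1e-9)),
      error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    3 * stats::coef(f)[["r"]]
  }
  direct <- range_km / (2 * sqrt(log(20))) # 95%-decorrelation mapping
  obj <- function(s) fitted_range(s) - range_km
  lo <- direct / 4; hi <- direct * 2
  flo <- obj(lo); fhi <- obj(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(direct)
  stats::uniroot(obj, c(lo, hi), tol = direct * 1e-3)$root
}

# Gaussian-kernel smoothing of a white-noise field. Smoothing white noise
# with a kernel of sd `sigma` (cells) yields correlation exp(-d^2 / (4 sigma^2)),
# so the 95%-decorrelation distance is 2*sigma*sqrt(log(20)) cells.
smooth_field <- function(nrow, ncol, sigma_cells) {
  half <- max(1L, ceiling(4 * sigma_cells))
  ker <- stats::dnorm(seq(-half, half), sd = max(sigma_cells, 1e-8))
  ker <- ker / sum(ker)
  pad_r <- nrow + 2L * half
  pad_c <- ncol + 2L * half
  z <- matrix(stats::rnorm(pad_r * pad_c), pad_r, pad_c)
  z <- apply(z, 2, function(col) stats::convolve(col, ker, type = "open"))
  z <- t(apply(z, 1, function(row) stats::convolve(row, ker, type = "open")))
  off <- 2L * half # convolve("open") adds half on each side again
  z <- z[off + seq_len(nrow), off + seq_len(ncol), drop = FALSE]
  (z - mean(z)) / stats::sd(z)
}

#' Generate the synthetic environmental grid
#'
#' Builds the covariate stack (smoothed Gaussian noise with the configured
#' autocorrelation ranges), a contiguous ecoregion partition (nearest random
#' seed), a species-pool layer constant within ecoregions, realm/biome band
#' layers, and a validity mask. Deterministic given `config$seed`.
#'
#' @param config A [world_config()].
#' @return An object of class `env_grid`: list with `layers` (named list of
#'   matrices), `roles` (character vector: climate/soil/topography/velocity),
#'   `ecoregion`, `pool`, `realm`, `biome` (matrices), `mask` (logical
#'   matrix), `cell_km`, `coord_mode = "planar"`, and level tables for realm
#'   and biome. Row 1 is the top (north) edge; x increases eastward.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$nrow; nc <- config$ncol
  n_cov <- length(config$range_km)
  roles <- rep(c("climate", "soil", "topography", "velocity"),
               c(config$n_climate, config$n_soil, config$n_topo,
                 config$n_velocity))
  prefix <- c(climate = "clim", soil = "soil", topography = "topo",
              velocity = "vel")[roles]
  nm <- paste0(prefix, "_", stats::ave(seq_len(n_cov), roles, FUN = seq_along))
  max_lag <- sqrt((nr * config$cell_km)^2 + (nc * config$cell_km)^2) / 2
  sigma_km <- vapply(unique(config$range_km), calibrate_smoothing_sigma,
                     numeric(1), max_lag = max_lag)
  names(sigma_km) <- as.character(unique(config$range_km))
  layers <- vector("list", n_cov)
  for (j in seq_len(n_cov)) {
    set.seed(child_seed(config$seed, "covariate", j))
    sigma <- sigma_km[[as.character(config$range_km[j])]] / config$cell_km
    layers[[j]] <- smooth_field(nr, nc, sigma)
  }
  names(layers) <- nm
  names(roles) <- nm

  # ecoregions: nearest-seed partition (contiguous by construction)
  set.seed(child_seed(config$seed, "ecoregions"))
  cx <- stats::runif(config$n_ecoregions, 0.5, nc + 0.5)
  cy <- stats::runif(config$n_ecoregions, 0.5, nr + 0.5)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rowm <- matrix(rep(seq_len(nr), nc), nr, nc)
  d2 <- sapply(seq_len(config$n_ecoregions),
               function(k) (colm - cx[k])^2 + (rowm - cy[k])^2)
  eco <- matrix(max.col(-d2, ties.method = "first"), nr, nc)

  set.seed(child_seed(config$seed, "pool"))
  pools <- pmax(50, round(stats::rlnorm(config$n_ecoregions,
                                        config$pool_meanlog,
                                        config$pool_sdlog)))
  pool <- matrix(pools[eco], nr, nc)

  # realm = west-east bands, biome = north-south bands
  realm_levels <- paste0("realm_", LETTERS[seq_len(config$n_realms)])
  biome_levels <- paste0("biome_", seq_len(config$n_biomes))
  realm <- matrix(pmin(config$n_realms,
                       1L + (colm - 1L) %/% ceiling(nc / config$n_realms)),
                  nr, nc)
  biome <- matrix(pmin(config$n_biomes,
                       1L + (rowm - 1L) %/% ceiling(nr / config$n_biomes)),
                  nr, nc)

  mask <- matrix(TRUE, nr, nc)
  if (config$mask_fraction > 0) {
    set.seed(child_seed(config$seed, "mask"))
    f <- smooth_field(nr, nc, max(2, 10 / config$cell_km))
    mask <- f > stats::quantile(f, config$mask_fraction)
  }

  structure(list(layers = layers, roles = roles, ecoregion = eco,
                 pool = pool, realm = realm, biome = biome, mask = mask,
                 realm_levels = realm_levels, biome_levels = biome_levels,
                 cell_km = config$cell_km, coord_mode = "planar"),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells (%g km), %d covariates, %d ecoregions, %d%% valid\n",
              nrow(x$mask), ncol(x$mask), x$cell_km, length(x$layers),
              max(x$ecoregion), round(100 * mean(x$mask))))
  invisible(x)
}

# grid coordinate helpers: planar km, cell centers; row 1 = top
cell_center_xy <- function(env, row, col) {
  nr <- nrow(env$mask)
  cbind(x = (col - 0.5) * env$cell_km, y = (nr - row + 0.5) * env$cell_km)
}

locate_cell <- function(env, x, y) {
  nr <- nrow(env$mask); nc <- ncol(env$mask)
  col <- ceiling(x / env$cell_km)
  row <- nr - ceiling(y / env$cell_km) + 1L
  bad <- col < 1 | col > nc | row < 1 | row > nr |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Expected richness under the synthetic species-area relationship
#'
#' \eqn{S = \exp(\beta \cdot \mathrm{cov} + \gamma \log \mathrm{pool})
#' \cdot (A/A_0)^z}: a power-law SAR whose coefficient is modulated by the
#' local environment and the regional species pool. Strictly increasing in
#' area whenever `z > 0`.
#'
#' @param area Plot area(s) in m^2 (> 0).
#' @param covariates Numeric vector (one cell) or matrix (rows = cells) of
#'   covariate values, matching `config$beta` in length/columns.
#' @param pool Ecoregional species pool count(s).
#' @param config A [world_config()].
#' @return Expected richness (real, not rounded).
#' @export
true_richness <- function(area, covariates, pool, config) {
  if (any(area <= 0)) stop("area must be positive")
  if (is.null(dim(covariates))) covariates <- matrix(covariates, nrow = 1)
  lin <- drop(covariates %*% config$beta) + config$gamma * log(pool)
  exp(lin) * (area / config$A0)^config$z
}

#' Partition complete richness into nested completeness tiers
#'
#' Emulates rarefaction of a complete-vegetation survey to woody-only
#' records: `S_trees = round(tree_frac * S)` and
#' `S_trees_shrubs = round((tree_frac + shrub_frac) * S)`. Nesting
#' `S_trees <= S_trees_shrubs <= S_complete` holds by monotonicity of
#' rounding.
#'
#' @param S_complete Complete-vegetation richness (non-negative counts).
#' @param tree_frac,shrub_frac Fractions of species that are trees / shrubs;
#'   each in \[0,1\] with `tree_frac + shrub_frac <= 1`. Vectorized.
#' @return A data.frame with columns `S_trees`, `S_trees_shrubs`,
#'   `S_complete`.
#' @export
partition_richness <- function(S_complete, tree_frac, shrub_frac) {
  if (any(tree_frac < 0 | tree_frac > 1 | shrub_frac < 0 | shrub_frac > 1))
    stop("tier shares must lie in [0, 1]")
  if (any(tree_frac + shrub_frac > 1 + 1e-12))
    stop("tree + shrub share must not exceed 1")
  data.frame(S_trees = round(tree_frac * S_complete),
             S_trees_shrubs = round((tree_frac + shrub_frac) * S_complete),
             S_complete = S_complete)
}

#' Sample a synthetic vegetation-plot survey
#'
#' Draws plot locations with geographic clustering (cluster centres with
#' Gaussian dispersion and unequal cluster weights, emulating survey bias),
#' plot areas log-uniform within formation-typical windows, growth-form
#' cover shares such that a configurable fraction of plots satisfies the
#' forest rule, realm/biome labels from the grid bands, richness from a
#' negative binomial around the SAR expectation, and nested completeness
#' tiers. Deterministic given `seed`.
#'
#' @param env An [generate_environment()] grid.
#' @param config The [world_config()] used to build `env`.
#' @param n_plots Number of plots (> 0).
#' @param n_clusters Number of sampling cluster centres.
#' @param cluster_sd_km Gaussian dispersion of plots around their centre; use
#'   `Inf` for spatially uniform sampling.
#' @param prop_forest,prop_unresolved Fractions of plots drawn as forest-like
#'   and as formation-unresolved (neither rule met).
#' @param prop_incomplete Fraction of plots reported as genuinely incomplete
#'   surveys (split evenly between 'trees only' and 'trees and shrubs only').
#' @param prop_anthropogenic,prop_aquatic,prop_missing_area Fractions flagged
#'   anthropogenic / aquatic / with missing area.
#' @param area_range_forest,area_range_nonforest Plot-area windows (m^2) for
#'   the log-uniform area draw.
#' @param seed Seed; defaults to a child of the master seed.
#' @return A data.frame of plot records (one row per plot) with attribute
#'   `coord_mode = "planar"`: id, x/y (km), area_m2, realm, biome,
#'   growth-form cover shares, plants_recorded, nested richness tiers,
#'   observed `richness`, `mu_true` (the generating SAR expectation, ground
#'   truth for recovery tests), and exclusion flags.
#' @export
sample_plots <- function(env, config, n_plots = 2000,
                         n_clusters = 40, cluster_sd_km = 25,
                         prop_forest = 0.5, prop_unresolved = 0.04,
                         prop_incomplete = 0.05,
                         prop_anthropogenic = 0.03, prop_aquatic = 0.02,
                         prop_missing_area = 0.02,
                         area_range_forest = c(100, 25000),
                         area_range_nonforest = c(10, 1500),
                         seed = child_seed(config$seed, "plots")) {
  stopifnot(inherits(env, "env_grid"), n_plots > 0)
  if (!any(env$mask)) stop("empty valid mask: nothing to sample")
  set.seed(seed)
  nr <- nrow(env$mask); nc <- ncol(env$mask)

  valid_idx <- which(env$mask)
  # cluster centres on valid cells, with unequal weights (sampling bias)
  ctr <- sample(valid_idx, n_clusters, replace = TRUE)
  ctr_rc <- arrayInd(ctr, dim(env$mask))
  ctr_xy <- cell_center_xy(env, ctr_rc[, 1], ctr_rc[, 2])
  w <- stats::rgamma(n_clusters, shape = 0.5)
  memb <- sample.int(n_clusters, n_plots, replace = TRUE, prob = w / sum(w))

  x <- y <- numeric(n_plots)
  for (i in seq_len(n_plots)) {
    repeat {
      if (is.infinite(cluster_sd_km)) {
        xi <- stats::runif(1, 0, nc * env$cell_km)
        yi <- stats::runif(1, 0, nr * env$cell_km)
      } else {
        xi <- ctr_xy[memb[i], 1] + stats::rnorm(1, 0, cluster_sd_km)
        yi <- ctr_xy[memb[i], 2] + stats::rnorm(1, 0, cluster_sd_km)
      }
      rc <- locate_cell(env, xi, yi)
      if (!is.na(rc[1, 1]) && env$mask[rc[1, 1], rc[1, 2]]) {
        x[i] <- xi; y[i] <- yi; break
      }
    }
  }
  rc <- locate_cell(env, x, y)
  cell <- cbind(rc[, 1], rc[, 2])

  # growth-form cover shares by intended formation
  kind <- sample(c("forest", "nonforest", "unresolved"), n_plots,
                 replace = TRUE,
                 prob = c(prop_forest, 1 - prop_forest - prop_unresolved,
                          prop_unresolved))
  tree_share <- shrub_share <- low_share <- numeric(n_plots)
  isf <- kind == "forest"; isn <- kind == "nonforest"; isu <- kind == "unresolved"
  tree_share[isf] <- stats::runif(sum(isf), 0.30, 0.95)
  shrub_share[isf] <- stats::runif(sum(isf), 0, 1) * (1 - tree_share[isf]) * 0.5
  tree_share[isn] <- stats::runif(sum(isn), 0, 0.05)
  low_raw <- stats::runif(sum(isn), 0.905, 1 - 1e-6)
  shrub_share[isn] <- pmax(0, 1 - low_raw - tree_share[isn])
  tree_share[isu] <- stats::runif(sum(isu), 0.05, 0.25)
  shrub_share[isu] <- stats::runif(sum(isu), 0.10, 0.40)
  low_share <- pmax(0, 1 - tree_share - shrub_share)

  area <- numeric(n_plots)
  fa <- log(area_range_forest); na_rng <- log(area_range_nonforest)
  area[isf | isu] <- exp(stats::runif(sum(isf | isu), fa[1], fa[2]))
  area[isn] <- exp(stats::runif(sum(isn), na_rng[1], na_rng[2]))

  cov_mat <- sapply(env$layers, function(L) L[cell])
  pool <- env$pool[cell]
  mu <- true_richness(area, cov_mat, pool, config)
  if (is.infinite(config$dispersion)) {
    S_complete <- round(mu)
  } else {
    S_complete <- stats::rnbinom(n_plots, size = config$dispersion, mu = mu)
  }

  # species-composition tiers: forests tree-heavy, open vegetation herb-heavy
  tree_frac <- ifelse(isf, stats::runif(n_plots, 0.15, 0.50),
                      stats::runif(n_plots, 0, 0.08))
  shrub_frac <- ifelse(isf, stats::runif(n_plots, 0.05, 0.25),
                       stats::runif(n_plots, 0, 0.10))
  tiers <- partition_richness(S_complete, tree_frac, shrub_frac)

  plants <- rep("complete vegetation", n_plots)
  inc <- stats::runif(n_plots) < prop_incomplete & isf
  plants[inc] <- sample(c("trees only", "trees and shrubs only"),
                        sum(inc), replace = TRUE)
  richness <- ifelse(plants == "trees only", tiers$S_trees,
                     ifelse(plants == "trees and shrubs only",
                            tiers$S_trees_shrubs, tiers$S_complete))

  realm <- env$realm_levels[env$realm[cell]]
  biome <- env$biome_levels[env$biome[cell]]
  anthropogenic <- stats::runif(n_plots) < prop_anthropogenic
  aquatic <- stats::runif(n_plots) < prop_aquatic
  area[stats::runif(n_plots) < prop_missing_area] <- NA_real_

  out <- data.frame(
    plot_id = sprintf("p%06d", seq_len(n_plots)),
    x = x, y = y, area_m2 = area,
    realm = realm, biome = biome,
    tree_share = tree_share, shrub_share = shrub_share,
    low_share = low_share,
    plants_recorded = plants,
    S_trees = tiers$S_trees, S_trees_shrubs = tiers$S_trees_shrubs,
    S_complete = tiers$S_complete, richness = richness,
    mu_true = mu,
    anthropogenic = anthropogenic, aquatic = aquatic,
    stringsAsFactors = FALSE
  )
  attr(out, "coord_mode") <- "planar"
  out
}
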