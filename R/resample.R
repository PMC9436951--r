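#' Group retained plots into resampling strata
#'
#' A stratum is a unique combination of realm, biome, formation and
#' plot-size class. Every retained plot belongs to exactly one stratum.
#'
#' @param plots Screened plot table (output of [filter_plots()]) with
#'   columns `plot_id`, `realm`, `biome`, `formation`, `size_class`.
#' @return Named list mapping stratum key (`realm|biome|formation|class`)
#'   to the vector of plot ids.
#' @export
build_strata <- function(plots) {
  comp <- plots[c("realm", "biome", "formation", "size_class")]
  if (any(vapply(comp, function(v) any(is.na(v)), logical(1))))
    stop("every plot needs realm, biome, formation and size class")
  key <- paste(comp$realm, comp$biome, comp$formation, comp$size_class,
               sep = "|")
  split(plots$plot_id, key)
}

#' Draw stratified resample sets
#'
#' In each of `n_iter` independent iterations, every stratum contributes up
#' to `max_per_stratum` plots sampled without replacement (all of them when
#' the stratum is smaller). Deterministic given `seed`; iteration `i` uses
#' the child seed `(seed, "resample", i)`.
#'
#' @param strata Output of [build_strata()].
#' @param max_per_stratum Cap per stratum (default 100).
#' @param n_iter Number of iterations (default 99).
#' @param seed Master seed.
#' @return List of `resample_set` objects: `iteration`, `plot_id`,
#'   `rarefy_to` (all `"none"` until [simulate_incompleteness()]), `seed`.
#' @export
stratified_resample <- function(strata, max_per_stratum = 100, n_iter = 99,
                                seed = 1L) {
  if (max_per_stratum < 1) stop("max_per_stratum must be >= 1")
  if (length(strata) == 0) stop("strata map is empty")
  lapply(seq_len(n_iter), function(i) {
    s <- child_seed(seed, "resample", i)
    set.seed(s)
    ids <- unlist(lapply(strata, function(v) {
      if (length(v) <= max_per_stratum) v
      else sample(v, max_per_stratum)
    }), use.names = FALSE)
    structure(list(iteration = i, plot_id = ids,
                   rarefy_to = rep("none", length(ids)), seed = s),
              class = "resample_set")
  })
}

#' Simulate survey incompleteness within a resample set
#'
#' Within biomes that hold more than `complete_threshold` complete-vegetation
#' plots in the full table, a `fraction` (floored, per biome) of the set's
#' complete-vegetation plots is annotated for rarefaction to `trees only` or
#' `trees and shrubs only`. The split between the two target levels follows
#' the frequency of those levels among genuinely incomplete plots in the
#' full table (50/50 when there are none). Ineligible biomes are untouched.
#'
#' @param set A `resample_set`.
#' @param plots Full screened plot table (used both for biome eligibility
#'   and for the level-split frequencies).
#' @param complete_threshold Biome eligibility cut on the number of
#'   complete-vegetation plots in the full table (default 10000; configure
#'   down for desk-scale synthetic runs).
#' @param fraction Fraction of eligible complete plots to rarefy
#'   (default 0.20).
#' @param seed Seed (default: child of the set's own seed).
#' @return The set with `rarefy_to` annotations filled in.
#' @export
simulate_incompleteness <- function(set, plots, complete_threshold = 10000,
                                    fraction = 0.20,
                                    seed = child_seed(set$seed, "rarefy")) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  complete <- plots$plants_recorded == "complete vegetation"
  eligible_biomes <- names(which(table(plots$biome[complete]) >
                                   complete_threshold))
  if (length(eligible_biomes) == 0) return(set)

  inc <- plots$plants_recorded[!complete]
  p_trees <- if (length(inc)) mean(inc == "trees only") else 0.5

  idx <- match(set$plot_id, plots$plot_id)
  set.seed(seed)
  for (b in eligible_biomes) {
    cand <- which(plots$biome[idx] == b & complete[idx])
    k <- floor(fraction * length(cand))
    if (k < 1) next
    pick <- sample(cand, k)
    set$rarefy_to[pick] <- ifelse(stats::runif(k) < p_trees,
                                  "trees only", "trees and shrubs only")
  }
  set
}

#' Materialize a resample set as a model-ready plot table
#'
#' Subsets the plot table to the set's plots and applies the rarefaction
#' annotations: a plot annotated `trees only` has its richness replaced by
#' its `S_trees` tier (and `plants_recorded` relabelled), likewise for
#' `trees and shrubs only`. Rarefaction never increases richness.
#'
#' @param set A `resample_set` (after [simulate_incompleteness()] if
#'   desired).
#' @param plots Full screened plot table.
#' @return Plot table rows for the set, transformed.
#' @export
apply_rarefaction <- function(set, plots) {
  out <- plots[match(set$plot_id, plots$plot_id), , drop = FALSE]
  to_t <- set$rarefy_to == "trees only"
  to_ts <- set$rarefy_to == "trees and shrubs only"
  out$richness[to_t] <- out$S_trees[to_t]
  out$richness[to_ts] <- out$S_trees_shrubs[to_ts]
  out$plants_recorded[to_t] <- "trees only"
  out$plants_recorded[to_ts] <- "trees and shrubs only"
  rownames(out) <- NULL
  out
}
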