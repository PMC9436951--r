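make_stratum_plots <- function(realms = 2, biomes = 2, formations = 2,
                               classes = 4, per = 3) {
  grid <- expand.grid(realm = paste0("r", seq_len(realms)),
                      biome = paste0("b", seq_len(biomes)),
                      formation = c("forest", "non-forest")[seq_len(formations)],
                      size_class = c("small", "medium", "large",
                                     "very large")[seq_len(classes)],
                      rep = seq_len(per), stringsAsFactors = FALSE)
  grid$plot_id <- paste0("p", seq_len(nrow(grid)))
  grid
}

test_that("strata are the realm x biome x formation x size-class cross", {
  plots <- make_stratum_plots()
  strata <- build_strata(plots)
  expect_lte(length(strata), 32)
  expect_setequal(unlist(strata), plots$plot_id)
  one <- build_strata(plots[1, ])
  expect_length(one, 1)
  expect_equal(unname(one[[1]]), plots$plot_id[1])
  # moving a plot's area across a class boundary changes only that component
  p <- plots[1, ]; p$size_class <- assign_size_class(400)
  k1 <- names(build_strata(p))
  p$size_class <- assign_size_class(700)
  k2 <- names(build_strata(p))
  expect_equal(sub("[^|]+$", "", k1), sub("[^|]+$", "", k2))
  expect_false(k1 == k2)
  p$size_class <- NA
  expect_error(build_strata(p), "size class|stratum|realm")
})

test_that("stratified resampling caps strata at the maximum and keeps small ones whole", {
  strata <- list(big = paste0("a", 1:250), small = paste0("b", 1:40))
  sets <- stratified_resample(strata, max_per_stratum = 100, n_iter = 10,
                              seed = 3)
  for (s in sets) {
    expect_false(any(duplicated(s$plot_id)))
    expect_equal(sum(s$plot_id %in% strata$big), 100)
    expect_setequal(s$plot_id[s$plot_id %in% strata$small], strata$small)
    expect_equal(length(s$plot_id), sum(pmin(lengths(strata), 100)))
  }
  expect_identical(stratified_resample(strata, 100, 10, seed = 3), sets)
  expect_error(stratified_resample(strata, max_per_stratum = 0), ">= 1")
})

test_that("per-iteration totals equal the brute-force stratum sum", {
  w <- tiny_world
  strata <- build_strata(w$plots)
  sets <- stratified_resample(strata, max_per_stratum = 20, n_iter = 5,
                              seed = 9)
  oracle <- sum(vapply(strata, function(v) min(length(v), 20), numeric(1)))
  for (s in sets) expect_equal(length(s$plot_id), oracle)
  # no stratum ever contributes more than the cap
  for (s in sets) {
    key <- with(w$plots[match(s$plot_id, w$plots$plot_id), ],
                paste(realm, biome, formation, size_class, sep = "|"))
    expect_lte(max(table(key)), 20)
  }
})

test_that("incompleteness simulation rarefies the configured share in eligible biomes", {
  n <- 600
  plots <- data.frame(
    plot_id = paste0("p", 1:n),
    biome = rep(c("eligible", "rare"), c(500, 100)),
    plants_recorded = "complete vegetation",
    S_trees = 10, S_trees_shrubs = 15, S_complete = 40, richness = 40,
    stringsAsFactors = FALSE
  )
  set <- structure(list(iteration = 1, plot_id = plots$plot_id,
                        rarefy_to = rep("none", n), seed = 5),
                   class = "resample_set")
  out <- simulate_incompleteness(set, plots, complete_threshold = 400,
                                 fraction = 0.20)
  rar <- out$rarefy_to != "none"
  expect_equal(sum(rar), 100) # floor(0.2 * 500), eligible biome only
  expect_true(all(plots$biome[match(out$plot_id[rar], plots$plot_id)] ==
                    "eligible"))
  # a biome below the threshold is untouched
  out2 <- simulate_incompleteness(set, plots, complete_threshold = 900)
  expect_true(all(out2$rarefy_to == "none"))
  expect_error(simulate_incompleteness(set, plots, fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("rarefaction substitutes tiers and never increases richness", {
  plots <- data.frame(plot_id = c("a", "b", "c"),
                      plants_recorded = "complete vegetation",
                      S_trees = c(10, 3, 0), S_trees_shrubs = c(15, 7, 2),
                      S_complete = c(40, 9, 5), richness = c(40, 9, 5),
                      stringsAsFactors = FALSE)
  set <- structure(list(iteration = 1, plot_id = c("a", "b", "c"),
                        rarefy_to = c("trees only", "trees and shrubs only",
                                      "none"), seed = 1),
                   class = "resample_set")
  out <- apply_rarefaction(set, plots)
  expect_equal(out$richness, c(10, 7, 5))
  expect_equal(out$plants_recorded,
               c("trees only", "trees and shrubs only",
                 "complete vegetation"))
  expect_true(all(out$richness <= plots$richness))
})

test_that("only complete-vegetation plots are ever annotated for rarefaction", {
  w <- tiny_world
  strata <- build_strata(w$plots)
  sets <- stratified_resample(strata, n_iter = 3, seed = 21)
  sets <- lapply(sets, simulate_incompleteness, plots = w$plots,
                 complete_threshold = 50)
  for (s in sets) {
    rar <- s$rarefy_to != "none"
    if (!any(rar)) next
    before <- w$plots$plants_recorded[match(s$plot_id[rar], w$plots$plot_id)]
    expect_true(all(before == "complete vegetation"))
    after <- apply_rarefaction(s, w$plots)
    full <- w$plots[match(s$plot_id, w$plots$plot_id), ]
    expect_true(all(after$richness <= full$richness))
  }
})
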