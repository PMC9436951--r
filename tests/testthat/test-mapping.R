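grid_from <- function(v, nr, nc) matrix(v, nr, nc)

fake_stack <- function(grids, mask = !is.na(grids[[1]])) {
  structure(list(grain = 100, formation = "forest", grids = grids,
                 mask = mask), class = "prediction_stack")
}

test_that("stack summaries are order statistics across members", {
  g <- grid_from(c(1, 2, NA, 4), 2, 2)
  mask <- !is.na(g)
  one <- summarize_stack(fake_stack(list(g), mask))
  expect_equal(one$median, g)
  expect_equal(one$iqr[mask], rep(0, 3))
  three <- summarize_stack(fake_stack(list(g * 0 + 10, g * 0 + 20,
                                           g * 0 + 30), mask))
  expect_equal(three$median[1, 1], 20)
  expect_equal(three$iqr[1, 1], 10)
  expect_true(is.na(three$median[1, 2])) # mask inherited
  # permutation invariance over members
  perm <- summarize_stack(fake_stack(list(g * 0 + 30, g * 0 + 10,
                                          g * 0 + 20), mask))
  expect_equal(perm$median, three$median)
  expect_equal(perm$iqr, three$iqr)
})

test_that("zero-median pixels get nodata relative uncertainty and are counted", {
  g1 <- grid_from(c(0, 5, 2, 8), 2, 2)
  g2 <- grid_from(c(0, 7, 2, 9), 2, 2)
  s <- summarize_stack(fake_stack(list(g1, g2)))
  expect_true(is.na(s$rel_uncertainty[1, 1]))
  expect_equal(s$n_zero_median, 1)
  expect_equal(s$rel_uncertainty[2, 2], 0.5 / 8.5)
})

test_that("hotspot masks match the brute-force sort oracle and stay disjoint", {
  set.seed(3)
  v <- sample(1:1000)
  g <- grid_from(v, 40, 25)
  hs <- hotspots(g)
  # oracle: sort and take the strict top/bottom 5%
  expect_equal(sum(hs$hot), 50)
  expect_equal(sum(hs$cold), 50)
  expect_setequal(g[hs$hot], sort(v, decreasing = TRUE)[1:50])
  expect_setequal(g[hs$cold], sort(v)[1:50])
  expect_false(any(hs$hot & hs$cold))
  expect_error(hotspots(grid_from(1:9, 3, 3)), "20 valid")
  expect_warning(hc <- hotspots(grid_from(rep(5, 100), 10, 10)), "constant")
  expect_equal(sum(hc$hot), 0)
  expect_equal(sum(hc$cold), 0)
})

test_that("hotspot masks propagate nodata and respect custom percentiles", {
  g <- grid_from(c(NA, 1:99), 10, 10)
  hs <- hotspots(g, upper = 0.9, lower = 0.1)
  expect_true(is.na(hs$hot[1, 1]))
  expect_lte(sum(hs$hot, na.rm = TRUE), 10)
})

test_that("bivariate quartile classes are diagonal for identical grids", {
  set.seed(4)
  g <- grid_from(rnorm(400), 20, 20)
  an <- scaling_anomalies(g, g)
  expect_true(all(an$fine_bin == an$coarse_bin, na.rm = TRUE))
  expect_equal(an$frac_fine_high_coarse_low, 0)
  expect_equal(an$frac_fine_low_coarse_high, 0)
  # marginal shares ~ 25% per bin
  shares <- table(an$fine_bin) / sum(!is.na(an$fine_bin))
  expect_true(all(abs(shares - 0.25) < 0.01))
})

test_that("rank reversal concentrates pixels on the anti-diagonal", {
  set.seed(5)
  v <- sample(1:400)
  fine <- grid_from(v, 20, 20)
  coarse <- grid_from(401 - v, 20, 20) # exact rank reversal
  an <- scaling_anomalies(fine, coarse)
  expect_true(all(an$fine_bin + an$coarse_bin == 5, na.rm = TRUE))
  expect_equal(an$frac_fine_high_coarse_low, 0.25)
  expect_equal(an$frac_fine_low_coarse_high, 0.25)
  expect_error(scaling_anomalies(fine, matrix(1, 2, 2)), "shape")
})

test_that("ignorance mask flags pixels beyond the distance threshold", {
  cfg <- world_config(nrow = 40, ncol = 40, cell_km = 25, mask_fraction = 0,
                      seed = 3)
  env <- generate_environment(cfg)
  plots <- data.frame(x = 500, y = 500)
  attr(plots, "coord_mode") <- "planar"
  ig <- ignorance_mask(plots, env, max_dist_km = 500)
  # the pixel containing the plot is never data-poor
  row <- 40 - ceiling(500 / 25) + 1; col <- ceiling(500 / 25)
  expect_false(ig[row, col])
  # exhaustive per-pixel distance oracle: boundary within one cell
  idx <- seq_len(40 * 40)
  rcs <- arrayInd(idx, c(40, 40))
  px <- (rcs[, 2] - 0.5) * 25
  py <- (40 - rcs[, 1] + 0.5) * 25
  d <- sqrt((px - 500)^2 + (py - 500)^2)
  expect_equal(as.vector(ig), d > 500)
  disagree <- abs(d - 500) > 25 * sqrt(2) # away from the boundary ring
  expect_true(all((d[disagree] > 500) == as.vector(ig)[disagree]))
  expect_warning(ig0 <- ignorance_mask(plots[0, , drop = FALSE], env),
                 "data-poor")
  expect_true(all(ig0))
})

test_that("gridded predictions honour the mask and identical members give zero IQR", {
  w <- tiny_world
  mem <- tiny_member$member
  tr <- tiny_member$transforms
  st <- predict_grid(list(mem, mem), w$env, grain = 1000,
                     formation = "forest", transforms = tr)
  expect_true(all(is.na(st$grids[[1]][!st$mask])))
  expect_identical(st$grids[[1]], st$grids[[2]])
  s <- summarize_stack(st)
  expect_true(all(s$iqr[st$mask] == 0))
  expect_true(all(s$median[st$mask] >= 0))
  expect_warning(predict_grid(list(mem), w$env, grain = 1e6,
                              formation = "forest", transforms = tr),
                 "outside the training size range")
})

test_that("grid round trip through the ASCII raster format preserves values", {
  g <- grid_from(c(1.5, NA, -2, 44), 2, 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path, cell_km = 2)
  back <- read_ascii_grid(path)
  expect_equal(back, g, ignore_attr = TRUE)
  expect_equal(attr(back, "cell_km"), 2)
})
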