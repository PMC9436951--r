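#' Write / read a plot table
#'
#' Tab-separated text, one plot per row, header row; the coordinate mode
#' is stored in a `# coord_mode:` comment line and restored on read.
#'
#' @param plots Plot table.
#' @param path File path.
#' @export
write_plot_table <- function(plots, path) {
  mode <- attr(plots, "coord_mode")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mode)) writeLines(paste0("# coord_mode: ", mode), con)
  utils::write.table(plots, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_plot_table
#' @return `read_plot_table`: the plot table with its `coord_mode`
#'   attribute.
#' @export
read_plot_table <- function(path) {
  first <- readLines(path, n = 1)
  mode <- if (startsWith(first, "# coord_mode:"))
    trimws(sub("# coord_mode:", "", first)) else NULL
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(mode)) attr(out, "coord_mode") <- mode
  out
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from the top edge down),
#' matching the package's row-1-is-north convention.
#'
#' @param grid Numeric matrix (`NA` = nodata).
#' @param path File path.
#' @param cell_km Cell size (written in the same units as the origin).
#' @param nodata Nodata sentinel written for `NA` (default -9999).
#' @export
write_ascii_grid <- function(grid, path, cell_km = 1, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(grid)),
               paste("nrows", nrow(grid)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cell_km),
               paste("NODATA_value", nodata)), con)
  g <- grid
  g[is.na(g)] <- nodata
  utils::write.table(g, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid`: a numeric matrix with attribute `cell_km`;
#'   nodata cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  g <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(g) <- NULL
  g[g == h[["nodata_value"]]] <- NA_real_
  attr(g, "cell_km") <- h[["cellsize"]]
  g
}

#' Write an environmental grid to a directory
#'
#' One ASCII raster per covariate layer plus `ecoregion.asc`, `pool.asc`,
#' `mask.asc`, `realm.asc`, `biome.asc`, and a sidecar table
#' `ecoregions.tsv` (ecoregion id, species pool).
#'
#' @param env An `env_grid`.
#' @param dir Output directory (created if needed).
#' @export
write_env_grid <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(env$layers))
    write_ascii_grid(env$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     env$cell_km)
  write_ascii_grid(env$ecoregion, file.path(dir, "ecoregion.asc"),
                   env$cell_km)
  write_ascii_grid(env$pool, file.path(dir, "pool.asc"), env$cell_km)
  write_ascii_grid(env$mask + 0, file.path(dir, "mask.asc"), env$cell_km)
  write_ascii_grid(env$realm, file.path(dir, "realm.asc"), env$cell_km)
  write_ascii_grid(env$biome, file.path(dir, "biome.asc"), env$cell_km)
  eco <- data.frame(ecoregion = sort(unique(as.vector(env$ecoregion))))
  eco$pool <- env$pool[match(eco$ecoregion, env$ecoregion)]
  utils::write.table(eco, file.path(dir, "ecoregions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
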