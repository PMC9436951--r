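#' Classify a plot's broad formation from growth-form cover shares
#'
#' A plot is `forest` when trees contribute more than 25% of total cover,
#' `non-forest` when low-growing taxa (other than trees and shrubs)
#' contribute more than 90%, and `excluded` when neither rule is met.
#'
#' @param tree_share,low_share Cover shares (fractions of total cover) of
#'   tree taxa and of low-growing taxa; each in \[0,1\]. Vectorized.
#' @return Character vector in `{"forest", "non-forest", "excluded"}`.
#' @export
classify_formation <- function(tree_share, low_share) {
  if (any(tree_share < 0 | tree_share > 1 | low_share < 0 | low_share > 1,
          na.rm = TRUE))
    stop("cover shares must lie in [0, 1]")
  ifelse(tree_share > 0.25, "forest",
         ifelse(low_share > 0.90, "non-forest", "excluded"))
}

#' Assign the plot-size class used for resampling strata
#'
#' Four classes with right-closed boundaries: small (0,150\], medium
#' (150,600\], large (600,1200\], very large (1200,Inf) m^2.
#'
#' @param area Plot area(s) in m^2 (> 0).
#' @return Character vector in
#'   `{"small", "medium", "large", "very large"}`.
#' @export
assign_size_class <- function(area) {
  if (any(area <= 0, na.rm = TRUE)) stop("area must be positive")
  as.character(cut(area, breaks = c(0, 150, 600, 1200, Inf),
                   labels = c("small", "medium", "large", "very large"),
                   right = TRUE))
}

#' Label survey completeness ('plants recorded')
#'
#' `trees only` when only woody individuals above a 5 cm DBH threshold were
#' recorded; `trees and shrubs only` when all woody species were recorded
#' (no herbs), i.e. woody-only with no DBH cutoff or a cutoff <= 5 cm;
#' `complete vegetation` otherwise.
#'
#' @param woody_only Logical: only woody species recorded.
#' @param herbs_sampled Logical: herbs were sampled (contradicts
#'   `woody_only`).
#' @param min_dbh_cm Minimum DBH threshold (cm) used for woody individuals;
#'   `NA` when no cutoff was applied.
#' @return Character vector in `{"trees only", "trees and shrubs only",
#'   "complete vegetation"}`.
#' @export
label_completeness <- function(woody_only, herbs_sampled = !woody_only,
                               min_dbh_cm = NA_real_) {
  n <- max(length(woody_only), length(herbs_sampled), length(min_dbh_cm))
  woody_only <- rep_len(woody_only, n)
  herbs_sampled <- rep_len(herbs_sampled, n)
  min_dbh_cm <- rep_len(min_dbh_cm, n)
  if (any(woody_only & herbs_sampled))
    stop("contradictory metadata: woody-only survey cannot include herbs")
  ifelse(!woody_only, "complete vegetation",
         ifelse(!is.na(min_dbh_cm) & min_dbh_cm > 5,
                "trees only", "trees and shrubs only"))
}

#' Screen a raw plot table
#'
#' Applies the screening rules in order: (1) formation unresolved (neither
#' the forest nor the non-forest cover rule met); (2) missing sampled area;
#' (3) area outside the formation window (forest 100-25000 m^2, non-forest
#' 10-1500 m^2); (4) anthropogenic; (5) aquatic/wetland. Each dropped plot
#' is attributed to the first rule it triggers. Retained plots gain
#' `formation` and `size_class` columns. Filtering is idempotent.
#'
#' @param plots Plot table with columns `tree_share`, `low_share`,
#'   `area_m2`, `anthropogenic`, `aquatic`.
#' @return List with `plots` (retained rows) and `report` (an
#'   `ingest_report`: per-rule drop counts plus the formation tally).
#' @export
filter_plots <- function(plots) {
  formation <- classify_formation(plots$tree_share, plots$low_share)
  n <- nrow(plots)
  reason <- rep(NA_character_, n)
  reason[formation == "excluded"] <- "formation unresolved"
  open <- is.na(reason)
  reason[open & is.na(plots$area_m2)] <- "missing area"
  open <- is.na(reason)
  bad_size <- open &
    ((formation == "forest" &
        (plots$area_m2 < 100 | plots$area_m2 > 25000)) |
       (formation == "non-forest" &
          (plots$area_m2 < 10 | plots$area_m2 > 1500)))
  reason[bad_size] <- "size out of range"
  open <- is.na(reason)
  reason[open & plots$anthropogenic] <- "anthropogenic"
  open <- is.na(reason)
  reason[open & plots$aquatic] <- "aquatic"

  keep <- is.na(reason)
  retained <- plots[keep, , drop = FALSE]
  retained$formation <- formation[keep]
  retained$size_class <- assign_size_class(retained$area_m2)

  rules <- c("formation unresolved", "missing area", "size out of range",
             "anthropogenic", "aquatic")
  report <- structure(list(
    n_input = n, n_retained = sum(keep), n_dropped = sum(!keep),
    dropped_by_rule = vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                             integer(1)),
    formation_tally = table(factor(retained$formation,
                                   levels = c("forest", "non-forest")))
  ), class = "ingest_report")
  list(plots = retained, report = report)
}

#' @export
print.ingest_report <- function(x, ...) {
  cat(sprintf("ingest: %d plots in, %d retained, %d dropped\n",
              x$n_input, x$n_retained, x$n_dropped))
  for (r in names(x$dropped_by_rule))
    cat(sprintf("  %-22s %d\n", r, x$dropped_by_rule[[r]]))
  cat(sprintf("  retained: %d forest, %d non-forest\n",
              x$formation_tally[["forest"]], x$formation_tally[["non-forest"]]))
  invisible(x)
}
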