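#' Relative growth rate of rosette area
#'
#' RGR over each consecutive day pair of a projected-rosette-area series:
#' `(ln A_t - ln A_{t-dt}) / dt`, in day^-1. Series are grouped by
#' `plant_id` (plus any other identifying columns present) and must have
#' strictly increasing days and positive areas.
#'
#' @param series A tibble with columns `day` and `area` (mm^2), optionally
#'   `plant_id` and grouping columns such as `species`/`treatment`.
#' @return A tibble with one row per interval: grouping columns,
#'   `day_start`, `day_end`, `rgr`.
#' @export
relative_growth_rate <- function(series) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("day", "area") %in% names(series)))
  id_cols <- intersect(c("plant_id", "species", "treatment", "replicate"),
                       names(series))
  grouped <- if (length(id_cols) > 0) {
    group_by(series, dplyr::across(dplyr::all_of(id_cols)))
  } else {
    group_by(series, .tmp = 1)
  }
  out <- grouped %>%
    arrange(.data$day, .by_group = TRUE) %>%
    dplyr::reframe(day_start = .data$day[-n()],
                   day_end = .data$day[-1],
                   area_start = .data$area[-n()],
                   area_end = .data$area[-1])
  if (any(out$day_end <= out$day_start)) {
    abort("Days must be strictly increasing within each plant.")
  }
  if (any(out$area_start <= 0 | out$area_end <= 0)) {
    abort("Areas must be positive to compute a relative growth rate.")
  }
  out <- out %>%
    mutate(rgr = (log(.data$area_end) - log(.data$area_start)) /
             (.data$day_end - .data$day_start)) %>%
    select(-"area_start", -"area_end")
  out[setdiff(names(out), ".tmp")]
}

#' Rosette shape descriptors
#'
#' `stockiness()` is the isoperimetric quotient `4*pi*area / perimeter^2`:
#' 1 for a circle and below 1 for any other simple closed outline.
#' `compactness()` is the ratio of rosette area to convex-hull area: 1 for a
#' convex rosette.
#'
#' @param area Projected rosette area (mm^2).
#' @param perimeter Rosette perimeter (mm); must be positive.
#' @param hull_area Convex-hull area (mm^2); must be at least `area`.
#' @return Dimensionless values in (0, 1] (vectorised).
#' @export
stockiness <- function(area, perimeter) {
  if (any(perimeter <= 0)) abort("`perimeter` must be positive.")
  if (any(area < 0)) abort("`area` must be nonnegative.")
  4 * pi * area / perimeter^2
}

#' @rdname stockiness
#' @export
compactness <- function(area, hull_area) {
  if (any(area <= 0)) abort("`area` must be positive.")
  if (any(hull_area < area)) {
    abort("Convex-hull area cannot be smaller than the rosette area.")
  }
  area / hull_area
}

#' Stomatal index
#'
#' Ratio of guard cells to epidermal cells, exactly as printed in the source
#' protocol. Note that a widely used alternative convention divides the
#' stomata count by (stomata + epidermal cells); set
#' `conventional = TRUE` for that form.
#'
#' @param guard_cells Number of guard cells (nonnegative).
#' @param epidermal_cells Number of epidermal cells (positive).
#' @param conventional Use stomata / (stomata + epidermal) instead of the
#'   printed guard/epidermal ratio. A stoma has two guard cells.
#' @return Dimensionless index (vectorised).
#' @export
stomatal_index <- function(guard_cells, epidermal_cells,
                           conventional = FALSE) {
  if (any(epidermal_cells <= 0)) abort("`epidermal_cells` must be positive.")
  if (any(guard_cells < 0)) abort("`guard_cells` must be nonnegative.")
  if (conventional) {
    stomata <- guard_cells / 2
    stomata / (stomata + epidermal_cells)
  } else {
    guard_cells / epidermal_cells
  }
}

#' Estimated cells per leaf
#'
#' Product of total leaf area and the average cell density, reported as a
#' real number (no rounding).
#'
#' @param leaf_area Leaf area (mm^2).
#' @param cells_per_area Average cell density (mm^-2).
#' @return Estimated cell count (vectorised).
#' @export
cells_per_leaf <- function(leaf_area, cells_per_area) {
  if (any(leaf_area < 0) || any(cells_per_area < 0)) {
    abort("Leaf area and cell density must be nonnegative.")
  }
  leaf_area * cells_per_area
}

#' Stomatal aperture ratio
#'
#' Ratio between the width and length of the ostiole: 0 for a fully closed
#' stoma, 1 for a circular opening.
#'
#' @param width Ostiole width (micrometres).
#' @param length Ostiole length (micrometres); must be positive and at least
#'   `width`.
#' @return Ratio in \[0, 1\] (vectorised).
#' @export
aperture_ratio <- function(width, length) {
  if (any(length <= 0)) abort("`length` must be positive.")
  if (any(width < 0) || any(width > length)) {
    abort("`width` must lie between 0 and `length`.")
  }
  width / length
}

#' Relative anthocyanin index
#'
#' `(A530 - A657) / fresh_weight`, the background-corrected absorbance of an
#' anthocyanin extract per gram fresh weight. A negative index (A657
#' exceeding A530) is reported with a warning rather than suppressed.
#'
#' @param a530,a657 Absorbances at 530 and 657 nm.
#' @param fresh_weight Fresh weight in grams; must be positive.
#' @return Index in absorbance units per gram (vectorised).
#' @export
anthocyanin_index <- function(a530, a657, fresh_weight) {
  if (any(fresh_weight <= 0)) abort("`fresh_weight` must be positive.")
  idx <- (a530 - a657) / fresh_weight
  if (any(idx < 0)) {
    warn(sprintf("%d negative anthocyanin index value(s) (A657 > A530).",
                 sum(idx < 0)))
  }
  idx
}

#' Survival rate after rewatering
#'
#' Percentage of plants surviving, computed per biological replicate and then
#' summarised across replicates as mean and standard deviation.
#'
#' @param outcomes A tibble with a logical `survived` column and a
#'   `replicate` column; optional grouping columns (e.g. `species`,
#'   `treatment`) are respected.
#' @param by Character vector of grouping columns (default: any of
#'   `species`, `treatment` present).
#' @return A tibble with `mean_pct`, `sd_pct`, `n_replicates` per group; the
#'   per-replicate percentages are attached as the `"per_replicate"`
#'   attribute.
#' @export
survival_rate <- function(outcomes, by = NULL) {
  outcomes <- tibble::as_tibble(outcomes)
  stopifnot(all(c("survived", "replicate") %in% names(outcomes)))
  by <- by %||% intersect(c("species", "treatment"), names(outcomes))
  per_rep <- outcomes %>%
    group_by(dplyr::across(dplyr::all_of(c(by, "replicate")))) %>%
    summarise(n_plants = n(),
              pct_survived = 100 * mean(.data$survived),
              .groups = "drop")
  if (any(per_rep$n_plants == 0)) abort("Empty replicate.")
  out <- per_rep %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(mean_pct = mean(.data$pct_survived),
              sd_pct = sd(.data$pct_survived),
              n_replicates = n(),
              .groups = "drop")
  attr(out, "per_replicate") <- per_rep
  out
}

#' First day with a significant drought growth reduction
#'
#' Compares projected rosette area between well-watered and water-deficit
#' plants day by day with a one-sided Welch t-test (alternative: WD smaller
#' than WW) and returns the earliest day at which `p <= alpha`, or `NA` if
#' the reduction never becomes significant. The full per-day test table is
#' attached as the `"tests"` attribute.
#'
#' @param ww,wd Tibbles with columns `day` and `area` for the well-watered
#'   and water-deficit groups (one row per plant per day).
#' @param alpha Significance level (default 0.05).
#' @return The earliest significant day (numeric), or `NA_real_`.
#' @export
first_growth_reduction_day <- function(ww, wd, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  ww <- tibble::as_tibble(ww)
  wd <- tibble::as_tibble(wd)
  stopifnot(all(c("day", "area") %in% names(ww)),
            all(c("day", "area") %in% names(wd)))
  days <- sort(intersect(unique(ww$day), unique(wd$day)))
  tests <- purrr::map_dfr(days, function(d) {
    a_ww <- ww$area[ww$day == d]
    a_wd <- wd$area[wd$day == d]
    if (length(a_ww) < 2 || length(a_wd) < 2) {
      abort(sprintf("Day %s has fewer than 2 plants in a group.", d))
    }
    p <- if (sd(a_ww) == 0 && sd(a_wd) == 0) {
      # degenerate noise-free case: identical constants are not a reduction
      if (mean(a_wd) < mean(a_ww)) 0 else 1
    } else {
      t.test(a_wd, a_ww, alternative = "less", var.equal = FALSE)$p.value
    }
    tibble::tibble(day = d, p = p)
  })
  hit <- tests$day[tests$p <= alpha]
  out <- if (length(hit) > 0) min(hit) else NA_real_
  attr(out, "tests") <- tests
  out
}
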