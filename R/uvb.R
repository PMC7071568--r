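## Half-degree grid helpers. Cells are addressed by centre (offset 0.25 from
## the half-degree lines); a coordinate exactly on a boundary belongs to the
## cell to the north/east (floor convention).
#' @noRd
cell_centre <- function(x) floor(x / 0.5) * 0.5 + 0.25

#' @noRd
centres_in_range <- function(lo, hi) {
  first <- ceiling((lo - 0.25) / 0.5) * 0.5 + 0.25
  if (first > hi) return(numeric(0))
  seq(first, hi + 1e-9, by = 0.5)
}

#' Raster cells covering one location
#'
#' @param lat_min,lat_max Latitude range (equal for a point location).
#' @param lon Longitude of the location.
#' @param range_mode `"all"`: every half-degree cell whose centre latitude
#'   falls in the closed range, at the location's longitude cell (minimum one
#'   cell, the nearest centre); `"midpoint"`: the single cell containing the
#'   range midpoint.
#' @return Tibble `lat_cell`, `lon_cell`.
#' @export
location_cells <- function(lat_min, lat_max, lon, range_mode = c("all", "midpoint")) {
  range_mode <- match.arg(range_mode)
  if (is.na(lat_min) || is.na(lat_max) || is.na(lon)) {
    return(tibble::tibble(lat_cell = numeric(0), lon_cell = numeric(0)))
  }
  lon_cell <- cell_centre(lon)
  if (lat_min == lat_max || range_mode == "midpoint") {
    return(tibble::tibble(lat_cell = cell_centre((lat_min + lat_max) / 2),
                          lon_cell = lon_cell))
  }
  lat_cells <- centres_in_range(lat_min, lat_max)
  if (length(lat_cells) == 0) {
    lat_cells <- cell_centre((lat_min + lat_max) / 2)
  }
  tibble::tibble(lat_cell = lat_cells, lon_cell = lon_cell)
}

#' Raster cells for every sample set
#'
#' @param sets Sample-set tibble.
#' @param range_mode See [location_cells()].
#' @return Tibble `sample_set_id`, `lat_cell`, `lon_cell`; sets without
#'   coordinates contribute no rows and trigger a warning.
#' @export
cells_for_location <- function(sets, range_mode = c("all", "midpoint")) {
  range_mode <- match.arg(range_mode)
  unlocated <- sets$id[is.na(sets$lat_min)]
  if (length(unlocated) > 0) {
    warn(paste0("sample set(s) without coordinates skipped in UVB lookup: ",
                paste(unlocated, collapse = ", ")))
  }
  located <- sets[!is.na(sets$lat_min), ]
  purrr::map_dfr(seq_len(nrow(located)), function(i) {
    dplyr::mutate(location_cells(located$lat_min[i], located$lat_max[i],
                                 located$lon[i], range_mode),
                  sample_set_id = located$id[i], .before = 1)
  })
}

#' Mean annual UVB over a set of cells
#'
#' Arithmetic mean of every daily irradiance value across all selected cells
#' and all days present in the raster (optionally restricted to a period).
#'
#' @param cells Tibble `lat_cell`, `lon_cell`.
#' @param raster UVB raster tibble (see [read_uvb_raster()]).
#' @param period Optional length-2 Date vector restricting the days used.
#' @return Mean irradiance (mW/m^2/nm), `NA` if no data falls in any cell.
#' @export
mean_annual_uvb <- function(cells, raster, period = NULL) {
  sel <- dplyr::semi_join(raster, cells, by = c("lat_cell", "lon_cell"))
  if (!is.null(period)) {
    sel <- sel[sel$date >= period[1] & sel$date <= period[2], ]
  }
  if (nrow(sel) == 0) return(NA_real_)
  mean(sel$irradiance)
}

#' Per-sample-set mean annual UVB
#'
#' Maps each located sample set to its raster cells and averages all daily
#' values; the workhorse behind the per-group UVB comparison.
#'
#' @inheritParams cells_for_location
#' @inheritParams mean_annual_uvb
#' @return Tibble `sample_set_id`, `group`, `n`, `mean_uvb`, `cells_used`,
#'   `days_used`. Unlocated sets appear with `NA` values.
#' @export
uvb_by_sample_set <- function(sets, raster, range_mode = c("all", "midpoint"),
                              period = NULL) {
  range_mode <- match.arg(range_mode)
  cells <- cells_for_location(sets, range_mode)
  purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    my_cells <- cells[cells$sample_set_id == sets$id[i], ]
    if (nrow(my_cells) == 0) {
      return(tibble::tibble(sample_set_id = sets$id[i], group = sets$group[i],
                            n = sets$n[i], mean_uvb = NA_real_,
                            cells_used = 0L, days_used = 0L))
    }
    sel <- dplyr::semi_join(raster, my_cells, by = c("lat_cell", "lon_cell"))
    if (!is.null(period)) sel <- sel[sel$date >= period[1] & sel$date <= period[2], ]
    tibble::tibble(sample_set_id = sets$id[i], group = sets$group[i],
                   n = sets$n[i],
                   mean_uvb = if (nrow(sel) == 0) NA_real_ else mean(sel$irradiance),
                   cells_used = length(unique(paste(sel$lat_cell, sel$lon_cell))),
                   days_used = length(unique(sel$date)))
  })
}

#' Compare mean annual UVB between ancestry groups
#'
#' One-way ANOVA of per-set mean annual UVB on group (unit of analysis the
#' sample set, weighted by cohort size) with Tukey-Kramer pairwise p values,
#' plus weighted and unweighted group means.
#'
#' @param uvb Tibble from [uvb_by_sample_set()].
#' @return List of class `uvb_comparison`: `summary` (per-group means),
#'   `fit` (the [weighted_anova()] object), `pairwise` (Tukey table), and
#'   `uvb_order` (groups sorted by ascending weighted mean UVB, the ordering
#'   the cline classifier uses).
#' @export
compare_group_uvb <- function(uvb) {
  located <- uvb[!is.na(uvb$mean_uvb), ]
  sizes <- table(located$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("group(s) with < 2 located sets dropped from UVB comparison: ",
                paste(small, collapse = ", ")))
    located <- located[!located$group %in% small, ]
  }
  summary <- located |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(mean_uvb = weighted.mean(.data$mean_uvb, .data$n),
                     mean_uvb_unweighted = mean(.data$mean_uvb),
                     n_sets = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$group, GROUP_LEVELS))
  fit <- weighted_anova(located, y = mean_uvb, group = group, w = n)
  structure(list(summary = summary, fit = fit, pairwise = tukey_kramer(fit),
                 uvb_order = summary$group[order(summary$mean_uvb)]),
            class = "uvb_comparison")
}

#' @export
print.uvb_comparison <- function(x, ...) {
  cat("Group mean annual UVB (305 nm, mW/m^2/nm):\n")
  print(x$summary)
  cat(sprintf("ANOVA p = %.3g; UVB ordering (ascending): %s\n",
              x$fit$p_value, paste(x$uvb_order, collapse = " < ")))
  print(x$pairwise[c("pair", "diff", "p")])
  invisible(x)
}
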