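#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot group means and confidence intervals of a weighted ANOVA fit
#'
#' @param object A [weighted_anova()] fit.
#' @param conf.level Interval level.
#' @param ... Unused.
#' @return A ggplot: weighted group means with model-based error bars over the
#'   per-set observations (point size proportional to cohort size).
#' @export
autoplot.uvb_anova <- function(object, conf.level = 0.95, ...) {
  ci <- group_confidence_interval(object, level = conf.level)
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_jitter(data = object$data,
                         ggplot2::aes(y = .data$y, size = .data$w),
                         width = 0.15, alpha = 0.35, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             colour = "firebrick") +
    ggplot2::scale_size_area(max_size = 4, name = "cohort n") +
    ggplot2::labs(x = NULL, y = "variant-allele frequency") +
    ggplot2::theme_minimal()
}

#' Heatmap of group mean frequencies across variants
#'
#' @param results Per-variant results from [compare_variants()].
#' @return A ggplot: variants (rows, grouped by locus) by ancestry group,
#'   tiles shaded by weighted mean frequency and annotated with the pattern
#'   label.
#' @export
plot_variant_frequencies <- function(results) {
  long <- results |>
    dplyr::select("rsid", "locus", "pattern",
                  dplyr::all_of(paste0("mean_", ANALYSIS_GROUPS))) |>
    tidyr::pivot_longer(dplyr::starts_with("mean_"), names_to = "group",
                        values_to = "mean", names_prefix = "mean_") |>
    dplyr::mutate(group = factor(.data$group, ANALYSIS_GROUPS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$rsid,
                                     fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean)),
                       size = 2.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$locus), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1),
                                 name = "weighted mean\nfrequency") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' Mean annual UVB against latitude
#'
#' @param uvb Per-set UVB tibble from [uvb_by_sample_set()], joined with set
#'   latitudes if available.
#' @param sets Optional sample-set tibble supplying latitude midpoints.
#' @return A ggplot of per-set mean annual UVB by latitude, coloured by group.
#' @export
plot_uvb_latitude <- function(uvb, sets = NULL) {
  if (!is.null(sets)) {
    uvb <- dplyr::left_join(
      uvb,
      dplyr::transmute(sets, sample_set_id = .data$id,
                       latitude = (.data$lat_min + .data$lat_max) / 2),
      by = "sample_set_id")
  }
  if (!"latitude" %in% names(uvb)) abort("supply `sets` to derive latitudes")
  ggplot2::ggplot(uvb[!is.na(uvb$mean_uvb), ],
                  ggplot2::aes(x = .data$latitude, y = .data$mean_uvb,
                               colour = .data$group, size = .data$n)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 5, name = "cohort n") +
    ggplot2::labs(x = "latitude (degrees)",
                  y = "mean annual 305 nm irradiance (mW/m²/nm)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
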