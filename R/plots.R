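# ggplot2 views of the result types.

#' Map of annual-mean deposition velocities
#'
#' @param x An `hg_vd_map` (see [annual_mean_vd()]) or any tibble with
#'   `lat`, `lon` and `vd_cm_s`.
#' @return A ggplot object.
#' @export
plot_vd_map <- function(x) {
  check_columns(x, c("lat", "lon", "vd_cm_s"), "x")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$lon, y = .data$lat,
                                  fill = .data$vd_cm_s)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(v[d] ~ "(cm s"^-1 * ")")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Annual mean Hg0 dry deposition velocity")
}

#' @rdname plot_vd_map
#' @param object,... Passed through.
#' @export
autoplot.hg_vd_map <- function(object, ...) plot_vd_map(object)

#' Median and interquartile range of velocities per group
#'
#' Companion to [group_stats()]: medians as points, interquartile ranges as
#' error bars, one position per group -- the standard view for comparing
#' observation methods or model settings.
#'
#' @param stats A [group_stats()] result.
#' @param x Name of the grouping column to place on the x axis.
#' @param colour Optional second grouping column mapped to colour.
#' @return A ggplot object.
#' @export
plot_velocity_groups <- function(stats, x = "method", colour = NULL) {
  check_columns(stats, c(x, "median", "q25", "q75"), "stats")
  mapping <- if (is.null(colour)) {
    ggplot2::aes(x = .data[[x]], y = .data$median)
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$median, colour = .data[[colour]])
  }
  ggplot2::ggplot(stats, mapping) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = expression("Dry deposition velocity (cm s"^-1 * ")"),
                  x = NULL)
}

#' Process fluxes of a tuned box model
#'
#' @param object An `hg_alpha_fit` from [tune_alpha()].
#' @param ... Unused.
#' @return A ggplot object: process fluxes (Mg yr-1) per box and species,
#'   inflows up, outflows down.
#' @export
autoplot.hg_alpha_fit <- function(object, ...) {
  rep <- budget_report(object$state, object$config, object$alpha) |>
    mutate(signed = ifelse(.data$direction == "in", 1, -1) * .data$flux_Mg_yr)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$process, y = .data$signed,
                                    fill = .data$box)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$species, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Flux (Mg yr-1; inflows positive)", x = NULL)
}
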