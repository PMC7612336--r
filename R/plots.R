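# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_polygon geom_boxplot
#'   geom_pointrange scale_fill_viridis_c coord_equal labs facet_wrap
#'   theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a voxel field
#'
#' Heat map of the (single) slice of a [voxel_field()].
#'
#' @param object A `voxel_field`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.voxel_field <- function(object, ...) {
  d <- dim(object$data)
  df <- tidyr::expand_grid(j = seq_len(d[2]), i = seq_len(d[1]))
  df$value <- as.numeric(object$data[, , 1])[(df$j - 1L) * d[1] + df$i]
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "value") +
    theme_minimal()
}

#' Plot a per-element field on its mesh
#'
#' Draws each quad element filled by a per-element value (e.g. peak strain).
#'
#' @param mesh A `brain_mesh`.
#' @param values Per-element numeric vector.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_element_field <- function(mesh, values, name = "value") {
  ne <- nrow(mesh$elems)
  ids <- rep(seq_len(ne), each = 4)
  nd <- as.integer(t(mesh$elems))
  df <- tibble::tibble(id = ids,
                       x = 1000 * mesh$nodes[nd, 1],
                       y = 1000 * mesh$nodes[nd, 2],
                       value = rep(values, each = 4))
  ggplot(df, aes(x = .data$x, y = .data$y, group = .data$id,
                 fill = .data$value)) +
    geom_polygon(colour = NA) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = name) +
    theme_minimal()
}

#' Plot sulcal vs gyral strain across profiles
#'
#' Boxplots of per-impact sulcal and gyral mean strain (and strain rate)
#' by exposure profile.
#'
#' @param object A `cohort_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cohort_table <- function(object, ...) {
  long <- object |>
    dplyr::select("event_id", "profile", "sulcal_mean_strain",
                  "gyral_mean_strain", "sulcal_mean_strain_rate",
                  "gyral_mean_strain_rate") |>
    tidyr::pivot_longer(-c("event_id", "profile")) |>
    tidyr::separate_wider_regex(
      "name", c(region = "sulcal|gyral", "_mean_", metric = ".*"))
  ggplot(long, aes(x = factor(.data$profile), y = .data$value,
                   fill = .data$region)) +
    geom_boxplot(position = position_dodge()) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "player position profile", y = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot kinematics correlation strengths
#'
#' Point ranges of r^2 with Fisher-z confidence intervals per
#' response/predictor pair.
#'
#' @param object A `kin_correlations` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kin_correlations <- function(object, ...) {
  ggplot(object, aes(x = .data$predictor, y = .data$r2,
                     ymin = .data$r2_lo, ymax = .data$r2_hi)) +
    geom_pointrange() +
    facet_wrap(~response) +
    labs(x = NULL, y = expression(r^2)) +
    theme_minimal()
}
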