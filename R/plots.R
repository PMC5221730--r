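# ggplot2 views of the main result types

#' @export
autoplot.af_population <- function(object, x = "gNa", y = "gCaL", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                       colour = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = paste(x, "scale"), y = paste(y, "scale"),
                  colour = "calibrated") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.af_group_comparison <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("median_true", "median_false"),
                           names_to = "group", values_to = "median")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$median,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = dplyr::filter(tidy(object), .data$significant),
                        ggplot2::aes(x = .data$term, y = 0), inherit.aes = FALSE,
                        shape = 8, size = 2) +
    ggplot2::labs(x = NULL, y = "group median scale factor",
                  caption = "* p below the configured alpha") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat map of partial correlations
#'
#' Mirrors the conductance-by-biomarker partial-correlation panels: one tile
#' per (conductance, outcome) pair, signed colour scale.
#'
#' @param ... One or more `af_pcr` results.
#' @return A ggplot object.
#' @export
plot_pcr_heatmap <- function(...) {
  d <- dplyr::bind_rows(lapply(list(...), tidy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$outcome,
                                  fill = .data$pcr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pcr)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Snapshot of a voltage or phase frame
#'
#' @param movie A `voltage_movie` or `phase_movie`.
#' @param at Time (ms) of the frame to draw.
#' @return A ggplot object (sheet meshes: tile map; spheres: Aitoff
#'   projection).
#' @export
plot_frame <- function(movie, at = 0) {
  is_phase <- inherits(movie, "phase_movie")
  val <- if (is_phase) movie$phase else movie$V
  i <- which.min(abs(movie$time - at))
  mesh <- movie$mesh
  d <- tibble(x = mesh$points[, 1], y = mesh$points[, 2],
              z = mesh$points[, 3], v = val[, i])
  if (mesh$kind == "sphere") {
    # Aitoff projection of (lon, lat)
    lon <- atan2(d$y, d$x)
    lat <- asin(d$z / sqrt(d$x^2 + d$y^2 + d$z^2))
    a <- acos(pmin(pmax(cos(lat) * cos(lon / 2), -1), 1))
    sinc <- ifelse(a == 0, 1, sin(a) / a)
    d$px <- 2 * cos(lat) * sin(lon / 2) / sinc
    d$py <- sin(lat) / sinc
  } else {
    d$px <- d$x; d$py <- d$y
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$px, y = .data$py,
                                       colour = .data$v)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (is_phase)
    p + ggplot2::scale_colour_gradientn(colours = c("#2166ac", "#f7f7f7",
                                                    "#b2182b", "#2166ac"),
                                        limits = c(-pi, pi), name = "phase")
  else
    p + ggplot2::scale_colour_viridis_c(name = "V (mV)")
}
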