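# ggplot2 visualizations for gait inputs, simulation outputs and contact
# fields.

#' Plot the gait input waveforms
#'
#' Faceted line plot of all input channels over stance.
#'
#' @param gait A `gait_series`.
#' @return A ggplot object.
#' @export
plot_gait <- function(gait) {
  long <- tidyr::pivot_longer(tibble::as_tibble(gait),
                              -"stance_fraction",
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stance_fraction,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "stance fraction", y = NULL,
                  title = "Stance-phase input waveforms") +
    ggplot2::theme_minimal()
}

#' Plot contact reactions over stance for one or more simulations
#'
#' @param ... `knee_sim` objects (named arguments become legend labels;
#'   unnamed ones are labelled by their mode).
#' @return A ggplot object.
#' @export
plot_reactions <- function(...) {
  sims <- list(...)
  nms <- names(sims)
  if (is.null(nms)) nms <- rep("", length(sims))
  lab <- purrr::imap_chr(sims, function(s, i) {
    if (nzchar(nms[[i]])) nms[[i]] else paste("mode", s$mode$model_id)
  })
  long <- purrr::map2_dfr(sims, lab, function(s, l) {
    dplyr::mutate(
      tidyr::pivot_longer(
        dplyr::select(s$steps, "stance_fraction", "R_axial_BW",
                      "R_ap_BW", "R_ml_BW"),
        -"stance_fraction", names_to = "reaction", values_to = "BW"),
      model = l)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stance_fraction,
                                     y = .data$BW, colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$reaction), scales = "free_y") +
    ggplot2::labs(x = "stance fraction", y = "reaction (BW)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-compartment tissue response
#'
#' @param response A [compartment_response()] tibble.
#' @param variables Columns to facet (default pressure, area, strain).
#' @return A ggplot object.
#' @export
plot_compartment <- function(response,
                             variables = c("peak_pressure_MPa",
                                           "contact_area_mm2",
                                           "min_log_strain")) {
  long <- tidyr::pivot_longer(response, dplyr::all_of(variables),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stance_fraction,
                                     y = .data$value,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "stance fraction", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Contact traction map at one stance fraction
#'
#' @param sim A `knee_sim`.
#' @param stance_fraction Requested stance fraction (nearest step is used).
#' @return A ggplot object (tile map over the plateau).
#' @export
plot_contact_map <- function(sim, stance_fraction = 0.5) {
  j <- which.min(abs(sim$steps$stance_fraction - stance_fraction))
  df <- dplyr::mutate(sim$columns,
                      traction_MPa = sim$fields[[j]]$traction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$x,
                                   fill = .data$traction_MPa)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "medial-lateral (mm)", y = "posterior-anterior (mm)",
      fill = "MPa",
      title = paste0("Contact traction, mode ", sim$mode$model_id, ", ",
                     round(100 * sim$steps$stance_fraction[j]), "% stance")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.gait_series` is [plot_gait()]; `autoplot.knee_sim` is
#' [plot_reactions()]; `autoplot.qf_sweep` shows the discrepancy against the
#' surrogate scale.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-kneedrive
NULL

#' @rdname autoplot-kneedrive
#' @method autoplot gait_series
#' @export
autoplot.gait_series <- function(object, ...) plot_gait(object)

#' @rdname autoplot-kneedrive
#' @method autoplot knee_sim
#' @export
autoplot.knee_sim <- function(object, ...) plot_reactions(object)

#' @rdname autoplot-kneedrive
#' @method autoplot qf_sweep
#' @export
autoplot.qf_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qf_scale,
                                       y = .data$discrepancy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "best"),
                        linetype = "dashed") +
    ggplot2::labs(x = "anterior-posterior quadriceps surrogate scale",
                  y = "discrepancy vs reference") +
    ggplot2::theme_minimal()
}
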