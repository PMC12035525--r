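#' Plot leaf optical properties
#'
#' @param object A `leaf_optics` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot leaf_optics
#' @export
autoplot.leaf_optics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("reflectance", "transmittance", "absorption"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$wavelength_nm, .data$value,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "Fraction", colour = NULL,
      title = "Leaf optical properties"
    ) +
    ggplot2::theme_minimal()
}

#' Plot canopy reflectance spectra
#'
#' @param object A `canopy_reflectance` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canopy_reflectance
#' @export
autoplot.canopy_reflectance <- function(object, ...) {
  cols <- intersect(c("rho", "rho_s", "rho_d"), names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(cols),
    names_to = "stream", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$wavelength_nm, .data$value,
    colour = .data$stream
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "Reflectance", colour = NULL,
      title = "Canopy reflectance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a trait-swap impact table
#'
#' Bar chart of total impacts (positive = toward the liana signal).
#'
#' @param object A `trait_swap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trait_swap_result
#' @export
autoplot.trait_swap_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$impact)
  df$swap <- factor(df$swap, levels = df$swap)
  ggplot2::ggplot(df, ggplot2::aes(.data$impact, .data$swap)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Impact on divergence toward liana signal (nats)", y = NULL,
      title = "Trait-swap importance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot divergence-versus-resolution curves
#'
#' @param curves Combined tibble from [scene_kld_curve()] /
#'   [random_baseline_curve()] runs; the `cluster_area` column
#'   distinguishes scenarios (1 = random baseline).
#' @return A ggplot with mean curves per scenario on log-x resolution.
#' @export
plot_kld_curves <- function(curves) {
  summ <- curves |>
    dplyr::group_by(.data$cluster_area, .data$resolution) |>
    dplyr::summarise(kld = mean(.data$kld, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(scenario = ifelse(
      .data$cluster_area <= 1, "random",
      paste0(.data$cluster_area, " m²")
    ))
  ggplot2::ggplot(summ, ggplot2::aes(
    .data$resolution, .data$kld,
    colour = .data$scenario, linetype = .data$scenario == "random"
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(
      x = "Resolution (m)", y = "Mean divergence (nats)",
      colour = "Cluster scale",
      title = "Detectability versus spatial resolution"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data .env
NULL
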