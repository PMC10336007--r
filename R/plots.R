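#' Plot a contact map
#'
#' Log-scaled heat map of the contact probabilities.
#'
#' @param object A [contact_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  n <- n_bins(object)
  df <- tidyr::expand_grid(i = seq_len(n) - 1L, j = seq_len(n) - 1L)
  df$p <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = log10(pmax(.data$p, 1e-6)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log10 P") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin j", y = "bin i") +
    ggplot2::theme_minimal()
}

#' Plot a radius-of-gyration profile
#'
#' @param profile Tibble from [rg_profile()].
#' @return A ggplot object with a mean line and a +/- 1 SD ribbon.
#' @export
plot_rg_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$start, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (bead)", y = "Rg (sigma)") +
    ggplot2::theme_minimal()
}

#' Plot an angle distribution and its sine-corrected density
#'
#' @param dist Tibble from [angle_distribution()].
#' @return A ggplot object.
#' @export
plot_angle_distribution <- function(dist) {
  long <- tidyr::pivot_longer(dist, c("p", "p_sin"), names_to = "measure",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$density,
                                     colour = .data$measure)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_discrete(labels = c(p = "P(theta)",
                                              p_sin = "P(theta)/sin(theta)")) +
    ggplot2::labs(x = "theta (degrees)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a tabulated potential
#'
#' @param object A [tabulated_potential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tabulated_potential
#' @export
autoplot.tabulated_potential <- function(object, ...) {
  df <- tibble::tibble(r = object$r, v = object$v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "r (sigma)", y = "V (kBT)") +
    ggplot2::theme_minimal()
}

#' Plot the KL convergence history of an IBI run
#'
#' @param object An `ibi_result` from [run_ibi()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled KL axis).
#' @method autoplot ibi_result
#' @export
autoplot.ibi_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$kl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "IBI iteration", y = "KL(target || simulated)") +
    ggplot2::theme_minimal()
}

#' Plot the additive bond-angle / dihedral energy surface
#'
#' @param energy_map Tibble from [angle_dihedral_energy_map()].
#' @return A ggplot heat map.
#' @export
plot_energy_map <- function(energy_map) {
  ggplot2::ggplot(energy_map, ggplot2::aes(x = .data$theta, y = .data$phi,
                                           fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (kBT)", na.value = "grey90") +
    ggplot2::labs(x = "theta (degrees)", y = "phi (degrees)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
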