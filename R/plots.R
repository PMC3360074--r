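# ggplot2 display helpers.

#' Plot a stimulus as oriented edge elements
#'
#' Draws every edge as a short segment along its direction, coloured by role.
#'
#' @param stimuli A stimulus tibble.
#' @param stimulus_id Which stimulus to draw (default: the first).
#' @param segment_length Drawn segment length, DVA.
#' @return A ggplot object.
#' @export
plot_stimulus <- function(stimuli, stimulus_id = NULL, segment_length = 0.8) {
  if (is.null(stimulus_id)) stimulus_id <- stimuli$stimulus_id[1]
  sid <- stimulus_id
  st <- stimuli %>% filter(.data$stimulus_id == sid, .data$role != "mask")
  h <- segment_length / 2
  ggplot2::ggplot(st) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x - h * cos(.data$theta), y = .data$y - h * sin(.data$theta),
      xend = .data$x + h * cos(.data$theta),
      yend = .data$y + h * sin(.data$theta),
      colour = .data$role
    ), linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(contour = "#d1351b",
                                            decoy = "#2b6fb3",
                                            background = "grey35")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (DVA)", y = "y (DVA)",
                  title = sid,
                  subtitle = paste("target:", st$target_side[1])) +
    ggplot2::theme_minimal()
}

#' @describeIn symmetrize_af_dynamics Heat-map of the mean likelihood per
#'   contour position across iterations.
#' @param object An `af_dynamics` tibble.
#' @param ... Unused.
#' @export
autoplot.af_dynamics <- function(object, ...) {
  d <- object %>%
    filter(.data$position != "background") %>%
    mutate(position = as.integer(.data$position)) %>%
    group_by(.data$iteration, .data$position) %>%
    summarise(likelihood = mean(.data$likelihood), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$iteration,
                                  fill = .data$likelihood)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean\nlikelihood") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "contour position", y = "iteration",
                  title = sprintf("Likelihood dynamics (%s association field)",
                                  attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' @describeIn grid_search Tile maps of `Phi_MH` over the angular scales,
#'   faceted by the eccentricity-scaling parameters; inadmissible candidates
#'   are blanked.
#' @param object An `af_grid_search` object.
#' @param ... Unused.
#' @export
autoplot.af_grid_search <- function(object, ...) {
  m <- object$map %>%
    mutate(phi_shown = ifelse(.data$admissible, .data$phi_mh, NA_real_))
  b <- object$best
  ggplot2::ggplot(m, ggplot2::aes(x = factor(round(.data$sigma_align, 4)),
                                  y = factor(round(.data$sigma_curv, 4)),
                                  fill = .data$phi_shown)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = m %>% filter(.data$sigma_align == b$sigma_align,
                          .data$sigma_curv == b$sigma_curv,
                          .data$amplitude == b$amplitude,
                          .data$gamma == b$gamma),
      colour = "purple", shape = 1, size = 4, stroke = 1.2) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$amplitude),
      cols = ggplot2::vars(.data$gamma),
      labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = expression(Phi[MH]), na.value = "white") +
    ggplot2::labs(x = "sigma_align (rad)", y = "sigma_curv (rad)",
                  title = "Model search: excess correlation with reference decisions",
                  subtitle = "white = performance below reference (inadmissible)") +
    ggplot2::theme_minimal()
}

#' Plot SOA performance curves
#'
#' @param curves Output of [soa_performance_curve()].
#' @return A ggplot object.
#' @export
plot_soa_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$soa,
                                       y = .data$fraction_correct,
                                       colour = .data$ensemble_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "SOA (ms)", y = "fraction correct") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot association-field cross-sections
#'
#' Shows the angular part of the link density as a function of the viewing
#' angle `phi` for several direction differences, and the radial part.
#'
#' @param params An [af_params()] object.
#' @param dthetas Direction differences (radians) to draw.
#' @return A ggplot object.
#' @export
plot_af_sections <- function(params, dthetas = c(0, pi / 6, pi / 3)) {
  phi <- seq(-pi, pi, length.out = 361)
  d <- purrr::map(dthetas, function(dt) {
    tibble(phi = phi, dtheta = sprintf("%.2f", dt),
           density = af_angular_density(phi, dt, params))
  }) %>% bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$density,
                                  colour = .data$dtheta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(phi ~ "(rad)"), y = "angular link density",
                  colour = expression(Delta * theta),
                  title = "Association field: angular part") +
    ggplot2::theme_minimal()
}

#' Plot the eccentricity-salience curve
#'
#' @param ecc An [ecc_params()] object.
#' @return A ggplot object showing `w(eps)` from fixation to `eps_max`.
#' @export
plot_salience_curve <- function(ecc) {
  eps <- seq(0, ecc$eps_max, length.out = 200)
  d <- tibble(eps = eps,
              w = 1 - ecc$amplitude * (eps / ecc$eps_max)^ecc$exponent)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eps, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "eccentricity (DVA)", y = "edge salience w") +
    ggplot2::theme_minimal()
}
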