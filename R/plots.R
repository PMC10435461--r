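#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy surface
#'
#' 2-D surfaces render as a filled raster of G (kcal/mol) with not-sampled
#' cells blank; 1-D surfaces as a line.
#'
#' @param object An `fel_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fel_surface <- function(object, ...) {
  df <- as.data.frame(object)
  df$G[!is.finite(df$G)] <- NA
  if ("y" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$G)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white",
                                    name = "G (kcal/mol)") +
      ggplot2::labs(x = "CV 1", y = "CV 2") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df[is.finite(df$G), ],
                    ggplot2::aes(x = .data$x, y = .data$G)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "CV", y = "G (kcal/mol)") +
      ggplot2::theme_minimal()
  }
}

#' Plot an interaction-energy profile
#'
#' Per-frame electrostatic, van der Waals and total interaction energies,
#' with the tightly/loosely bound frames marked.
#'
#' @param object An `energy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("e_elect", "e_vdw", "delta_e"),
                              names_to = "component", values_to = "energy")
  s <- summarize_profile(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$energy,
                                     colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(s$tb_frame, s$lb_frame),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "frame", y = "energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue projected electric-field profile
#'
#' Mean projected field per residue with a +/- sd ribbon and the
#' significance threshold line.
#'
#' @param object An `ef_profile`.
#' @param threshold Significance threshold to mark (MV/cm).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ef_profile <- function(object, threshold = 7.5, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$resid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "projected EF (MV/cm)") +
    ggplot2::theme_minimal()
}

#' Plot core-state assignments in collective-variable space
#'
#' @param assignment A `state_assignment` from [extract_core_states()].
#' @param points The projected coordinates the assignment was made on
#'   (first two columns are used).
#' @return A ggplot object.
#' @export
plot_core_states <- function(assignment, points) {
  df <- as.data.frame(points)[, 1:2]
  names(df) <- c("cv1", "cv2")
  df$state <- factor(assignment$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv1, y = .data$cv2,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6, na.rm = FALSE) +
    ggplot2::scale_colour_discrete(na.value = "grey80", name = "core state") +
    ggplot2::labs(x = "CV 1", y = "CV 2") +
    ggplot2::theme_minimal()
}
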