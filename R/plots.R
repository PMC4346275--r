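#' Plot a pursuit simulation
#'
#' Two panels worth of information in one plot: realised eye and target
#' trajectories over time, with occluded segments shaded.
#'
#' @param object A `pursuit_sim` from [simulate_pursuit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pursuit_sim <- function(object, ...) {
  st <- object$states
  long <- tidyr::pivot_longer(
    dplyr::select(st, "t_ms", "carrier", "eye"),
    cols = c("carrier", "eye"), names_to = "trace", values_to = "position")
  occ <- dplyr::filter(st, .data$occluded)
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms / 1000, .data$position,
                                     colour = .data$trace)) +
    ggplot2::geom_point(data = occ,
                        ggplot2::aes(y = 0, x = .data$t_ms / 1000),
                        inherit.aes = FALSE, colour = "grey80", shape = 15,
                        size = 3, alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(carrier = "black",
                                            eye = "firebrick")) +
    ggplot2::labs(x = "time (s)", y = "displacement (amplitude units)",
                  colour = NULL,
                  title = "Simulated pursuit of an occluded target") +
    ggplot2::theme_minimal()
}

#' Plot the position error of a simulation
#'
#' @param sim A `pursuit_sim`.
#' @return A ggplot object of eye-minus-target error against cycle phase.
#' @export
plot_position_error <- function(sim) {
  pe <- position_error(sim)
  ggplot2::ggplot(pe, ggplot2::aes(.data$phase, .data$error,
                                   group = .data$cycle,
                                   colour = factor(.data$cycle))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle phase", y = "position error (amplitude units)",
                  colour = "cycle") +
    ggplot2::theme_minimal()
}

#' Plot grand-averaged trajectories or errors
#'
#' @param object A `grand_average` tibble.
#' @param what `"error"` or `"trajectory"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grand_average <- function(object, what = c("error", "trajectory"),
                                   ...) {
  what <- match.arg(what)
  if (what == "error") {
    ggplot2::ggplot(object, ggplot2::aes(.data$phase, .data$error,
                                         colour = .data$condition)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "cycle phase",
                    y = "position error (amplitude units)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$phase, .data$eye,
                                         colour = .data$condition)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$carrier), colour = "black",
                         linetype = 2) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "cycle phase", y = "displacement (amplitude units)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot posterior deviations of a fitted DCM
#'
#' Posterior means of the latent deviations with 90% credible intervals,
#' grouped by effect (baseline, noise, speed); precision parameters are
#' highlighted.
#'
#' @param object A `pursuit_dcm` fit.
#' @param conf.level Credible level for the bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pursuit_dcm <- function(object, conf.level = 0.9, ...) {
  td <- tidy(object, conf.level = conf.level)
  td$param <- factor(td$param, levels = param_names())
  td$kind <- ifelse(grepl("^lnPi", as.character(td$param)), "precision",
                    "other")
  ggplot2::ggplot(td, ggplot2::aes(.data$param, .data$estimate,
                                   fill = .data$kind)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.3, colour = "deeppink3") +
    ggplot2::facet_wrap(~effect, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(precision = "darkcyan",
                                          other = "grey50"), guide = "none") +
    ggplot2::labs(x = NULL, y = "posterior deviation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
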