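#' Plot a concentration trajectory
#'
#' Plasma and effect-site propofol concentration against time.
#'
#' @param object A `ce_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("time_s", "cp_ug_ml", "ce_ug_ml")],
                              -"time_s", names_to = "compartment",
                              values_to = "concentration")
  long$compartment <- dplyr::recode(long$compartment,
                                    cp_ug_ml = "plasma", ce_ug_ml = "effect site")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$concentration,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since infusion start (s)",
                  y = expression("propofol concentration (" * mu * "g/mL)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one EMG sweep
#'
#' Raw sweep amplitude with the T1 (R1) and T2 (R2) analysis windows shaded.
#'
#' @param samples Numeric sweep samples, µV.
#' @param fs Sampling rate, Hz.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_sweep <- function(samples, fs = 10000, title = NULL) {
  d <- tibble(t_ms = (seq_along(samples) - 1) / fs * 1000, uv = samples)
  shade <- tibble(lo = c(10, 25), hi = c(25, 200), window = c("T1", "T2"))
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = -Inf, ymax = Inf, fill = .data$window),
                       alpha = 0.12, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(.data$t_ms, .data$uv), linewidth = 0.3) +
    ggplot2::labs(x = "time after stimulus (ms)",
                  y = expression("amplitude (" * mu * "V)"),
                  fill = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Plot a simulated session
#'
#' Effect-site concentration with the sedation staircase and the
#' ground-truth endpoints.
#'
#' @param object A `blink_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blink_session <- function(object, ...) {
  traj <- object$trajectory
  sed <- object$sedation
  truth <- object$truth
  ggplot2::ggplot(traj, ggplot2::aes(.data$time_s, .data$ce_ug_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_step(data = sed,
                       ggplot2::aes(.data$time_s, -.data$arass),
                       colour = "grey50", linetype = 2) +
    ggplot2::geom_vline(data = truth,
                        ggplot2::aes(xintercept = .data$time_s),
                        colour = "firebrick", alpha = 0.6) +
    ggplot2::annotate("text", x = truth$time_s, y = max(traj$ce_ug_ml),
                      label = toupper(truth$endpoint), hjust = -0.1, size = 3) +
    ggplot2::labs(x = "time since infusion start (s)",
                  y = expression("effect-site Ce (" * mu *
                                   "g/mL); dashed: -aRASS")) +
    ggplot2::theme_minimal()
}

#' Plot a Pk table
#'
#' Direction-folded prediction probability with jackknife standard errors
#' per feature and analysis window; the dashed lines mark chance (0.5) and
#' the feature-selection threshold (0.7).
#'
#' @param object A `pk_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$pk, stats::reorder(.data$feature, .data$pk),
                               colour = .data$window)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$pk - .data$se, xmax = .data$pk + .data$se),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = expression(P[k]), y = NULL, colour = "window") +
    ggplot2::theme_minimal()
}
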