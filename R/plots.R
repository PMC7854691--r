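#' Plot a solved race trajectory
#'
#' Facets the instantaneous speed, propulsive force and remaining
#' anaerobic energy against distance, with bends shaded.
#'
#' @param object A `race_trajectory`.
#' @param shade_bends Shade the bend segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.race_trajectory <- function(object, shade_bends = TRUE, ...) {
  track <- attr(object, "track")
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s_m", "v_mps", "f_Nkg", "e_Jkg")],
    cols = c("v_mps", "f_Nkg", "e_Jkg"),
    names_to = "state", values_to = "value"
  )
  df$state <- factor(df$state, levels = c("v_mps", "f_Nkg", "e_Jkg"),
                     labels = c("speed (m/s)", "force (N/kg)",
                                "anaerobic energy (J/kg)"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s_m, y = .data$value))
  if (shade_bends && !is.null(track)) {
    seg <- segment_boundaries(track)
    bends <- seg[seg$type == "bend", ]
    p <- p + ggplot2::geom_rect(
      data = bends,
      ggplot2::aes(xmin = .data$start_m, xmax = .data$end_m),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "distance (m)", y = NULL,
                  title = sprintf("Optimal race, final time %s",
                                  format_race_time(attr(object, "final_time")))) +
    ggplot2::theme_minimal()
}

#' Plot a split series
#'
#' @param object A `split_series`.
#' @param ... Unused.
#' @return A ggplot object (step plot of mean speed per segment).
#' @export
autoplot.split_series <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$distance_end_m, y = .data$mean_speed_mps)
  ) +
    ggplot2::geom_step(direction = "vh", colour = "#2c7fb8") +
    ggplot2::labs(x = "distance (m)", y = "mean speed (m/s)") +
    ggplot2::theme_minimal()
}

#' Plot a speed corridor
#'
#' @param object A `speed_corridor`.
#' @param ... Unused.
#' @return A ggplot object (ribbon of the admissible speeds).
#' @export
autoplot.speed_corridor <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start_m + df$end_m) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$v_lo, ymax = .data$v_hi),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = (.data$v_lo + .data$v_hi) / 2),
                       linetype = "dashed") +
    ggplot2::labs(x = "distance (m)", y = "speed (m/s)",
                  title = "Tactical speed corridor") +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' @param object A `scenario_report`.
#' @param ... Unused.
#' @return A ggplot object comparing per-split mean speeds.
#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$splits,
                            cols = c("v_base", "v_variant"),
                            names_to = "run", values_to = "v")
  df$run <- factor(df$run, levels = c("v_base", "v_variant"),
                   labels = c("baseline", "variant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_end_m, y = .data$v,
                                   colour = .data$run)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(
      x = "distance (m)", y = "mean speed (m/s)", colour = NULL,
      title = sprintf("Scenario comparison (delta_t = %+.2f s)",
                      object$delta_t)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' @param object A `pace_fit`.
#' @param ... Unused.
#' @return A ggplot object of observed vs fitted mean speeds.
#' @export
autoplot.pace_fit <- function(object, ...) {
  obs <- tibble::as_tibble(object$observed)
  # residuals are simulated minus observed, in the fit metric's units
  obs$fitted <- if (object$metric == "speed") {
    obs$mean_speed_mps + object$residuals
  } else {
    seg_len <- attr(object$observed, "segment_length")
    seg_len / (obs$time_s + object$residuals)
  }
  df <- tidyr::pivot_longer(obs[, c("distance_end_m", "mean_speed_mps",
                                    "fitted")],
                            cols = c("mean_speed_mps", "fitted"),
                            names_to = "series", values_to = "v")
  df$series <- factor(df$series, levels = c("mean_speed_mps", "fitted"),
                      labels = c("observed", "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_end_m, y = .data$v,
                                   colour = .data$series)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "distance (m)", y = "mean speed (m/s)",
                  colour = NULL,
                  title = sprintf("Calibration fit (rmse %.3f)",
                                  object$rmse)) +
    ggplot2::theme_minimal()
}
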