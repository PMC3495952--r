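#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dense walk trajectory
#'
#' Facets of hip angle, angular velocity, ankle torques and ground reaction
#' forces against time, with double-stance spans distinguishable by the
#' torque traces.
#'
#' @param object a `walker_trajectory` tibble (from [simulate_walk()] with
#'   `record = TRUE`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.walker_trajectory <- function(object, ...) {
  df <- tibble::tibble(
    t = rep(object$t, 4),
    value = c(object$theta, object$theta_dot,
              object$torque_spring + object$torque_pulse,
              dplyr::coalesce(object$F_B, object$f_ss)),
    variable = rep(c("theta [rad]", "theta_dot [rad/s]",
                     "ankle torque [N·m]", "vertical-support GRF [N]"),
                   each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stride periods of a perturbed walk
#'
#' Stride period against stride number with the pulse period marked;
#' entrained gaits converge onto the dashed line.
#'
#' @param object an `entrainment_sim` from [simulate_perturbed()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.entrainment_sim <- function(object, ...) {
  ggplot2::ggplot(object$strides,
                  ggplot2::aes(x = .data$stride_index, y = .data$stride_period)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = object$pulse$period, linetype = "dashed") +
    ggplot2::labs(x = "stride number", y = "stride period [s]",
                  title = sprintf("tau_p = %.4f s — %s", object$pulse$period,
                                  if (object$entrained) "entrained" else "not entrained")) +
    ggplot2::theme_minimal()
}

#' Plot the locked-phase series of a perturbed walk
#'
#' Phase of the pulse onset relative to the perturbed leg's toe-off (as a
#' fraction of the stride, wrapped to \[-0.5, 0.5)) against stride number.
#' Entrained runs converge to a constant slightly below zero: the pulse
#' locks to the end of double stance.
#'
#' @param sim an `entrainment_sim`, or a list of them (e.g. several initial
#'   offsets).
#' @return a ggplot object.
#' @export
plot_phase_locking <- function(sim) {
  sims <- if (inherits(sim, "entrainment_sim")) list(sim) else sim
  df <- purrr::imap(sims, function(s, i) {
    tibble::tibble(run = as.character(i),
                   stride_index = s$strides$stride_index,
                   locked_phase = s$strides$locked_phase)
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stride_index, y = .data$locked_phase,
                                   colour = .data$run)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "stride number", y = "pulse phase re toe-off [stride]",
                  colour = "run") +
    ggplot2::theme_minimal()
}

#' Plot a basin-of-entrainment scan
#'
#' @param object a `basin_scan` from [basin_scan()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.basin_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$detuning_ms,
                                       y = as.integer(.data$entrained))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "detuning tau_p - 2 tau_0 [ms]", y = "entrained (all offsets)",
                  title = sprintf("basin width = %.2f%% of 2 tau_0",
                                  basin_width_pct(object))) +
    ggplot2::theme_minimal()
}

#' Plot the speed-versus-pulse-phase curve
#'
#' @param object a `speed_phase_curve` from [speed_vs_phase()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.speed_phase_curve <- function(object, ...) {
  v0 <- attr(object, "v0")
  ds <- attr(object, "ds_fraction")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = v0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = ds, linetype = "dotted") +
    ggplot2::labs(x = "pulse onset phase of the stride",
                  y = "average speed [m/s]") +
    ggplot2::theme_minimal()
}
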