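#' Plot a session's route with delivery moments
#'
#' The full trajectory as a thin path with the animal's location at each
#' delivery moment overplotted as black points, dispenser as an open
#' circle.
#'
#' @param session A [session_record()].
#' @return A ggplot object.
#' @export
plot_routes <- function(session) {
  stopifnot(inherits(session, "session_record"))
  fr <- session$trajectory$frames
  dm <- delivery_moments(session)
  a <- session$arena
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.2, colour = "grey55") +
    ggplot2::geom_point(data = dm, size = 0.9, colour = "black") +
    ggplot2::annotate("point", x = a$dispenser[1], y = a$dispenser[2],
                      shape = 21, size = 3, stroke = 1, colour = "red3") +
    ggplot2::coord_fixed(xlim = c(0, a$width), ylim = c(0, a$height),
                         expand = FALSE) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = sprintf("%s %s, session %d", session$subject,
                                  session$condition, session$session_index)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot an occupancy map as a heatmap
#'
#' Accumulated dwell time (s) per zone-grid region.
#'
#' @param occ An [occupancy_map()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ) {
  stopifnot(inherits(occ, "occupancy_map"))
  g <- occ$grid
  idx <- 0:(n_regions(g) - 1L)
  d <- tibble::tibble(
    col = idx %% g$n_cols, row = idx %/% g$n_cols,
    time = occ$time_per_region
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$time)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "time (s)") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "grid column", y = "grid row") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a recurrence matrix
#'
#' Black marks where the animal occupied the same region at both times.
#'
#' @param R A [recurrence_matrix()].
#' @return A ggplot object.
#' @export
plot_recurrence <- function(R) {
  stopifnot(inherits(R, "recurrence_matrix"))
  d <- tibble::tibble(
    i = rep(seq_len(R$n), times = R$n),
    j = rep(seq_len(R$n), each = R$n),
    rec = as.vector(R$indicator) == 1L
  )
  ggplot2::ggplot(d[d$rec, ], ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(fill = "black") +
    ggplot2::coord_fixed(xlim = c(0, R$n + 1), ylim = c(0, R$n + 1),
                         expand = FALSE) +
    ggplot2::labs(x = sprintf("frame (stride %d)", R$frame_stride),
                  y = "frame") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a relative-distance series with its moving average
#'
#' Raw per-frame relative distance as grey dots, trailing moving average
#' as a red line, against session time.
#'
#' @param ds A [relative_distance_series()] result.
#' @param traj The [trajectory()] it came from (for the time axis).
#' @return A ggplot object.
#' @export
plot_distance_series <- function(ds, traj) {
  stopifnot(inherits(ds, "distance_series"), inherits(traj, "trajectory"))
  d <- tibble::tibble(t = traj$frames$t, raw = ds$raw, smoothed = ds$smoothed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), size = 0.2,
                        colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red3") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "relative distance to dispenser") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a per-session metric across all sessions
#'
#' One line per subject over session index, with the condition change
#' marked. Used for the entropy and divergence series.
#'
#' @param metrics Metric table from [run_analyze()].
#' @param metric Column name to plot (e.g. `"entropy"`).
#' @return A ggplot object.
#' @export
plot_metric_series <- function(metrics, metric = "entropy") {
  stopifnot(metric %in% names(metrics))
  metrics <- metrics[!is.na(metrics[[metric]]), ]  # first sessions have no divergence
  transition <- max(metrics$session_index[metrics$condition == "center"]) + 0.5
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$session_index, y = .data[[metric]],
                               colour = .data$subject)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = transition, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~experiment) +
    ggplot2::labs(x = "session", y = metric) +
    ggplot2::theme_minimal(base_size = 9)
}
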