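#' Default run configuration
#'
#' The default mirrors the study layout: two experiments (FT then VT,
#' mean interval 30 s, 3-s availability), three subjects each, 20 sessions
#' per condition (centre then wall), 20-min sessions sampled at 0.2 s in a
#' 100 x 100 cm arena with a 10 x 10 zone grid and a 200-frame smoothing
#' window. Any field can be overridden via `...`, or from a YAML file with
#' [read_run_config()].
#'
#' @param ... Named overrides of the default fields.
#' @return A validated list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    experiments = list(
      list(id = "exp1", schedule_type = "FT", subject_offset = 0),
      list(id = "exp2", schedule_type = "VT", subject_offset = 3)
    ),
    n_subjects = 3,
    n_sessions = 20,
    session_length = 1200,
    mean_interval = 30,
    availability = 3,
    wall_offset = 5,
    width = 100, height = 100,
    grid_rows = 10, grid_cols = 10,
    sampling_period = 0.2,
    window = 200,
    pseudocount = 0.2,
    agent = unclass(agent_params()),
    master_seed = 1,
    figures = FALSE,
    figure_sessions = c(1, 10, 20)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_sessions >= 1,
            cfg$session_length > 0, cfg$mean_interval > 0,
            cfg$availability >= 0, cfg$grid_rows >= 1, cfg$grid_cols >= 1,
            cfg$sampling_period > 0, cfg$window >= 1, cfg$pseudocount > 0)
  do.call(agent_params, cfg$agent)  # validates agent fields
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [default_config()];
#' anything not named keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(vals)) {
    if (nm == "agent") {
      for (an in names(vals$agent)) cfg$agent[[an]] <- vals$agent[[an]]
    } else cfg[[nm]] <- vals[[nm]]
  }
  validate_config(cfg)
  cfg
}

#' Analyse a list of sessions into a metric table
#'
#' Computes [session_metrics()] for every session, chaining each subject's
#' sessions in `session_index` order so that the divergence column compares
#' consecutive sessions. Sessions failing [validate_session()] abort the
#' run with the session id and the finding list. Optionally writes the
#' metric table, figures and a provenance block to `out_dir`.
#'
#' @param sessions List of [session_record()]s.
#' @param grid_rows,grid_cols Zone-grid resolution.
#' @param window,pseudocount,detect_radius Analysis settings (see
#'   [session_metrics()]).
#' @param out_dir Output directory, or `NULL` for no files.
#' @param figures Also write per-session figures (routes, occupancy) and
#'   per-subject entropy/divergence series.
#' @param figure_sessions Session indices to draw per-session figures for.
#' @param config The effective configuration echoed into provenance.
#' @return A list of class `report_bundle`: `metrics` (tibble), `paths`
#'   (named list of written files) and `provenance`.
#' @export
run_analyze <- function(sessions, grid_rows = 10, grid_cols = 10,
                        window = 200, pseudocount = 0.2, detect_radius = 5,
                        out_dir = NULL, figures = FALSE,
                        figure_sessions = c(1, 10, 20), config = NULL) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  for (s in sessions) {
    findings <- validate_session(s)
    if (length(findings))
      stop(sprintf("session %s/%s #%d failed validation:\n  - %s",
                   s$subject, s$condition, s$session_index,
                   paste(findings, collapse = "\n  - ")), call. = FALSE)
  }
  subjects <- vapply(sessions, `[[`, character(1), "subject")
  idx <- vapply(sessions, `[[`, integer(1), "session_index")
  ord <- order(subjects, idx)
  rows <- vector("list", length(sessions))
  prev_by_subject <- list()
  for (i in ord) {
    s <- sessions[[i]]
    grid <- zone_grid(s$arena, grid_rows, grid_cols)
    prev <- prev_by_subject[[s$subject]]
    message(sprintf("analyzing %s %s %s session %d (%d frames, %d deliveries)",
                    s$experiment, s$subject, s$condition, s$session_index,
                    nrow(s$trajectory$frames), length(s$deliveries$onsets)))
    rows[[i]] <- session_metrics(s, grid, previous = prev, window = window,
                                 pseudocount = pseudocount,
                                 detect_radius = detect_radius)
    prev_by_subject[[s$subject]] <- s
  }
  metrics <- do.call(rbind, rows)
  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths$metrics <- file.path(out_dir, "session_metrics.csv")
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
    prov <- list(
      package_version = as.character(utils::packageVersion("mofs")),
      n_sessions = length(sessions),
      settings = list(grid_rows = grid_rows, grid_cols = grid_cols,
                      window = window, pseudocount = pseudocount,
                      detect_radius = detect_radius),
      config = if (is.null(config)) NULL else unclass(config)
    )
    paths$provenance <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    if (figures) {
      fig_dir <- file.path(out_dir, "figures")
      if (!dir.exists(fig_dir)) dir.create(fig_dir)
      for (i in seq_along(sessions)) {
        s <- sessions[[i]]
        within_cond <- s$session_index -
          (if (s$condition == "wall") max(idx[subjects == s$subject &
            vapply(sessions, `[[`, character(1), "condition") == "center"],
            0L) else 0L)
        if (!(within_cond %in% figure_sessions)) next
        stem <- sprintf("%s_%s_%s_s%02d", s$experiment, s$subject,
                        s$condition, s$session_index)
        grid <- zone_grid(s$arena, grid_rows, grid_cols)
        f1 <- file.path(fig_dir, paste0(stem, "_route.png"))
        ggplot2::ggsave(f1, plot_routes(s), width = 4, height = 4, dpi = 120)
        f2 <- file.path(fig_dir, paste0(stem, "_occupancy.png"))
        ggplot2::ggsave(f2, plot_occupancy(occupancy_map(s$trajectory, grid)),
                        width = 4.5, height = 4, dpi = 120)
        f3 <- file.path(fig_dir, paste0(stem, "_recurrence.png"))
        rr <- recurrence_matrix(region_sequence(s$trajectory, grid),
                                frame_stride = max(1L, nrow(s$trajectory$frames) %/% 400L))
        ggplot2::ggsave(f3, plot_recurrence(rr), width = 4, height = 4,
                        dpi = 120)
        f4 <- file.path(fig_dir, paste0(stem, "_distance.png"))
        ds <- relative_distance_series(s$trajectory, s$arena, window)
        ggplot2::ggsave(f4, plot_distance_series(ds, s$trajectory),
                        width = 5, height = 3, dpi = 120)
        paths$figures <- c(paths$figures, f1, f2, f3, f4)
      }
      f5 <- file.path(fig_dir, "entropy_series.png")
      ggplot2::ggsave(f5, plot_metric_series(metrics, "entropy"),
                      width = 6, height = 4, dpi = 120)
      f6 <- file.path(fig_dir, "divergence_series.png")
      ggplot2::ggsave(f6, plot_metric_series(metrics, "divergence_from_previous"),
                      width = 6, height = 4, dpi = 120)
      paths$figures <- c(paths$figures, f5, f6)
    }
  }
  structure(list(metrics = metrics, paths = paths,
                 provenance = list(config = config)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d sessions analysed\n", nrow(x$metrics)))
  if (length(x$paths))
    cat("  files:", paste(unlist(x$paths[c("metrics", "provenance")]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Simulate and analyse a full configured run
#'
#' Runs [simulate_experiment()] for every experiment in the configuration,
#' then [run_analyze()] on all sessions. Deterministic under a fixed
#' `master_seed`.
#'
#' @param config A `run_config` from [default_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A `report_bundle` (see [run_analyze()]).
#' @export
run_full <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  params <- do.call(agent_params, config$agent)
  sessions <- list()
  for (ex in config$experiments) {
    sessions <- c(sessions, simulate_experiment(
      experiment = ex$id, schedule_type = ex$schedule_type,
      n_subjects = config$n_subjects, n_sessions = config$n_sessions,
      session_length = config$session_length,
      mean_interval = config$mean_interval,
      availability = config$availability, wall_offset = config$wall_offset,
      width = config$width, height = config$height,
      grid_rows = config$grid_rows, grid_cols = config$grid_cols,
      params = params, sampling_period = config$sampling_period,
      master_seed = config$master_seed,
      subject_offset = ex$subject_offset %||% 0))
  }
  run_analyze(sessions, grid_rows = config$grid_rows,
              grid_cols = config$grid_cols, window = config$window,
              pseudocount = config$pseudocount,
              detect_radius = config$agent$detect_radius,
              out_dir = out_dir, figures = isTRUE(config$figures),
              figure_sessions = config$figure_sessions, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a configured run to disk
#'
#' Writes every simulated session (trajectory, deliveries, manifest) under
#' `out_dir` and returns the manifest paths; `run_analyze` can then be fed
#' from the manifests via [read_session()].
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return Character vector of manifest paths, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  validate_config(config)
  params <- do.call(agent_params, config$agent)
  manifests <- character(0)
  for (ex in config$experiments) {
    sessions <- simulate_experiment(
      experiment = ex$id, schedule_type = ex$schedule_type,
      n_subjects = config$n_subjects, n_sessions = config$n_sessions,
      session_length = config$session_length,
      mean_interval = config$mean_interval,
      availability = config$availability, wall_offset = config$wall_offset,
      width = config$width, height = config$height,
      grid_rows = config$grid_rows, grid_cols = config$grid_cols,
      params = params, sampling_period = config$sampling_period,
      master_seed = config$master_seed,
      subject_offset = ex$subject_offset %||% 0)
    dir <- file.path(out_dir, ex$id)
    for (s in sessions)
      manifests <- c(manifests, write_session(s, dir,
        stem = sprintf("%s_%s_%s_s%02d", ex$id, s$subject, s$condition,
                       s$session_index)))
  }
  invisible(manifests)
}
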