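#' Tracking trajectory
#'
#' A trajectory is the frame-by-frame (x, y) location of one animal, sampled
#' at a fixed period (0.2 s in the reference recording system). Frame times
#' must be strictly increasing and fall on the sampling lattice; gaps
#' (missing frames) are permitted at construction and can be repaired with
#' [fill_gaps()].
#'
#' @param t Numeric vector of frame times in seconds, strictly increasing.
#' @param x,y Numeric coordinate vectors in cm, same length as `t`.
#' @param sampling_period Sampling period in seconds; if `NULL`, inferred
#'   as the median successive time difference.
#' @return An object of class `trajectory`: a list with `sampling_period`
#'   and a tibble `frames` with columns `t`, `x`, `y`.
#' @export
trajectory <- function(t, x, y, sampling_period = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("trajectory frames must be finite", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop(sprintf("frame times must be strictly increasing (first violation at row %d)",
                 which(diff(t) <= 0)[1] + 1L), call. = FALSE)
  if (is.null(sampling_period)) {
    sampling_period <- if (length(t) > 1L) stats::median(diff(t)) else 0.2
  }
  if (!is.numeric(sampling_period) || sampling_period <= 0)
    stop("sampling_period must be positive", call. = FALSE)
  if (length(t) > 1L) {
    k <- diff(t) / sampling_period
    if (any(abs(k - round(k)) > 1e-6 / sampling_period) || any(round(k) < 1))
      stop("frame times must fall on the sampling lattice (tolerance 1e-6 s)",
           call. = FALSE)
  }
  structure(
    list(sampling_period = sampling_period,
         frames = tibble::tibble(t = t, x = x, y = y)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("<trajectory> %d frames at %g s (%.1f s span)\n",
              n, x$sampling_period,
              if (n) x$frames$t[n] - x$frames$t[1] else 0))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$frames)

#' Read a trajectory from a comma-separated file
#'
#' The file dialect is fixed: comma separators, dot decimals, UTF-8, one
#' header row `frame,t_s,x_cm,y_cm`; times in seconds, coordinates in cm.
#' Coordinates are validated against the arena rectangle and the first
#' offending row is named in the error.
#'
#' @param path File path.
#' @param arena An [arena_spec()] used for bounds validation.
#' @param tol Out-of-bounds tolerance in cm (tracking jitter at the walls).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, arena, tol = 1e-6) {
  stopifnot(inherits(arena, "arena_spec"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "t_s", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop("trajectory file must have columns frame, t_s, x_cm, y_cm",
         call. = FALSE)
  if (nrow(d) > 1L && any(diff(d$t_s) <= 0))
    stop(sprintf("non-monotone time at row %d of %s",
                 which(diff(d$t_s) <= 0)[1] + 1L, path), call. = FALSE)
  bad <- which(d$x_cm < -tol | d$x_cm > arena$width + tol |
               d$y_cm < -tol | d$y_cm > arena$height + tol)
  if (length(bad))
    stop(sprintf("out-of-bounds coordinate at row %d of %s: (%g, %g)",
                 bad[1], path, d$x_cm[bad[1]], d$y_cm[bad[1]]), call. = FALSE)
  trajectory(t = d$t_s,
             x = pmin(pmax(d$x_cm, 0), arena$width),
             y = pmin(pmax(d$y_cm, 0), arena$height))
}

#' Write a trajectory to a comma-separated file
#'
#' Deterministic formatting: header `frame,t_s,x_cm,y_cm`, six decimal
#' places, frame numbers recovered from the time lattice. Writing the same
#' trajectory twice yields byte-identical files.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  frame <- if (nrow(fr)) as.integer(round((fr$t - fr$t[1]) / traj$sampling_period)) else integer(0)
  lines <- c("frame,t_s,x_cm,y_cm",
             sprintf("%d,%.6f,%.6f,%.6f", frame, fr$t, fr$x, fr$y))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Fill short tracking gaps by linear interpolation
#'
#' Tracking systems drop frames; gaps of at most `max_gap` missing frames
#' are filled by linear interpolation of x and y on the sampling lattice.
#' Existing frames are never altered. Since the arena is convex, the
#' interpolated points are in bounds whenever their neighbours are.
#'
#' @param traj A [trajectory()] (possibly with gaps).
#' @param max_gap Maximum number of consecutive missing frames to fill.
#' @return A gap-free [trajectory()].
#' @export
fill_gaps <- function(traj, max_gap = 5) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  dt <- traj$sampling_period
  if (nrow(fr) < 2L) return(traj)
  k <- round(diff(fr$t) / dt)
  gaps <- which(k > 1)
  if (!length(gaps)) return(traj)
  too_long <- gaps[k[gaps] - 1 > max_gap]
  if (length(too_long)) {
    i <- too_long[1]
    stop(sprintf("gap of %d missing frames between t = %.3f s and t = %.3f s exceeds max_gap = %d",
                 k[i] - 1, fr$t[i], fr$t[i + 1], max_gap), call. = FALSE)
  }
  tt <- fr$t[1] + dt * seq(0, round((fr$t[nrow(fr)] - fr$t[1]) / dt))
  # snap to existing times where present, interpolate elsewhere
  xs <- stats::approx(fr$t, fr$x, xout = tt)$y
  ys <- stats::approx(fr$t, fr$y, xout = tt)$y
  have <- round((fr$t - fr$t[1]) / dt) + 1L
  xs[have] <- fr$x; ys[have] <- fr$y; tt[have] <- fr$t
  trajectory(t = tt, x = xs, y = ys, sampling_period = dt)
}

#' Water-delivery log
#'
#' Ordered onset times of water deliveries in a session, with the common
#' availability window (seconds each drop can be consumed) and, for
#' bookkeeping, the session length and the schedule type that produced it.
#'
#' @param onsets Strictly increasing numeric vector of onset times (s).
#' @param availability Availability window in seconds.
#' @param session_length Session length in seconds.
#' @param schedule_type `"FT"` (fixed time) or `"VT"` (variable time).
#' @return An object of class `delivery_log`.
#' @export
delivery_log <- function(onsets, availability = 3, session_length = 1200,
                         schedule_type = c("FT", "VT")) {
  schedule_type <- match.arg(schedule_type)
  onsets <- as.numeric(onsets)
  if (anyNA(onsets)) stop("onsets must be finite", call. = FALSE)
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing", call. = FALSE)
  if (availability < 0) stop("availability must be >= 0", call. = FALSE)
  if (length(onsets) && max(onsets) + availability > session_length + 1e-9)
    stop("onset + availability exceeds session length", call. = FALSE)
  structure(
    list(onsets = onsets, availability = availability,
         session_length = session_length, schedule_type = schedule_type),
    class = "delivery_log"
  )
}

#' @export
print.delivery_log <- function(x, ...) {
  cat(sprintf("<delivery_log> %s schedule: %d onsets in %g s, %g s availability\n",
              x$schedule_type, length(x$onsets), x$session_length,
              x$availability))
  invisible(x)
}

#' Read / write a delivery log
#'
#' Dialect: comma-separated with header `onset_s,duration_s`.
#'
#' @param path File path.
#' @param session_length,schedule_type Metadata not stored in the table.
#' @return `read_deliveries` returns a [delivery_log()];
#'   `write_deliveries` returns `path` invisibly.
#' @export
read_deliveries <- function(path, session_length = 1200,
                            schedule_type = c("FT", "VT")) {
  schedule_type <- match.arg(schedule_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "duration_s") %in% names(d)))
    stop("delivery file must have columns onset_s, duration_s", call. = FALSE)
  avail <- if (nrow(d)) d$duration_s[1] else 3
  delivery_log(d$onset_s, availability = avail,
               session_length = session_length, schedule_type = schedule_type)
}

#' @rdname read_deliveries
#' @param log A [delivery_log()].
#' @export
write_deliveries <- function(log, path) {
  stopifnot(inherits(log, "delivery_log"))
  lines <- c("onset_s,duration_s",
             sprintf("%.6f,%.6f", log$onsets,
                     rep(log$availability, length(log$onsets))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' One subject-session record
#'
#' Bundles the trajectory, the delivery log and the session metadata
#' (subject, experiment, condition, 1-based session index, schedule type).
#'
#' @param subject,experiment Identifiers.
#' @param condition `"center"` or `"wall"`.
#' @param session_index 1-based session number (continuing across
#'   conditions within a subject).
#' @param schedule_type `"FT"` or `"VT"`.
#' @param trajectory A [trajectory()].
#' @param deliveries A [delivery_log()].
#' @param arena The [arena_spec()] the session was recorded in.
#' @return An object of class `session_record`.
#' @export
session_record <- function(subject, experiment, condition, session_index,
                           schedule_type, trajectory, deliveries, arena) {
  condition <- match.arg(condition, c("center", "wall"))
  schedule_type <- match.arg(schedule_type, c("FT", "VT"))
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(deliveries, "delivery_log"),
            inherits(arena, "arena_spec"))
  rec <- structure(
    list(subject = as.character(subject), experiment = as.character(experiment),
         condition = condition, session_index = as.integer(session_index),
         schedule_type = schedule_type, trajectory = trajectory,
         deliveries = deliveries, arena = arena),
    class = "session_record"
  )
  rec
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> subject %s, %s, %s condition, session %d (%s)\n",
              x$subject, x$experiment, x$condition, x$session_index,
              x$schedule_type))
  print(x$trajectory)
  print(x$deliveries)
  invisible(x)
}

#' Validate a session record
#'
#' Checks the structural invariants of a [session_record()] and returns one
#' finding (character string) per violation; an empty character vector means
#' the record is consistent. Findings are returned, never raised.
#'
#' @param record A [session_record()].
#' @return Character vector of findings.
#' @export
validate_session <- function(record) {
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)
  if (!inherits(record, "session_record")) {
    return("not a session_record")
  }
  if (is.na(record$session_index) || record$session_index < 1L)
    add(sprintf("session_index must be >= 1 (got %s)", record$session_index))
  tr <- record$trajectory; dl <- record$deliveries; a <- record$arena
  if (nrow(tr$frames)) {
    span <- tr$frames$t[nrow(tr$frames)] + tr$sampling_period - tr$frames$t[1]
    if (abs(span - dl$session_length) > tr$sampling_period + 1e-6)
      add(sprintf("trajectory spans %.1f s but deliveries declare a %.1f-s session",
                  span, dl$session_length))
    if (any(tr$frames$x < 0 | tr$frames$x > a$width |
            tr$frames$y < 0 | tr$frames$y > a$height))
      add("trajectory contains out-of-bounds frames")
    k <- diff(tr$frames$t) / tr$sampling_period
    if (length(k) && any(abs(k - 1) > 1e-6))
      add("trajectory has gaps (missing frames)")
  } else {
    add("trajectory is empty")
  }
  if (length(dl$onsets) &&
      max(dl$onsets) + dl$availability > dl$session_length + 1e-9)
    add("delivery onset + availability exceeds session length")
  findings
}

#' Write / read a session (manifest + data files)
#'
#' A session is stored as three files in `dir`: a trajectory table, a
#' delivery table, and a YAML manifest naming them together with the
#' metadata and arena description.
#'
#' @param record A [session_record()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to `subject_condition_session`.
#' @return Path to the manifest, invisibly (`write_session`); a
#'   [session_record()] (`read_session`).
#' @export
write_session <- function(record, dir, stem = NULL) {
  stopifnot(inherits(record, "session_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem))
    stem <- sprintf("%s_%s_s%02d", record$subject, record$condition,
                    record$session_index)
  traj_file <- paste0(stem, "_trajectory.csv")
  del_file <- paste0(stem, "_deliveries.csv")
  write_trajectory(record$trajectory, file.path(dir, traj_file))
  write_deliveries(record$deliveries, file.path(dir, del_file))
  a <- record$arena
  manifest <- list(
    subject = record$subject, experiment = record$experiment,
    condition = record$condition, session_index = record$session_index,
    schedule_type = record$schedule_type,
    session_length_s = record$deliveries$session_length,
    trajectory = traj_file, deliveries = del_file,
    arena = list(width_cm = a$width, height_cm = a$height,
                 dispenser_x_cm = a$dispenser[1], dispenser_y_cm = a$dispenser[2],
                 patch_x_cm = a$patch[1], patch_y_cm = a$patch[2],
                 availability_s = a$availability)
  )
  mpath <- file.path(dir, paste0(stem, "_session.yaml"))
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_session
#' @param manifest_path Path to a session manifest written by
#'   `write_session`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  arena <- arena_spec(width = m$arena$width_cm, height = m$arena$height_cm,
                      dispenser = c(m$arena$dispenser_x_cm, m$arena$dispenser_y_cm),
                      patch = c(m$arena$patch_x_cm, m$arena$patch_y_cm),
                      availability = m$arena$availability_s)
  traj <- read_trajectory(file.path(dir, m$trajectory), arena)
  del <- read_deliveries(file.path(dir, m$deliveries),
                         session_length = m$session_length_s,
                         schedule_type = m$schedule_type)
  session_record(subject = m$subject, experiment = m$experiment,
                 condition = m$condition, session_index = m$session_index,
                 schedule_type = m$schedule_type, trajectory = traj,
                 deliveries = del, arena = arena)
}
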