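#' Generate a time-based water-delivery schedule
#'
#' Fixed-time (FT) schedules deliver at `k * mean_interval` for
#' k = 1, 2, ... as long as the availability window still fits in the
#' session; they are deterministic. Variable-time (VT) schedules draw
#' i.i.d. intervals from an exponential law with the given mean, truncated
#' to `[mean/5, 3*mean]`, accumulated until the next availability window
#' would overrun the session; they depend only on `seed`.
#'
#' @param schedule_type `"FT"` or `"VT"`.
#' @param mean_interval Mean inter-delivery interval in seconds.
#' @param session_length Session length in seconds.
#' @param availability Seconds each delivery remains available.
#' @param seed Integer seed (VT only).
#' @return A [delivery_log()].
#' @examples
#' length(generate_schedule("FT")$onsets)  # 39 onsets: 30, 60, ..., 1170
#' @export
generate_schedule <- function(schedule_type = c("FT", "VT"),
                              mean_interval = 30, session_length = 1200,
                              availability = 3, seed = 1) {
  schedule_type <- match.arg(schedule_type)
  if (mean_interval <= 0) stop("mean_interval must be > 0", call. = FALSE)
  if (session_length <= 0) stop("session_length must be > 0", call. = FALSE)
  if (availability < 0) stop("availability must be >= 0", call. = FALSE)
  if (schedule_type == "FT") {
    k_max <- floor((session_length - availability) / mean_interval)
    onsets <- if (k_max >= 1) mean_interval * seq_len(k_max) else numeric(0)
  } else {
    onsets <- local({
      set.seed(as.integer(seed))
      lo <- mean_interval / 5; hi <- 3 * mean_interval
      out <- numeric(0); t <- 0
      repeat {
        t <- t + rtrunc_exp(1, mean_interval, lo, hi)
        if (t + availability > session_length) break
        out <- c(out, t)
      }
      out
    })
  }
  delivery_log(onsets, availability = availability,
               session_length = session_length, schedule_type = schedule_type)
}

#' Truncated exponential deviates (inverse-CDF sampling)
#'
#' Exponential with mean `mean`, truncated to `[lo, hi]`. Used for VT
#' inter-delivery intervals.
#'
#' @param n Number of deviates.
#' @param mean Mean of the untruncated exponential, in seconds.
#' @param lo,hi Truncation bounds in seconds.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_exp <- function(n, mean, lo, hi) {
  stopifnot(mean > 0, lo >= 0, hi > lo)
  u <- stats::runif(n)
  flo <- exp(-lo / mean); fhi <- exp(-hi / mean)
  -mean * log(flo - u * (flo - fhi))
}

#' Rat-agent movement parameters
#'
#' Parameters of the correlated-random-walk rat agent used by
#' [simulate_session()]. Defaults were calibrated once so that the agent
#' reproduces the qualitative open-field patterns of interest (early
#' thigmotaxis; schedule-driven approach to the dispenser emerging across
#' sessions; contraction to the dispenser wall in the wall condition) and
#' then frozen.
#'
#' @param mean_speed Mean step speed, cm/s.
#' @param speed_sd SD of step speed, cm/s (draws below 0 are clipped).
#' @param turn_sd SD of the Gaussian heading perturbation per step, radians.
#' @param w_wall Dimensionless drift weight toward the nearest wall point
#'   (thigmotaxis).
#' @param w_disp Dimensionless drift weight toward the dispenser, scaled by
#'   the learning factor and the delivery gate.
#' @param g0 Baseline dispenser gate outside availability/anticipation
#'   windows (dimensionless, in \[0, 1\]).
#' @param learn_tau Time constant of across-session schedule learning, in
#'   sessions.
#' @param loc_tau Time constant (sessions) of re-acquiring the dispenser
#'   *location* after it moves; faster than `learn_tau` because the
#'   texturized patch signals the new location.
#' @param detect_radius Drinking contact radius around the dispenser, cm.
#' @param anticipation_window Seconds before each FT onset during which the
#'   dispenser gate opens (temporal anticipation; FT only).
#' @return A validated list of class `agent_params`.
#' @export
agent_params <- function(mean_speed = 12, speed_sd = 6, turn_sd = 0.6,
                         w_wall = 0.45, w_disp = 1.6, g0 = 0.06,
                         learn_tau = 5, loc_tau = 3, detect_radius = 5,
                         anticipation_window = 5) {
  p <- list(mean_speed = mean_speed, speed_sd = speed_sd, turn_sd = turn_sd,
            w_wall = w_wall, w_disp = w_disp, g0 = g0, learn_tau = learn_tau,
            loc_tau = loc_tau, detect_radius = detect_radius,
            anticipation_window = anticipation_window)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || !is.finite(v),
                 logical(1))))
    stop("all agent parameters must be finite scalars", call. = FALSE)
  if (mean_speed <= 0) stop("mean_speed must be > 0", call. = FALSE)
  if (speed_sd < 0 || turn_sd < 0 || w_wall < 0 || w_disp < 0 || g0 < 0)
    stop("speed_sd, turn_sd and drift weights must be >= 0", call. = FALSE)
  if (learn_tau <= 0 || loc_tau <= 0)
    stop("learn_tau and loc_tau must be > 0", call. = FALSE)
  if (detect_radius <= 0) stop("detect_radius must be > 0", call. = FALSE)
  if (anticipation_window < 0)
    stop("anticipation_window must be >= 0", call. = FALSE)
  structure(p, class = "agent_params")
}

#' Across-session learning factor
#'
#' `lambda(s) = 1 - exp(-(s - 1) / learn_tau)`: 0 in session 1, rising
#' toward 1 as the animal accumulates sessions of exposure. The session
#' index continues across conditions, so learning carries over when the
#' dispenser moves.
#'
#' @param session_index 1-based session index (may be a vector).
#' @param learn_tau Learning time constant in sessions.
#' @return Numeric in \[0, 1).
#' @export
learning_factor <- function(session_index, learn_tau) {
  stopifnot(all(session_index >= 1), learn_tau > 0)
  1 - exp(-(session_index - 1) / learn_tau)
}

# Reflect a scalar coordinate into [lo, hi] (specular wall reflection).
reflect_into <- function(v, lo, hi) {
  while (v < lo || v > hi) {
    if (v < lo) v <- 2 * lo - v
    if (v > hi) v <- 2 * hi - v
  }
  v
}

# Unit vector from p toward the nearest point of the arena boundary, or
# (0, 0) once inside the wall band: thigmotaxis pulls the agent to the
# wall zone but does not pin it there, so the correlated walk slides
# along the perimeter instead of being trapped against one wall point.
unit_to_nearest_wall <- function(p, width, height, band = 5) {
  dists <- c(p[1], width - p[1], p[2], height - p[2])
  side <- which.min(dists)
  if (dists[side] <= band) return(c(0, 0))
  switch(side, c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
}

#' Simulate one session of a rat agent in the arena
#'
#' Discrete-time correlated random walk at the sampling period. Each step
#' the heading receives Gaussian turn noise and is biased by a drift
#' vector
#' `w_wall * u_wall + lambda * w_disp * g(t) * u_dispenser`,
#' where `u_wall` points to the nearest wall (thigmotaxis), `u_dispenser`
#' points to the water dispenser, and the gate `g(t)` equals 1 while water is
#' available — and, under FT schedules, during the anticipation window
#' before each onset — and a small baseline `g0` otherwise. Step length is
#' `max(0, N(mean_speed, speed_sd)) * sampling_period`; positions reflect
#' off the walls. While water is available and the agent is within
#' `detect_radius` of the dispenser it holds position (drinking) until the
#' availability window closes. The agent starts each session at the same
#' corner of the arena (animals are introduced at the same entry point
#' every session), 5 cm from both walls, with a random initial heading.
#'
#' The learned attraction `lambda` is the product of two saturating
#' components: across-session schedule learning
#' `1 - exp(-(session_index - 1) / learn_tau)` (session indices continue
#' across conditions, so it carries over when the dispenser moves) and
#' location re-acquisition `1 - exp(-session_in_condition / loc_tau)`,
#' which resets when the dispenser moves and recovers within a few
#' sessions because the patch signals the new location.
#'
#' @param arena An [arena_spec()].
#' @param grid A [zone_grid()] (carried into the record for analysis).
#' @param params An [agent_params()].
#' @param schedule A [delivery_log()].
#' @param session_index 1-based session index, continuing across
#'   conditions (drives schedule learning).
#' @param session_in_condition 1-based session index within the current
#'   condition (drives location re-acquisition); defaults to
#'   `session_index`.
#' @param sampling_period Sampling period in seconds (default 0.2).
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param subject,experiment,condition Metadata stored in the record.
#' @return A [session_record()].
#' @export
simulate_session <- function(arena, grid, params, schedule, session_index,
                             session_in_condition = session_index,
                             sampling_period = 0.2, seed = 1,
                             subject = "r1", experiment = "exp1",
                             condition = c("center", "wall")) {
  stopifnot(inherits(arena, "arena_spec"), inherits(grid, "zone_grid"),
            inherits(params, "agent_params"), inherits(schedule, "delivery_log"))
  condition <- match.arg(condition)
  n <- round(schedule$session_length / sampling_period)
  tt <- (seq_len(n) - 1) * sampling_period
  w <- arena$width; h <- arena$height
  disp <- arena$dispenser
  avail <- schedule$availability

  # per-frame dispenser gate and availability flag
  available <- logical(n)
  gate <- rep(params$g0, n)
  avail_end <- numeric(n)  # end of the availability window covering frame i
  for (on in schedule$onsets) {
    i0 <- ceiling(on / sampling_period - 1e-9) + 1L
    i1 <- min(n, floor((on + avail) / sampling_period + 1e-9) + 1L)
    if (i0 <= i1 && i0 <= n) {
      idx <- i0:i1
      available[idx] <- TRUE
      gate[idx] <- 1
      avail_end[idx] <- on + avail
    }
    if (schedule$schedule_type == "FT" && params$anticipation_window > 0) {
      a0 <- max(1L, ceiling((on - params$anticipation_window) / sampling_period - 1e-9) + 1L)
      a1 <- max(0L, floor(on / sampling_period - 1e-9) + 1L)  # last frame strictly before onset
      if (a0 <= a1) gate[a0:a1] <- pmax(gate[a0:a1], 1)
    }
  }

  set.seed(as.integer(seed))
  turn <- stats::rnorm(n, 0, params$turn_sd)
  steps <- pmax(0, stats::rnorm(n, params$mean_speed, params$speed_sd)) *
    sampling_period
  stopifnot(session_in_condition >= 1)
  lam <- learning_factor(session_index, params$learn_tau) *
    (1 - exp(-session_in_condition / params$loc_tau))

  # same entry corner every session, random initial heading
  band <- min(5, w / 2, h / 2)
  pos <- c(band, band)
  heading <- stats::runif(1, -pi, pi)

  x <- numeric(n); y <- numeric(n)
  drink_until <- -Inf
  for (i in seq_len(n)) {
    x[i] <- pos[1]; y[i] <- pos[2]
    d_disp <- sqrt((pos[1] - disp[1])^2 + (pos[2] - disp[2])^2)
    if (available[i] && d_disp <= params$detect_radius)
      drink_until <- max(drink_until, avail_end[i])
    if (tt[i] < drink_until) next  # drinking: hold position
    heading <- heading + turn[i]
    dirx <- cos(heading); diry <- sin(heading)
    uw <- unit_to_nearest_wall(pos, w, h)
    dirx <- dirx + params$w_wall * uw[1]
    diry <- diry + params$w_wall * uw[2]
    if (d_disp > 1e-9) {
      k <- lam * params$w_disp * gate[i] / d_disp
      dirx <- dirx + k * (disp[1] - pos[1])
      diry <- diry + k * (disp[2] - pos[2])
    }
    nv <- sqrt(dirx^2 + diry^2)
    if (nv > 1e-12) {
      dirx <- dirx / nv; diry <- diry / nv
      heading <- atan2(diry, dirx)
    }
    pos <- c(reflect_into(pos[1] + steps[i] * dirx, 0, w),
             reflect_into(pos[2] + steps[i] * diry, 0, h))
  }

  traj <- trajectory(t = tt, x = x, y = y, sampling_period = sampling_period)
  session_record(subject = subject, experiment = experiment,
                 condition = condition, session_index = session_index,
                 schedule_type = schedule$schedule_type, trajectory = traj,
                 deliveries = schedule, arena = arena)
}

# Deterministic per-session seed derived from the master seed.
# Kept below 2^31 and exact in double arithmetic.
derive_seed <- function(master_seed, subject_i, session_i, stream = 0L) {
  (((master_seed %% 1000003) * 1000003 + subject_i * 10007 +
      session_i * 101 + stream * 17) %% 2147483647) + 1
}

#' Simulate a full two-condition experiment
#'
#' Mirrors the study layout: each subject runs `n_sessions` sessions with
#' the dispenser at the centre, then `n_sessions` with the dispenser at a
#' wall, session indices continuing across conditions so that learning
#' carries over. Experiment 1 uses an FT schedule, Experiment 2 a VT
#' schedule with the same mean interval. Per-session seeds are derived
#' deterministically from `master_seed`.
#'
#' @param experiment Identifier stored in the records (e.g. `"exp1"`).
#' @param schedule_type `"FT"` or `"VT"`.
#' @param n_subjects Number of subjects (default 3).
#' @param n_sessions Sessions per condition (default 20).
#' @param session_length Session length in seconds (default 1200 = 20 min).
#' @param mean_interval Mean inter-delivery interval in seconds (default 30).
#' @param availability Water availability in seconds (default 3).
#' @param wall_offset Dispenser-to-wall distance in the wall condition, cm.
#' @param width,height Arena dimensions in cm.
#' @param grid_rows,grid_cols Zone-grid resolution (default 10 x 10).
#' @param params An [agent_params()].
#' @param sampling_period Sampling period in seconds.
#' @param master_seed Master seed; all per-session seeds derive from it.
#' @param subject_offset Added to subject numbers in labels (Experiment 2's
#'   subjects are rats 4-6).
#' @return List of [session_record()]s, ordered by subject then session.
#' @export
simulate_experiment <- function(experiment = "exp1",
                                schedule_type = c("FT", "VT"),
                                n_subjects = 3, n_sessions = 20,
                                session_length = 1200, mean_interval = 30,
                                availability = 3, wall_offset = 5,
                                width = 100, height = 100,
                                grid_rows = 10, grid_cols = 10,
                                params = agent_params(),
                                sampling_period = 0.2, master_seed = 1,
                                subject_offset = 0) {
  schedule_type <- match.arg(schedule_type)
  stopifnot(n_subjects >= 1, n_sessions >= 1)
  arenas <- list(center = make_arena("center", wall_offset, width, height,
                                     availability),
                 wall = make_arena("wall", wall_offset, width, height,
                                   availability))
  records <- vector("list", n_subjects * 2L * n_sessions)
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    label <- sprintf("r%d", subj + subject_offset)
    for (cond_i in 1:2) {
      cond <- c("center", "wall")[cond_i]
      arena <- arenas[[cond]]
      grid <- zone_grid(arena, grid_rows, grid_cols)
      for (s in seq_len(n_sessions)) {
        s_global <- (cond_i - 1L) * n_sessions + s
        sched_seed <- derive_seed(master_seed, subj, s_global, stream = 1L)
        schedule <- generate_schedule(schedule_type, mean_interval,
                                      session_length, availability,
                                      seed = sched_seed)
        sess_seed <- derive_seed(master_seed, subj, s_global, stream = 0L)
        k <- k + 1L
        records[[k]] <- simulate_session(
          arena, grid, params, schedule, session_index = s_global,
          session_in_condition = s,
          sampling_period = sampling_period, seed = sess_seed,
          subject = label, experiment = experiment, condition = cond)
      }
    }
  }
  records
}
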