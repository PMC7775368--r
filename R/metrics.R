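#' Region sequence of a trajectory
#'
#' Maps every frame to its 0-based zone-grid region via [region_of()]; this
#' categorical time series underlies the occupancy map, the recurrence plot
#' and the entropy/divergence indices.
#'
#' @param traj A [trajectory()].
#' @param grid A [zone_grid()].
#' @return Integer vector, one region index per frame.
#' @export
region_sequence <- function(traj, grid) {
  stopifnot(inherits(traj, "trajectory"))
  region_of(traj$frames$x, traj$frames$y, grid)
}

#' Occupancy map: accumulated time of stays per region
#'
#' Each frame contributes one sampling period to exactly one region, so the
#' per-region dwell counts sum exactly to the frame count; dwell times are
#' the counts times the sampling period.
#'
#' @param traj A [trajectory()].
#' @param grid A [zone_grid()].
#' @return An object of class `occupancy_map`: list with `grid`,
#'   `frames_per_region` (integer dwell counts; element k+1 belongs to
#'   region k), `time_per_region` (the counts times the sampling period,
#'   seconds), `sampling_period` and `total_time`.
#' @export
occupancy_map <- function(traj, grid) {
  regions <- region_sequence(traj, grid)
  counts <- tabulate(regions + 1L, nbins = n_regions(grid))
  structure(
    list(grid = grid,
         frames_per_region = counts,
         time_per_region = counts * traj$sampling_period,
         sampling_period = traj$sampling_period,
         total_time = length(regions) * traj$sampling_period),
    class = "occupancy_map"
  )
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d regions, %.1f s total, %d occupied\n",
              x$grid$n_rows, x$grid$n_cols, x$total_time,
              sum(x$time_per_region > 0)))
  invisible(x)
}

#' Relative distance to the dispenser with moving-average smoothing
#'
#' The per-frame distance from the animal to the dispenser is divided by
#' the maximum possible distance for that dispenser placement
#' ([max_distance_to()]), giving a dimensionless series in \[0, 1\]
#' (0 = at the dispenser, 1 = farthest possible). A trailing moving
#' average of `window` frames (200 frames = 40 s at 0.2-s sampling) shows
#' the tendency; at the start of the session the window shrinks to the
#' frames available.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena_spec()].
#' @param window Moving-average window in frames (default 200).
#' @return An object of class `distance_series`: list with `raw`,
#'   `smoothed` (same length) and `window`.
#' @export
relative_distance_series <- function(traj, arena, window = 200) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_spec"))
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window))
    stop("window must be a positive integer number of frames", call. = FALSE)
  d_max <- max_distance_to(arena$dispenser, arena)
  raw <- sqrt((traj$frames$x - arena$dispenser[1])^2 +
              (traj$frames$y - arena$dispenser[2])^2) / d_max
  n <- length(raw)
  cs <- cumsum(raw)
  i <- seq_len(n)
  lag <- pmin(window, i)
  smoothed <- (cs - c(rep(0, min(window, n)), cs[seq_len(max(0, n - window))])) / lag
  structure(list(raw = raw, smoothed = smoothed, window = as.integer(window)),
            class = "distance_series")
}

#' Animal location at each delivery moment
#'
#' For each water-delivery onset, returns the first tracking frame at or
#' after the onset (the first 0.2-s frame of the availability window) with
#' the animal's position and its distance to the dispenser.
#'
#' @param session A [session_record()].
#' @return A tibble with columns `onset`, `t`, `x`, `y`, `dist`, one row
#'   per delivery.
#' @export
delivery_moments <- function(session) {
  stopifnot(inherits(session, "session_record"))
  fr <- session$trajectory$frames
  onsets <- session$deliveries$onsets
  if (!length(onsets))
    return(tibble::tibble(onset = numeric(0), t = numeric(0),
                          x = numeric(0), y = numeric(0), dist = numeric(0)))
  idx <- findInterval(onsets - 1e-9, fr$t) + 1L
  if (any(idx > nrow(fr)))
    stop("delivery onset beyond the last tracked frame", call. = FALSE)
  disp <- session$arena$dispenser
  tibble::tibble(
    onset = onsets, t = fr$t[idx], x = fr$x[idx], y = fr$y[idx],
    dist = sqrt((fr$x[idx] - disp[1])^2 + (fr$y[idx] - disp[2])^2)
  )
}

#' Categorical recurrence matrix of a region sequence
#'
#' The recurrence plot of the region time series: after optionally
#' retaining every `frame_stride`-th frame, entry (i, j) is 1 when the
#' animal occupied the same grid region at retained frames i and j. Dense
#' black blocks indicate permanence in a region, black-white mosaics
#' recurrent returns, white transitions.
#'
#' @param regions Integer vector of region indices (e.g. from
#'   [region_sequence()]).
#' @param frame_stride Keep every `frame_stride`-th frame (default 1 =
#'   full resolution).
#' @return An object of class `recurrence_matrix`: list with
#'   `frame_stride`, `n` and the 0/1 `indicator` matrix.
#' @export
recurrence_matrix <- function(regions, frame_stride = 1) {
  if (!length(regions)) stop("empty region sequence", call. = FALSE)
  if (frame_stride < 1 || frame_stride != round(frame_stride))
    stop("frame_stride must be a positive integer", call. = FALSE)
  kept <- regions[seq(1L, length(regions), by = frame_stride)]
  ind <- outer(kept, kept, FUN = "==")
  storage.mode(ind) <- "integer"
  structure(list(frame_stride = as.integer(frame_stride),
                 n = length(kept), indicator = ind),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d (stride %d), recurrence rate %.3f\n",
              x$n, x$n, x$frame_stride,
              if (x$n >= 2) recurrence_rate(x) else NA_real_))
  invisible(x)
}

#' Off-diagonal recurrence rate
#'
#' Scalar summary of a recurrence plot: the fraction of off-diagonal
#' entries that are recurrent, in \[0, 1\].
#'
#' @param R A [recurrence_matrix()] with at least 2 retained frames.
#' @return Fraction in \[0, 1\].
#' @export
recurrence_rate <- function(R) {
  stopifnot(inherits(R, "recurrence_matrix"))
  if (R$n < 2) stop("recurrence_rate needs at least 2 frames", call. = FALSE)
  (sum(R$indicator) - R$n) / (R$n^2 - R$n)
}

#' Shannon entropy of an occupancy distribution
#'
#' `H = -sum p_k log p_k` (natural log, nats) over the per-region occupancy
#' probabilities `p_k = time_k / total_time`; zero-probability regions do
#' not contribute. High entropy means displacement spread over many
#' regions, low entropy concentration in few. The normalised variant
#' divides by `log(n_regions)` so grids of different size are comparable.
#'
#' @param occ An [occupancy_map()] with positive total time.
#' @param normalized Return `H / log(n_regions)` instead of nats.
#' @return Entropy in nats (or dimensionless in \[0, 1\] if normalised).
#' @export
entropy_index <- function(occ, normalized = FALSE) {
  stopifnot(inherits(occ, "occupancy_map"))
  if (occ$total_time <= 0) stop("total_time must be > 0", call. = FALSE)
  # occupancy probabilities; exact when integer dwell counts are present
  p <- if (!is.null(occ$frames_per_region))
    occ$frames_per_region / sum(occ$frames_per_region)
  else occ$time_per_region / occ$total_time
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalized) h / log(n_regions(occ$grid)) else h
}

#' Transition entropy of a region sequence
#'
#' Entropy (nats) of the empirical distribution of successive region pairs
#' (r_t, r_(t+1)) — an alternative reading of "variation of displacement
#' patterns" that weighs movement between regions, offered alongside the
#' default occupancy entropy.
#'
#' @param regions Integer vector of region indices.
#' @return Entropy in nats.
#' @export
transition_entropy <- function(regions) {
  if (length(regions) < 2) stop("need at least 2 frames", call. = FALSE)
  pair <- paste(regions[-length(regions)], regions[-1])
  p <- table(pair) / (length(regions) - 1)
  -sum(p * log(p))
}

#' Kullback-Leibler divergence between two occupancy maps
#'
#' Regularises both maps with an additive pseudocount per region (default
#' one sampling period, 0.2 s), renormalises to probabilities and returns
#' `D(P || Q) = sum p_k log(p_k / q_k)` in nats. The pseudocount keeps the
#' divergence finite when a region visited in one session is empty in the
#' other; it is negligible against a full session. Values near 0 mean the
#' two sessions' displacement patterns match; the divergence is asymmetric,
#' and the convention for consecutive sessions is D(earlier || later).
#'
#' @param p_occ,q_occ [occupancy_map()]s on the same grid.
#' @param pseudocount Seconds added to every region of both maps.
#' @param symmetric If `TRUE`, return the Jensen-Shannon divergence
#'   (symmetrised, bounded by log 2) instead.
#' @return Divergence in nats, always finite and >= 0.
#' @export
kl_divergence <- function(p_occ, q_occ, pseudocount = 0.2,
                          symmetric = FALSE) {
  stopifnot(inherits(p_occ, "occupancy_map"), inherits(q_occ, "occupancy_map"))
  if (n_regions(p_occ$grid) != n_regions(q_occ$grid) ||
      p_occ$grid$n_rows != q_occ$grid$n_rows)
    stop("occupancy maps are on different grids", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  p <- p_occ$time_per_region + pseudocount
  q <- q_occ$time_per_region + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  if (symmetric) {
    m <- (p + q) / 2
    sum(p * log(p / m)) / 2 + sum(q * log(q / m)) / 2
  } else {
    sum(p * log(p / q))
  }
}

#' Path length of a trajectory
#'
#' Total distance travelled: the sum of Euclidean distances between
#' consecutive frames, in cm. A measure of the vigor of displacement,
#' as opposed to its directionality.
#'
#' @param traj A [trajectory()] with at least one frame.
#' @return Distance in cm.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  if (nrow(fr) < 1L) stop("trajectory has no frames", call. = FALSE)
  if (nrow(fr) == 1L) return(0)
  sum(sqrt(diff(fr$x)^2 + diff(fr$y)^2))
}

#' Per-session scalar metrics
#'
#' Assembles the session-level summary used throughout the analysis:
#' occupancy entropy (nats and normalised), KL divergence from the
#' previous session of the same subject (NA for the first), mean smoothed
#' relative distance to the dispenser, path length, delivery count, and
#' the delivery-proximity rate (fraction of deliveries at whose onset
#' frame the animal was within `detect_radius` of the dispenser).
#'
#' @param session A [session_record()].
#' @param grid A [zone_grid()]; defaults to a 10 x 10 grid on the
#'   session's arena.
#' @param previous The same subject's previous [session_record()], or
#'   `NULL` for the first session.
#' @param window Moving-average window in frames.
#' @param pseudocount KL regularisation in seconds.
#' @param detect_radius Proximity radius in cm.
#' @return One-row tibble.
#' @export
session_metrics <- function(session, grid = NULL, previous = NULL,
                            window = 200, pseudocount = 0.2,
                            detect_radius = 5) {
  stopifnot(inherits(session, "session_record"))
  if (is.null(grid)) grid <- zone_grid(session$arena)
  if (!is.null(previous)) {
    stopifnot(inherits(previous, "session_record"))
    if (previous$subject != session$subject)
      stop("previous session belongs to a different subject", call. = FALSE)
  }
  occ <- occupancy_map(session$trajectory, grid)
  div <- if (is.null(previous)) NA_real_ else {
    prev_grid <- zone_grid(previous$arena, grid$n_rows, grid$n_cols)
    kl_divergence(occupancy_map(previous$trajectory, prev_grid), occ,
                  pseudocount = pseudocount)
  }
  ds <- relative_distance_series(session$trajectory, session$arena, window)
  dm <- delivery_moments(session)
  tibble::tibble(
    subject = session$subject,
    experiment = session$experiment,
    condition = session$condition,
    session_index = session$session_index,
    schedule_type = session$schedule_type,
    entropy = entropy_index(occ),
    normalized_entropy = entropy_index(occ, normalized = TRUE),
    divergence_from_previous = div,
    mean_relative_distance = mean(ds$smoothed),
    path_length = path_length(session$trajectory),
    n_deliveries = nrow(dm),
    delivery_proximity_rate = if (nrow(dm)) mean(dm$dist <= detect_radius)
                              else NA_real_
  )
}
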