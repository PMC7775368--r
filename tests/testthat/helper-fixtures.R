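# Fixtures built in code: small arenas, trajectories and sessions.

default_arena <- function() arena_spec()

# trajectory visiting given (x, y) points at the 0.2-s lattice
traj_from_points <- function(xy, dt = 0.2) {
  trajectory(t = (seq_len(nrow(xy)) - 1) * dt, x = xy[, 1], y = xy[, 2],
             sampling_period = dt)
}

random_traj <- function(n, arena = default_arena(), dt = 0.2) {
  traj_from_points(cbind(runif(n, 0, arena$width),
                         runif(n, 0, arena$height)), dt)
}

# small consistent simulated session for I/O and validation tests
small_session <- function(seed = 7, session_length = 60,
                          condition = "center") {
  arena <- make_arena(condition)
  grid <- zone_grid(arena)
  sched <- generate_schedule("FT", mean_interval = 10,
                             session_length = session_length)
  simulate_session(arena, grid, agent_params(), sched, session_index = 1,
                   seed = seed, condition = condition)
}

# occupancy map with prescribed per-region dwell times (seconds)
occ_from_times <- function(times, grid = zone_grid(default_arena())) {
  stopifnot(length(times) == grid$n_rows * grid$n_cols)
  structure(list(grid = grid, time_per_region = times,
                 total_time = sum(times)),
            class = "occupancy_map")
}
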