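test_that("simulation is deterministic under a seed and degenerate at speed 0", {
  a <- make_arena("center")
  g <- zone_grid(a)
  sch <- generate_schedule("FT", session_length = 60)
  r1 <- simulate_session(a, g, agent_params(), sch, 1, seed = 42)
  r2 <- simulate_session(a, g, agent_params(), sch, 1, seed = 42)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  r3 <- simulate_session(a, g, agent_params(), sch, 1, seed = 43)
  expect_false(identical(r1$trajectory$frames, r3$trajectory$frames))

  # zero speed: agent never moves from the entry point
  p0 <- agent_params(mean_speed = 1e-12, speed_sd = 0)
  r0 <- simulate_session(a, g, p0, sch, 1, seed = 1)
  expect_equal(diff(range(r0$trajectory$frames$x)), 0)
  expect_equal(diff(range(r0$trajectory$frames$y)), 0)
  expect_equal(path_length(r0$trajectory), 0, tolerance = 1e-6)
})

test_that("all simulated frames stay in bounds, even at extreme speeds", {
  a <- make_arena("wall")
  g <- zone_grid(a)
  sch <- generate_schedule("FT", session_length = 30)
  for (speed in c(12, 120, 400)) {
    p <- agent_params(mean_speed = speed, speed_sd = speed / 2)
    for (sd in 1:3) {
      r <- simulate_session(a, g, p, sch, 1, seed = sd, condition = "wall")
      fr <- r$trajectory$frames
      expect_true(all(fr$x >= 0 & fr$x <= a$width))
      expect_true(all(fr$y >= 0 & fr$y <= a$height))
      expect_equal(nrow(fr), 150)  # 30 s at 0.2 s
    }
  }
})

test_that("learning factor is strictly increasing and bounded", {
  lam <- learning_factor(1:40, learn_tau = 5)
  expect_equal(lam[1], 0)
  expect_true(all(diff(lam) > 0))
  expect_true(all(lam >= 0 & lam < 1))
})

test_that("wall-condition agents with learned attraction stay nearer the dispenser", {
  a <- make_arena("wall")
  g <- zone_grid(a)
  sch <- generate_schedule("FT", session_length = 300)
  p <- agent_params()
  nearer <- vapply(1:6, function(sd) {
    naive <- simulate_session(a, g, p, sch, 1, seed = sd, condition = "wall")
    learned <- simulate_session(a, g, p, sch, 40, seed = sd, condition = "wall")
    d <- function(r) mean(sqrt((r$trajectory$frames$x - a$dispenser[1])^2 +
                               (r$trajectory$frames$y - a$dispenser[2])^2))
    d(learned) < d(naive)
  }, logical(1))
  expect_true(all(nearer))
})

test_that("with wall drift only, occupancy concentrates on the peripheral ring", {
  a <- make_arena("center")
  g <- zone_grid(a)
  p <- agent_params(w_disp = 0)
  sch <- generate_schedule("FT", session_length = 300)
  shares <- vapply(1:10, function(sd) {
    r <- simulate_session(a, g, p, sch, 1, seed = sd)
    occ <- occupancy_map(r$trajectory, g)
    sum(occ$time_per_region[peripheral_mask(g) + 1]) / occ$total_time
  }, numeric(1))
  expect_true(all(shares > 0.8))
})

test_that("simulate_experiment reproduces the study layout deterministically", {
  e <- simulate_experiment("exp1", "FT", n_subjects = 3, n_sessions = 2,
                           session_length = 30, master_seed = 9)
  expect_length(e, 12)  # 3 subjects x 2 conditions x 2 sessions
  conds <- vapply(e, `[[`, character(1), "condition")
  idx <- vapply(e, `[[`, integer(1), "session_index")
  # centre first, then wall, session indices continuing across conditions
  expect_identical(conds[1:4], c("center", "center", "wall", "wall"))
  expect_identical(idx[1:4], 1:4)
  expect_true(all(vapply(e, `[[`, character(1), "schedule_type") == "FT"))
  e2 <- simulate_experiment("exp1", "FT", n_subjects = 3, n_sessions = 2,
                            session_length = 30, master_seed = 9)
  expect_identical(lapply(e, `[[`, "trajectory"),
                   lapply(e2, `[[`, "trajectory"))
  e3 <- simulate_experiment("exp1", "FT", n_subjects = 3, n_sessions = 2,
                            session_length = 30, master_seed = 10)
  expect_false(identical(e[[1]]$trajectory, e3[[1]]$trajectory))
})

test_that("drinking holds the agent at the dispenser while water is available", {
  # dispenser placed at the entry corner so contact is frequent
  a <- arena_spec(dispenser = c(5, 5))
  g <- zone_grid(a)
  p <- agent_params(detect_radius = 5)
  sch <- generate_schedule("FT", mean_interval = 10, session_length = 120)
  r <- simulate_session(a, g, p, sch, 40, seed = 3)
  fr <- r$trajectory$frames
  dist <- sqrt((fr$x - 5)^2 + (fr$y - 5)^2)
  held <- 0L
  for (on in sch$onsets) {
    win <- which(fr$t >= on & fr$t <= on + sch$availability)
    hit <- win[dist[win] <= p$detect_radius]
    if (!length(hit)) next
    hold <- hit[1]:win[length(win)]
    expect_equal(diff(range(fr$x[hold])), 0)
    expect_equal(diff(range(fr$y[hold])), 0)
    held <- held + 1L
  }
  expect_gt(held, 0L)  # the scenario actually exercises drinking
})
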