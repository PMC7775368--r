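test_that("region_sequence follows the trajectory cell by cell", {
  a <- default_arena()
  g2 <- zone_grid(a, 2, 2)
  # diagonal sweep corner to corner visits regions 0 and 3
  sweep <- traj_from_points(cbind(seq(0, 100, length.out = 11),
                                  seq(0, 100, length.out = 11)))
  expect_identical(sort(unique(region_sequence(sweep, g2))), c(0L, 3L))
  # stationary trajectory -> constant sequence; length = frame count
  still <- traj_from_points(cbind(rep(7, 25), rep(7, 25)))
  rs <- region_sequence(still, zone_grid(a))
  expect_length(rs, 25)
  expect_identical(unique(rs), 0L)
})

test_that("occupancy accumulates one sampling period per frame, exactly", {
  a <- default_arena()
  g <- zone_grid(a)
  still <- traj_from_points(cbind(rep(55, 6000), rep(55, 6000)))
  occ <- occupancy_map(still, g)
  expect_equal(occ$total_time, 1200)
  expect_equal(max(occ$time_per_region), 1200)
  expect_equal(sum(occ$time_per_region > 0), 1)

  # strict alternation between two cells for 100 frames: 10 s each
  alt <- traj_from_points(cbind(rep(c(5, 15), 50), rep(5, 100)))
  occ2 <- occupancy_map(alt, g)
  expect_equal(sort(occ2$time_per_region[occ2$time_per_region > 0]),
               c(10, 10))

  # random trajectory equals a brute-force per-frame tally
  set.seed(8)
  tr <- random_traj(500)
  occ3 <- occupancy_map(tr, g)
  rs <- region_sequence(tr, g)
  brute <- vapply(0:99, function(k) sum(rs == k), integer(1))
  expect_identical(occ3$frames_per_region, brute)
  # conservation: exact in frame counts, one sampling period per frame
  expect_identical(sum(occ3$frames_per_region), 500L)
  expect_equal(sum(occ3$time_per_region), occ3$total_time, tolerance = 1e-12)
})

test_that("relative distance is normalised to [0, 1] with trailing smoothing", {
  a <- make_arena("center")
  at_disp <- traj_from_points(matrix(c(50, 50), 1))
  expect_equal(relative_distance_series(at_disp, a)$raw, 0)
  at_corner <- traj_from_points(matrix(c(0, 0), 1))
  expect_equal(relative_distance_series(at_corner, a)$raw, 1)

  # constant series is a fixed point of the moving average
  const <- traj_from_points(cbind(rep(20, 300), rep(30, 300)))
  ds <- relative_distance_series(const, a, window = 50)
  expect_equal(ds$smoothed, ds$raw)

  # random series equals the brute-force trailing windowed mean
  set.seed(4)
  tr <- random_traj(400)
  ds2 <- relative_distance_series(tr, a, window = 37)
  brute <- vapply(seq_along(ds2$raw), function(i)
    mean(ds2$raw[max(1, i - 36):i]), numeric(1))
  expect_equal(ds2$smoothed, brute)
  # contraction: smoothed range within raw range
  expect_gte(min(ds2$smoothed), min(ds2$raw))
  expect_lte(max(ds2$smoothed), max(ds2$raw))
  expect_error(relative_distance_series(tr, a, window = 0), "window")
})

test_that("delivery moments pick the first frame at or after each onset", {
  s <- small_session(seed = 2, session_length = 1200)
  s$deliveries <- generate_schedule("FT", 30, 1200, 3)
  dm <- delivery_moments(s)
  expect_equal(nrow(dm), 39)
  expect_equal(dm$t, dm$onset)  # onsets fall exactly on the 0.2-s lattice

  # onset between frames k and k+1 resolves to frame k+1
  tr <- traj_from_points(cbind(0:9, 0:9))
  arena <- default_arena()
  rec <- session_record("rx", "exp1", "center", 1, "FT", tr,
                        delivery_log(c(0.3, 0.8), availability = 0.2,
                                     session_length = 2), arena)
  dm2 <- delivery_moments(rec)
  expect_equal(dm2$t, c(0.4, 0.8))
  expect_equal(dm2$x, c(2, 4))

  rec$deliveries <- delivery_log(1.95, availability = 0.05,
                                 session_length = 2)
  expect_error(delivery_moments(rec), "beyond the last")
})

test_that("recurrence matrix equals the pairwise brute-force oracle", {
  const <- recurrence_matrix(rep(3L, 10))
  expect_true(all(const$indicator == 1L))
  expect_equal(recurrence_rate(const), 1)
  distinct <- recurrence_matrix(1:8)
  expect_identical(distinct$indicator, diag(1L, 8))
  expect_equal(recurrence_rate(distinct), 0)

  set.seed(12)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    regions <- sample(0:8, n, replace = TRUE)
    R <- recurrence_matrix(regions)
    brute <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      brute[i, j] <- as.integer(regions[i] == regions[j])
    expect_identical(R$indicator, brute)
    # symmetry, unit diagonal
    expect_identical(R$indicator, t(R$indicator))
    expect_true(all(diag(R$indicator) == 1L))
    expect_equal(recurrence_rate(R), (sum(brute) - n) / (n^2 - n))
  }

  # stride retains every k-th frame
  Rs <- recurrence_matrix(0:9, frame_stride = 3)
  expect_equal(Rs$n, 4)
  expect_error(recurrence_matrix(integer(0)), "empty")
  expect_error(recurrence_rate(recurrence_matrix(1L)), "at least 2")
})

test_that("two-state alternation recurrence rate matches brute force", {
  n <- 40
  regions <- rep(c(0L, 1L), n / 2)
  R <- recurrence_matrix(regions)
  same <- outer(regions, regions, "==")
  expect_equal(recurrence_rate(R), (sum(same) - n) / (n^2 - n))
  expect_equal(recurrence_rate(R), (n / 2 - 1) / (n - 1))
})

test_that("entropy has its closed-form extremes and oracle values", {
  g <- zone_grid(default_arena())
  one <- occ_from_times(c(1200, rep(0, 99)), g)
  expect_equal(entropy_index(one), 0)
  unif <- occ_from_times(rep(12, 100), g)
  expect_equal(entropy_index(unif), log(100))
  expect_equal(entropy_index(unif, normalized = TRUE), 1)

  # (0.5, 0.25, 0.25) occupancy: direct-summation oracle
  occ3 <- occ_from_times(c(600, 300, 300, rep(0, 97)), g)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(entropy_index(occ3), -sum(p * log(p)))

  # invariant under region relabeling
  perm <- sample(100)
  set.seed(21)
  times <- runif(100)
  expect_equal(entropy_index(occ_from_times(times, g)),
               entropy_index(occ_from_times(times[perm], g)))
  expect_error(entropy_index(occ_from_times(rep(0, 100), g)), "total_time")
})

test_that("entropy is bounded and maximal only at uniformity", {
  g <- zone_grid(default_arena())
  set.seed(5)
  for (rep in 1:50) {
    occ <- occ_from_times(runif(100), g)
    h <- entropy_index(occ)
    expect_gte(h, 0)
    expect_lte(h, log(100) + 1e-12)
    expect_lt(h, log(100))  # random times are almost surely non-uniform
  }
})

test_that("KL divergence is a regularised, nonnegative, asymmetric index", {
  g <- zone_grid(default_arena())
  set.seed(6)
  occ <- occ_from_times(runif(100, 0, 30), g)
  expect_equal(kl_divergence(occ, occ), 0)

  # disjoint single-region maps: closed form under the pseudocount
  p1 <- occ_from_times(c(1200, rep(0, 99)), g)
  p2 <- occ_from_times(c(0, 1200, rep(0, 98)), g)
  eps <- 0.2; tot <- 1200 + 100 * eps
  pa <- c(1200 + eps, rep(eps, 99)) / tot
  pb <- c(eps, 1200 + eps, rep(eps, 98)) / tot
  expect_equal(kl_divergence(p1, p2, pseudocount = eps),
               sum(pa * log(pa / pb)))
  expect_gt(kl_divergence(p1, p2), 0)

  # nonnegativity over random pairs; asymmetry on an uneven pair
  for (rep in 1:50) {
    a <- occ_from_times(runif(100, 0, 50), g)
    b <- occ_from_times(runif(100, 0, 50), g)
    expect_gte(kl_divergence(a, b), 0)
  }
  skew <- occ_from_times(c(rep(100, 5), rep(0.5, 95)), g)
  flat <- occ_from_times(rep(10, 100), g)
  expect_false(isTRUE(all.equal(kl_divergence(skew, flat),
                                kl_divergence(flat, skew))))
  # Jensen-Shannon variant is symmetric and bounded by log 2
  js1 <- kl_divergence(skew, flat, symmetric = TRUE)
  expect_equal(js1, kl_divergence(flat, skew, symmetric = TRUE))
  expect_lte(js1, log(2))
  expect_error(kl_divergence(occ, occ_from_times(rep(1, 25),
                                                 zone_grid(default_arena(), 5, 5))),
               "different grids")
})

test_that("path length sums consecutive displacements", {
  still <- traj_from_points(cbind(rep(3, 10), rep(3, 10)))
  expect_equal(path_length(still), 0)
  # straight 100-cm sweep, any frame count
  for (n in c(2, 11, 101)) {
    sweep <- traj_from_points(cbind(seq(0, 100, length.out = n), rep(50, n)))
    expect_equal(path_length(sweep), 100)
  }
  set.seed(9)
  tr <- random_traj(200)
  brute <- sum(sqrt(diff(tr$frames$x)^2 + diff(tr$frames$y)^2))
  expect_equal(path_length(tr), brute)
})

test_that("session metrics assemble per-session values and divergence chaining", {
  s1 <- small_session(seed = 1)
  s2 <- small_session(seed = 2)
  m1 <- session_metrics(s1)
  expect_true(is.na(m1$divergence_from_previous))
  expect_equal(m1$n_deliveries, length(s1$deliveries$onsets))
  expect_gte(m1$delivery_proximity_rate, 0)
  expect_lte(m1$delivery_proximity_rate, 1)
  expect_gte(m1$entropy, 0)
  expect_lte(m1$entropy, log(100))

  # two identical sessions diverge by 0
  m_same <- session_metrics(s1, previous = s1)
  expect_equal(m_same$divergence_from_previous, 0)
  m12 <- session_metrics(s2, previous = s1)
  expect_gt(m12$divergence_from_previous, 0)

  other <- s2
  other$subject <- "someone-else"
  expect_error(session_metrics(s2, previous = other), "different subject")
})

test_that("transition entropy summarises movement between regions", {
  expect_equal(transition_entropy(rep(1L, 50)), 0)
  # strict alternation: 25 forward and 24 backward transitions in 49 pairs
  p <- c(25, 24) / 49
  expect_equal(transition_entropy(rep(c(0L, 1L), 25)), -sum(p * log(p)))
})
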