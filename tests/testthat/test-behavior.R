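make_dir_traj <- function(dirs) {
  n <- length(dirs)
  tr <- data.frame(t = seq_len(n) * 0.4, x = 0, y = 0, hd = dirs,
                   speed = 10, run_dir = dirs, valid = TRUE)
  attr(tr, "rate") <- 2.5
  tr
}

test_that("Rayleigh vector length of running direction matches resultant arithmetic", {
  expect_equal(running_dir_rayleigh(make_dir_traj(rep(73, 50))), 1)
  expect_equal(running_dir_rayleigh(make_dir_traj(seq(0, 359, by = 1))), 0,
               tolerance = 1e-10)
  # 2:1 mixture of opposite directions: |2 - 1| / 3
  expect_equal(running_dir_rayleigh(make_dir_traj(c(rep(0, 40), rep(180, 20)))),
               1 / 3, tolerance = 1e-12)
  expect_error(running_dir_rayleigh(make_dir_traj(10)), "2")
  # invariance under global rotation
  set.seed(2)
  dirs <- runif(200, 0, 360)
  expect_equal(running_dir_rayleigh(make_dir_traj(dirs)),
               running_dir_rayleigh(make_dir_traj((dirs + 111) %% 360)))
})

test_that("mean absolute direction change matches constructions", {
  expect_equal(mean_abs_direction_change(make_dir_traj(rep(45, 30))), 0)
  expect_equal(mean_abs_direction_change(make_dir_traj(cumsum(rep(10, 40)) %% 360)),
               10, tolerance = 1e-9)
  zig <- rep(c(45, -45), 30) %% 360
  expect_equal(mean_abs_direction_change(make_dir_traj(zig)), 90)
})

test_that("path excess ratio is path length over goal separation", {
  cfg <- quick_config(60)
  tr <- straight_trajectory(cfg, start = c(5, 30), v = c(10, 0), duration = 4)
  goal <- c(tr$x[nrow(tr)], 30)
  expect_equal(path_excess_ratio(tr, c(5, 30), goal, 0, 4), 1,
               tolerance = 1e-9)
  # two sides of a square between opposite corners -> sqrt(2)
  t <- seq(0, 20, by = 0.02)
  x <- pmin(10 * t / 10, 10); y <- pmax(0, 10 * (t - 10) / 10)
  trs <- data.frame(t = t, x = x, y = y, hd = 0, speed = 0, run_dir = 0,
                    valid = TRUE)
  attr(trs, "rate") <- 50
  expect_equal(path_excess_ratio(trs, c(0, 0), c(10, 10), 0, 20), sqrt(2),
               tolerance = 1e-3)
  expect_error(path_excess_ratio(tr, c(5, 30), c(5, 30), 0, 2), "coincide")
  # invariant: never meaningfully below 1
  cfg2 <- quick_config(120)
  trr <- simulate_trajectory(cfg2, seed = 3)
  p0 <- c(trr$x[1], trr$y[1]); p1 <- c(trr$x[3000], trr$y[3000])
  expect_gte(path_excess_ratio(trr, p0, p1, 0, trr$t[3000]), 1 - 1e-6)
})

test_that("quadrant dwell fractions sum to one and match constructions", {
  cfg <- quick_config(120)
  tr <- simulate_trajectory(cfg, seed = 6)
  q <- quadrant_dwell(tr)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  # confined to the first quadrant (x > w/2, y > w/2)
  trc <- tr
  trc$x <- 30 + trc$x / 4 + 1
  trc$y <- 30 + trc$y / 4 + 1
  expect_equal(quadrant_dwell(trc), c(1, 0, 0, 0))
  # near-uniform occupancy: about 0.25 each
  trl <- simulate_trajectory(quick_config(1200), seed = 7)
  expect_true(all(abs(quadrant_dwell(trl) - 0.25) < 0.1))
})

test_that("behavior_summary assembles the battery", {
  s <- quick_session(duration = 120, seed = 8)
  b <- behavior_summary(s)
  expect_true(all(c("mean_speed", "dir_rayleigh", "mean_abs_dir_change") %in%
                  names(b)))
  expect_gt(b$mean_speed, 5)
  expect_equal(b$q1 + b$q2 + b$q3 + b$q4, 1, tolerance = 1e-9)
})

test_that("wall-following fraction detects wall-parallel running", {
  cfg <- quick_config(300)
  free <- simulate_trajectory(cfg, seed = 9)
  hug <- simulate_trajectory(cfg, wall_follow_bias = 0.9, seed = 9)
  chance <- 4 * 30 / 360
  expect_gt(wall_following_fraction(hug), wall_following_fraction(free))
  expect_gt(wall_following_fraction(hug), chance)
  # straight axis-aligned path: fraction 1
  ax <- straight_trajectory(cfg, start = c(5, 30), v = c(12, 0))
  expect_equal(wall_following_fraction(ax), 1)
})
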