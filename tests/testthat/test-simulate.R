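test_that("trajectories stay in the arena, are deterministic, and hit the target speed", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, mean_speed = 12, seed = 5)
  expect_true(all(tr$x >= 0 & tr$x <= 60 & tr$y >= 0 & tr$y <= 60))
  expect_lt(abs(mean(tr$speed) - 12) / 12, 0.10)
  tr2 <- simulate_trajectory(cfg, mean_speed = 12, seed = 5)
  expect_identical(tr, tr2)
  # zero acceleration noise: straight billiard segments at constant speed
  tr0 <- simulate_trajectory(cfg, smoothness = 0, seed = 6)
  # constant speed except at the isolated wall-reflection samples
  expect_lt(unname(quantile(abs(tr0$speed - 12), 0.99)), 0.5)
  expect_true(all(in_arena(cfg, tr0$x, tr0$y)))
  # cylinder containment
  cfgc <- session_config(arena_shape = "cylinder", arena_width = 60,
                         trial_duration = 300)
  trc <- simulate_trajectory(cfgc, seed = 7)
  expect_true(all(trc$x^2 + trc$y^2 <= 30.001^2))
})

test_that("homogeneous Poisson spike counts match the rate", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 8)
  lam <- 3
  sp <- simulate_spikes(tr, cell_spec("uniform", peak_rate = lam), seed = 9)
  expect_lt(abs(length(sp$t) - lam * 600), 4 * sqrt(lam * 600))
  expect_true(all(sp$t >= 0 & sp$t <= 600))
  expect_false(is.unsorted(sp$t))
})

test_that("place-cell spikes concentrate in the field", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 10)
  sp <- simulate_spikes(tr, cell_spec("place", peak_rate = 8,
                                      centers = c(30, 30), sigma = 8),
                        seed = 11)
  d <- sqrt((sp$ann$x - 30)^2 + (sp$ann$y - 30)^2)
  expect_gt(mean(d <= 24), 0.90) # 3 sigma
})

test_that("kappa = 0 head-direction cells fire uniformly over direction", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 12)
  sp <- simulate_spikes(tr, cell_spec("hd", peak_rate = 5, hd_kappa = 0),
                        seed = 13)
  # compare spike directions against occupancy via binned rates
  tun <- make_dir_tuning(tr, sp, kernel = 1)
  expected <- length(sp$t) * tun$occupancy / sum(tun$occupancy)
  keep <- expected > 1
  stat <- sum((tun$spike_count[keep] - expected[keep])^2 / expected[keep])
  p <- stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("time-rescaling of simulated spike trains matches the generative intensity", {
  # Ogata: transform spike times by the cumulative intensity; the rescaled
  # intervals must be Exp(1)
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 14)
  spec <- cell_spec("place", peak_rate = 8, centers = c(30, 30), sigma = 10,
                    baseline_rate = 0.5)
  sp <- simulate_spikes(tr, spec, seed = 15)
  lam <- spatcell:::cell_rate(spec, tr$x, tr$y, tr$hd, tr$speed, cfg)
  dt <- 1 / cfg$position_rate
  Lam <- cumsum(lam) * dt
  Lam_at <- stats::approx(c(tr$t, 600), c(0, Lam), xout = sp$t)$y
  u <- diff(Lam_at)
  ks <- stats::ks.test(u, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("speed-coupled LFP has the generative frequency structure", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 16)
  # no speed coupling, no noise: a pure tone
  l0 <- simulate_lfp(tr, base_freq = 8, speed_slope = 0, noise_sd = 0, seed = 1)
  th0 <- instantaneous_theta(l0)
  mid <- 1000:(length(th0$freq) - 1000)
  expect_lt(max(abs(th0$freq[mid] - 8), na.rm = TRUE), 0.05)
  # slope 0.1 Hz/(cm/s): f(v=20) - f(v=5) = 1.5 Hz by construction
  l1 <- simulate_lfp(tr, base_freq = 7, speed_slope = 0.1, noise_sd = 0, seed = 2)
  f <- attr(l1, "gt_freq")
  tl <- (seq_along(f) - 1) / l1$rate
  v <- stats::approx(tr$t, tr$speed, xout = tl, rule = 2)$y
  f20 <- mean(f[abs(v - 20) < 1]); f5 <- mean(f[abs(v - 5) < 1])
  expect_equal(f20 - f5, 1.5, tolerance = 0.05)
  # determinism
  l2 <- simulate_lfp(tr, base_freq = 8, speed_slope = 0.05, seed = 3)
  l3 <- simulate_lfp(tr, base_freq = 8, speed_slope = 0.05, seed = 3)
  expect_identical(l2$v, l3$v)
  # undersampled LFP is rejected
  expect_error(simulate_lfp(tr, base_freq = 8, lfp_rate = 20, seed = 1),
               "4x")
})

test_that("VR manipulations transform the generative parameters exactly", {
  cfg <- quick_config(120)
  specs <- list(cell_spec("place", peak_rate = 8, centers = c(20, 35), sigma = 7),
                cell_spec("grid", peak_rate = 10, grid_spacing = 25,
                          centers = c(30, 30)),
                cell_spec("hd", peak_rate = 10, hd_mu = 40, hd_kappa = 3))
  # neutral manipulation: identical ground truth
  id <- vr_manipulation(scale_factor = 1, grid_scale_factor = 1)
  pr <- make_vr_pair(specs, id, cfg, cfg, seed = 1)
  expect_equal(pr$vr$ground_truth$specs, pr$r$ground_truth$specs)
  # the paper-scale expansion: sigma and spacing ratios exact
  manip <- vr_manipulation(scale_factor = 1.44, grid_scale_factor = 1.42,
                           rotation = 180)
  pr2 <- make_vr_pair(specs, manip, cfg, cfg, seed = 1)
  expect_equal(pr2$vr$ground_truth$specs[[1]]$sigma / specs[[1]]$sigma, 1.44)
  expect_equal(pr2$vr$ground_truth$specs[[2]]$grid_spacing /
                 specs[[2]]$grid_spacing, 1.42)
  # 180-degree rotation reflects field centres through the arena centre
  expect_equal(as.vector(pr2$vr$ground_truth$specs[[1]]$centers),
               c(60 - 20, 60 - 35))
  expect_equal(pr2$vr$ground_truth$specs[[3]]$hd_mu, (40 + 180) %% 360)
})

test_that("loop trajectories are direction-biased and stay in the arena", {
  cfg <- quick_config(300)
  tr <- simulate_loop_trajectory(cfg, seed = 3)
  expect_true(all(in_arena(cfg, tr$x, tr$y)))
  # one rotational sense dominates: signed heading change is mostly positive
  ds <- downsample_behavior(derive_kinematics(smooth_positions(tr)))
  dchange <- spatcell:::wrap180(diff(ds$run_dir))
  expect_gt(mean(dchange, na.rm = TRUE), 5) # net positive angular drift

})
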