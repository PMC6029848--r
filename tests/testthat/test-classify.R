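test_that("spike-time shuffling is a rigid modular shift", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 41)
  sp <- simulate_spikes(tr, cell_spec("uniform", peak_rate = 3), seed = 42)
  # full-wrap offset restores the original train
  back <- shuffle_spikes(sp, tr, offset = cfg$trial_duration)
  expect_equal(back$t, sp$t, tolerance = 1e-9)
  # inter-spike intervals preserved up to the single wrap point
  sh <- shuffle_spikes(sp, tr, seed = 5)
  isi0 <- sort(round(diff(sp$t), 9))
  isi1 <- sort(round(diff(sh$t), 9))
  expect_gte(sum(isi1 %in% isi0), length(isi0) - 2)
  expect_length(sh$t, length(sp$t))
  expect_error(shuffle_spikes(sp, straight_trajectory(quick_config(6)), ),
               "short")
})

test_that("tuned cells pass their own classifier and fail irrelevant criteria", {
  s <- quick_session(duration = 600, seed = 43)
  # cells: 1 place, 2 grid, 3 hd, 4 speed, 5 uniform
  res <- classify_cells(s, n_shuffles = 300, seed = 7, max_lag = 20)
  expect_true(res$place_pass[1])
  expect_true(res$grid_pass[2])
  expect_true(res$hd_pass[3])
  expect_true(res$speed_pass[4])
  expect_false(res$place_pass[5])
  expect_false(res$grid_pass[5])
  expect_false(res$hd_pass[5])
  expect_false(res$speed_pass[5])
  expect_false(res$grid_pass[1]) # a single field is not a grid
})

test_that("classification is reproducible and respects the peak-rate criterion", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 44)
  # a highly informative but weak (sub-2 Hz) place cell fails the rule
  weak <- simulate_spikes(tr, cell_spec("place", peak_rate = 1.2,
                                        centers = c(30, 30), sigma = 8,
                                        baseline_rate = 0.1), seed = 45)
  s <- session(cfg, tr, list(weak))
  r1 <- classify_place(s, 1, n_shuffles = 200, seed = 3)
  expect_gt(r1$observed, r1$percentile_99) # informative...
  expect_lt(r1$peak_rate, 2)
  expect_false(r1$passes) # ...but below the 2 Hz requirement
  r2 <- classify_place(s, 1, n_shuffles = 200, seed = 3)
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$null_values, r2$null_values)
})

test_that("a low-count cell is flagged rather than classified", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 46)
  sp <- annotate_spikes(spike_train(sort(runif(30, 0, 300))), tr)
  s <- session(cfg, tr, list(sp))
  r <- classify_place(s, 1, n_shuffles = 100, seed = 1)
  expect_true(isTRUE(r$low_count))
  expect_true(is.na(r$passes))
})

test_that("the batched grid null agrees with the per-map scores", {
  cfg <- quick_config(600)
  tr <- simulate_trajectory(cfg, seed = 47)
  sp <- simulate_spikes(tr, cell_spec("grid", peak_rate = 10,
                                      grid_spacing = 24,
                                      centers = c(30, 30)), seed = 48)
  s <- session(cfg, tr, list(sp))
  ctx <- spatcell:::classify_context(s)
  shifts <- spatcell:::shuffle_shifts(ctx, 5, 4, 9)
  sm <- as.matrix(spatcell:::shifted_counts(ctx, s$cells[[1]], shifts) %*% ctx$K)
  rates <- sweep(sm, 2, ctx$sm_dwell, `/`)
  gb <- spatcell:::gridness_batch(t(rates), 40, 40, 20)
  gr <- apply(rates, 1, function(rv) {
    ac <- spatcell:::autocorr_cpp(matrix(rv, 40, 40), 20L, 20L)
    spatcell:::gridness_core(ac, 20)$gridness
  })
  expect_equal(as.numeric(gb), as.numeric(gr), tolerance = 1e-10)
})

test_that("the FFT shifted-correlation engine matches direct Pearson r", {
  set.seed(49)
  n <- 500
  a <- rpois(n, 2); ma <- rep(1, n)
  b <- rnorm(n, 10, 3); mb <- rep(1, n)
  r_all <- spatcell:::shifted_pearson(a, ma, b, mb)
  for (s in c(0, 7, 133)) {
    a_s <- a[((seq_len(n) - 1 + s) %% n) + 1]
    expect_equal(r_all[s + 1], cor(a_s, b), tolerance = 1e-9)
  }
  # with masked samples
  mv <- as.numeric(runif(n) > 0.1)
  r_m <- spatcell:::shifted_pearson(a, ma, b * mv, mv)
  s <- 13
  a_s <- a[((seq_len(n) - 1 + s) %% n) + 1]
  keep <- mv > 0
  expect_equal(r_m[s + 1], cor(a_s[keep], b[keep]), tolerance = 1e-9)
})
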