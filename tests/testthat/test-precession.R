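# a circular ideal field and hand-built straight passes give exact
# geometric oracles for pass normalisation and pdcd
make_circular_field <- function(cfg, center = c(30, 30), sigma = 8) {
  m <- ideal_ratemap(cfg, function(x, y)
    10 * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma^2)))
  detect_fields(m, min_bins = 5)
}

test_that("field passes are normalised onto the unit disc", {
  cfg <- quick_config(60)
  fs <- make_circular_field(cfg)
  # straight diametric pass: a horizontal chord through the origin
  tr <- straight_trajectory(cfg, start = c(10, 30), v = c(12, 0), duration = 3.4)
  passes <- extract_passes(tr, fs, cfg)
  expect_length(passes, 1)
  sm <- passes[[1]]$samples
  expect_lt(max(abs(sm$uy)), 0.1) # on the horizontal axis
  expect_lt(min(abs(sm$ux)), 0.05) # crosses the origin
  expect_gt(max(sm$ux), 0.9) # reaches the edge
  expect_true(all(abs(sm$dir) < 1e-6 | abs(sm$dir - 360) < 1e-6))
  # a pass along the field edge keeps radius near 1
  r_edge <- sqrt(2 * log(2)) * 8
  tr2 <- straight_trajectory(cfg, start = c(30 - 6, 30 + r_edge * 0.97),
                             v = c(12, 0), duration = 1)
  p2 <- extract_passes(tr2, fs, cfg)
  if (length(p2)) {
    rr <- sqrt(p2[[1]]$samples$ux^2 + p2[[1]]$samples$uy^2)
    expect_gt(min(rr), 0.75)
  }
  # passes shorter than 3 samples are discarded
  trs <- straight_trajectory(cfg, start = c(10, 30), v = c(12, 0), duration = 3.4)
  trs$valid[trs$x > 25 & trs$x < 35] <- FALSE
  trs$valid[which(trs$x >= 22 & trs$x <= 23)[-(1:2)]] <- FALSE
  # count matches the contiguous in-field segments of the schedule
  p3 <- extract_passes(trs, fs, cfg)
  expect_true(all(vapply(p3, function(p) nrow(p$samples), 1L) >= 3))
})

test_that("pdcd is the signed travelled distance through the field", {
  cfg <- quick_config(60)
  fs <- make_circular_field(cfg)
  tr <- straight_trajectory(cfg, start = c(10, 30), v = c(12, 0), duration = 3.4)
  pass <- extract_passes(tr, fs, cfg)[[1]]
  t_peak <- (30 - 10) / 12 # crossing the centre
  st <- c(pass$samples$t[3], t_peak, max(pass$samples$t) - 0.05)
  out <- compute_pdcd(pass, st)
  expect_lt(abs(out$pdcd[2]), 0.05) # spike at the peak: pdcd ~ 0
  expect_true(all(diff(out$pdcd) > 0)) # monotone along a straight pass
  expect_equal(nrow(out), 3)
  # spikes at known traversal fractions map to those fractions
  frac <- c(-0.5, 0.5)
  st2 <- t_peak + frac * (sqrt(2 * log(2)) * 8) / 12
  out2 <- compute_pdcd(pass, st2)
  expect_equal(out2$pdcd, frac, tolerance = 0.12)
})

test_that("circular-linear regression recovers slopes and calibrates its null", {
  set.seed(61)
  n <- 400
  x <- runif(n, -1, 1)
  ph <- (180 - 180 * x + rnorm(n, 0, 40)) %% 360
  fit <- fit_precession(data.frame(pdcd = x, phase = ph))
  expect_equal(fit$slope, -180, tolerance = 12)
  expect_lt(fit$p, 0.05)
  expect_lt(fit$circ_lin_r, 0) # phase decreases with pdcd
  # offset shifts with an added constant; slope does not
  fit2 <- fit_precession(data.frame(pdcd = x, phase = (ph + 50) %% 360))
  expect_equal(fit2$slope, fit$slope, tolerance = 3)
  expect_equal(spatcell:::wrap180(fit2$offset - fit$offset - 50), 0,
               tolerance = 5)
  # phase independent of pdcd: near-zero slope significance at nominal rate
  ph0 <- runif(n, 0, 360)
  fit0 <- fit_precession(data.frame(pdcd = x, phase = ph0))
  expect_gt(fit0$p, 0.01)
  expect_lt(abs(fit0$circ_lin_r), 0.15)
  # too few spikes: NaN fit
  tiny <- fit_precession(data.frame(pdcd = x[1:10], phase = ph[1:10]))
  expect_true(is.nan(tiny$slope))
})

test_that("the full 2-D precession pipeline recovers the generative sweep", {
  cfg <- quick_config(1200)
  spec <- cell_spec("place", peak_rate = 12, centers = c(30, 30), sigma = 9,
                    precession_range = 360)
  s <- simulate_session(cfg, list(spec), seed = 62, lfp_noise_sd = 0.2)
  pf <- phase_precession(s, 1)
  expect_lt(pf$p, 0.05)
  expect_lt(pf$circ_lin_r, -0.4)
  expect_equal(pf$slope, -180, tolerance = 25)
  samp <- attr(pf, "samples")
  expect_true(all(abs(samp$pdcd) <= 1.2 + 1e-9))
  # shuffled phases: non-significant
  set.seed(63)
  samp$phase <- sample(samp$phase)
  null_fit <- fit_precession(samp)
  expect_gt(null_fit$p, 0.01)
  # a session without precession shows no phase-pdcd relationship
  s0 <- simulate_session(cfg, list(cell_spec("place", peak_rate = 12,
                                             centers = c(30, 30), sigma = 9)),
                         seed = 64, lfp_noise_sd = 0.2)
  pf0 <- phase_precession(s0, 1)
  expect_lt(abs(pf0$circ_lin_r), 0.15)
})
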