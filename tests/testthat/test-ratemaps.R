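test_that("rate maps follow the spikes/dwell definition", {
  cfg <- quick_config(120)
  tr <- simulate_trajectory(cfg, seed = 1)
  # zero spikes: all finite bins zero
  sp0 <- annotate_spikes(spike_train(numeric(0)), tr)
  m0 <- make_ratemap(tr, sp0, cfg)
  expect_true(all(m0$rate[is.finite(m0$rate)] == 0))
  # single spike, unsmoothed: rate = 1 / dwell in that bin
  spt <- annotate_spikes(spike_train(tr$t[500] + 0.01), tr)
  m1 <- make_ratemap(tr, spt, cfg, kernel = 1)
  b <- which(m1$spike_count == 1)
  expect_length(b, 1)
  expect_equal(m1$rate[b], 1 / m1$dwell[b])
  # homogeneous Poisson cell: rates approximately flat at lambda
  cfg2 <- quick_config(1200)
  tr2 <- simulate_trajectory(cfg2, seed = 2)
  sp <- simulate_spikes(tr2, cell_spec("uniform", peak_rate = 5), seed = 3)
  m <- make_ratemap(tr2, sp, cfg2)
  expect_equal(mean(m$rate[m$dwell > 0.3], na.rm = TRUE), 5, tolerance = 0.15)
})

test_that("smoothing conserves mass and never raises the peak", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 4)
  sp <- simulate_spikes(tr, cell_spec("place", peak_rate = 8,
                                      centers = c(30, 30)), seed = 5)
  m <- make_ratemap(tr, sp, cfg)
  expect_equal(sum(m$sm_spk, na.rm = TRUE), sum(m$spike_count))
  expect_equal(sum(m$sm_dwell, na.rm = TRUE), sum(m$dwell), tolerance = 1e-9)
  raw <- make_ratemap(tr, sp, cfg, kernel = 1)
  expect_lte(max(m$rate, na.rm = TRUE), max(raw$rate, na.rm = TRUE))
})

test_that("rate-map construction is linear in spike trains", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 6)
  a <- simulate_spikes(tr, cell_spec("uniform", peak_rate = 2), seed = 7)
  b <- simulate_spikes(tr, cell_spec("place", peak_rate = 6,
                                     centers = c(20, 40)), seed = 8)
  ab <- annotate_spikes(spike_train(sort(c(a$t, b$t))), tr)
  m_ab <- make_ratemap(tr, ab, cfg)
  m_a <- make_ratemap(tr, a, cfg)
  m_b <- make_ratemap(tr, b, cfg)
  expect_equal(m_ab$spike_count, m_a$spike_count + m_b$spike_count)
})

test_that("directional tuning matches oracles", {
  cfg <- quick_config(900)
  tr <- simulate_trajectory(cfg, seed = 9)
  # sharp HD cell peaks at its preferred direction
  sp <- simulate_spikes(tr, cell_spec("hd", peak_rate = 12, hd_mu = 90,
                                      hd_kappa = 8), seed = 10)
  tun <- make_dir_tuning(tr, sp)
  expect_lt(abs(spatcell:::wrap180(tun$centers[which.max(tun$rate)] - 90)), 15)
  # constant-rate cell: flat tuning
  spu <- simulate_spikes(tr, cell_spec("uniform", peak_rate = 5), seed = 11)
  tunu <- make_dir_tuning(tr, spu)
  expect_lt(rayleigh_vector(tunu), 0.08)
  # von Mises kappa = 2: Rayleigh length ~ I1(2)/I0(2)
  spv <- simulate_spikes(tr, cell_spec("hd", peak_rate = 10, hd_mu = 130,
                                       hd_kappa = 2), seed = 12)
  tunv <- make_dir_tuning(tr, spv)
  bessel <- besselI(2, 1) / besselI(2, 0)
  expect_equal(rayleigh_vector(tunv), bessel, tolerance = 0.05)
})

test_that("field detection matches geometry oracles", {
  cfg <- quick_config(120)
  # constant map: area fraction 1, every bin at the peak
  mc <- ideal_ratemap(cfg, function(x, y) 3 + 0 * x)
  fc <- detect_fields(mc)
  expect_equal(fc$area_frac, 1)
  # isolated Gaussian: half-max area ~ pi * (sigma sqrt(2 ln 2))^2
  sg <- 6
  mg <- ideal_ratemap(cfg, function(x, y)
    10 * exp(-((x - 30)^2 + (y - 30)^2) / (2 * sg^2)))
  fg <- detect_fields(mg)
  analytic <- pi * 2 * log(2) * sg^2 / 60^2
  expect_equal(fg$area_frac, analytic, tolerance = 0.08)
  # two equal far-apart Gaussians: two fields of equal area
  m2 <- ideal_ratemap(cfg, function(x, y)
    8 * (exp(-((x - 15)^2 + (y - 15)^2) / 50) +
         exp(-((x - 45)^2 + (y - 45)^2) / 50)))
  f2 <- detect_fields(m2)
  expect_equal(nrow(f2$fields), 2)
  expect_equal(f2$fields$n_bins[1], f2$fields$n_bins[2], tolerance = 0.1)
  expect_error(detect_fields(ideal_ratemap(cfg, function(x, y) NA * x)),
               "NaN")
})

test_that("spatial autocorrelograms have the required structure", {
  cfg <- quick_config(120)
  m <- ideal_ratemap(cfg, hex_rate_fun(24))
  ac <- spatial_autocorr(m, max_lag = 24)
  L <- ac$max_lag
  expect_equal(ac$ac[L + 1, L + 1], 1, tolerance = 1e-9) # self-correlation
  expect_equal(ac$ac, ac$ac[nrow(ac$ac):1, ncol(ac$ac):1]) # point symmetry
  # six nearest peaks at the lattice spacing
  expect_equal(grid_scale(ac), 24, tolerance = 1.5)
  # constant map: warning + NaN correlogram
  expect_warning(acc <- spatial_autocorr(ideal_ratemap(cfg, function(x, y) 1 + 0 * x)),
                 "degenerate")
  expect_true(all(is.nan(acc$ac)))
  # C++ fast path agrees with a plain-R reference on a masked map
  set.seed(13)
  r <- matrix(rexp(400), 20, 20)
  r[sample(400, 12)] <- NA
  acm <- autocorr_ref(r, 8, 20)
  accpp <- spatcell:::autocorr_cpp(r, 8L, 20L)
  expect_equal(accpp, acm, tolerance = 1e-12)
  # and the finite fast path agrees with the masked general path
  r2 <- matrix(rexp(400), 20, 20)
  expect_equal(spatcell:::autocorr_cpp(r2, 8L, 20L),
               autocorr_ref(r2, 8, 20), tolerance = 1e-12)
})
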