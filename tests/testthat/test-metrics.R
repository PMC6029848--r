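test_that("spatial information matches closed forms and a brute-force oracle", {
  cfg <- quick_config(120)
  # uniform map: zero bits
  mu <- ideal_ratemap(cfg, function(x, y) 4 + 0 * x)
  expect_equal(spatial_information(mu), 0)
  # rate 2L on half the bins, 0 elsewhere, uniform dwell: exactly 1 bit/spike
  mh <- ideal_ratemap(cfg, function(x, y) ifelse(x < 30, 4, 0))
  expect_equal(spatial_information(mh), 1, tolerance = 1e-12)
  # Gaussian field: matches direct summation to machine precision
  mg <- ideal_ratemap(cfg, function(x, y)
    7 * exp(-((x - 25)^2 + (y - 35)^2) / 72))
  lam <- as.vector(mg$rate)
  p <- rep(1 / length(lam), length(lam))
  lbar <- sum(p * lam)
  oracle <- sum(ifelse(lam > 0, p * lam / lbar * log2(lam / lbar), 0))
  expect_equal(spatial_information(mg), oracle, tolerance = 1e-12)
  # invariant under rate rescaling
  mg2 <- mg
  mg2$sm_spk <- mg$sm_spk * 3.7
  mg2$rate <- mg$rate * 3.7
  expect_equal(spatial_information(mg2), spatial_information(mg),
               tolerance = 1e-12)
  # zero-spike map: NaN
  expect_true(is.nan(spatial_information(ideal_ratemap(cfg, function(x, y) 0 * x))))
})

make_tuning <- function(rate, occ = rep(1, length(rate)), bin = 6) {
  structure(list(rate = rate, occupancy = occ, spike_count = rate * occ,
                 sm_occ = occ, bin_width = bin,
                 centers = (seq_along(rate) - 0.5) * bin),
            class = "dir_tuning")
}

test_that("directional information matches closed forms", {
  expect_equal(directional_information(make_tuning(rep(2, 60))), 0)
  one <- rep(0, 60); one[17] <- 5
  expect_equal(directional_information(make_tuning(one)), log2(60),
               tolerance = 1e-12)
  # von Mises tuning: numeric-integration oracle at fine binning
  kappa <- 2
  nb <- 360
  th <- (seq_len(nb) - 0.5) * (360 / nb)
  vm <- exp(kappa * cos((th - 180) * pi / 180))
  tun <- make_tuning(vm, bin = 1)
  lbar <- mean(vm)
  oracle <- mean(vm / lbar * log2(vm / lbar))
  expect_equal(directional_information(tun), oracle, tolerance = 1e-9)
})

test_that("Rayleigh vector and tuning width match circular-statistics oracles", {
  expect_equal(rayleigh_vector(make_tuning(rep(3, 60))), 0, tolerance = 1e-12)
  one <- rep(0, 60); one[5] <- 2
  expect_equal(rayleigh_vector(make_tuning(one)), 1)
  kappa <- 2
  th <- (seq_len(360) - 0.5)
  vm <- exp(kappa * cos((th - 90) * pi / 180))
  expect_equal(rayleigh_vector(make_tuning(vm, bin = 1)),
               besselI(kappa, 1) / besselI(kappa, 0), tolerance = 1e-4)
  # half-height width of a von Mises curve: root of exp(k cos w/2) = (1+e^k.. )/2
  # computed numerically on the same curve
  half <- (max(vm) + min(vm)) / 2
  wfun <- function(w) exp(kappa * cos(w)) - half
  w_half <- 2 * stats::uniroot(wfun, c(0, pi))$root * 180 / pi
  expect_equal(tuning_width(make_tuning(vm, bin = 1)), w_half, tolerance = 1)
  # rotation invariance
  vm_rot <- vm[c(101:360, 1:100)]
  expect_equal(tuning_width(make_tuning(vm_rot, bin = 1)),
               tuning_width(make_tuning(vm, bin = 1)), tolerance = 1e-9)
  # concentration limit: narrow tuning, small width
  vm_sharp <- exp(50 * cos((th - 90) * pi / 180))
  expect_lt(tuning_width(make_tuning(vm_sharp, bin = 1)), 45)
  expect_true(is.nan(tuning_width(make_tuning(rep(1, 60)))))
})

test_that("gridness separates hexagonal, square and rotationally symmetric maps", {
  cfg <- quick_config(120)
  hexmap <- ideal_ratemap(cfg, hex_rate_fun(24))
  achex <- spatial_autocorr(hexmap, max_lag = 24)
  expect_gt(gridness(achex), 0.8)
  # square lattice: 90-degree symmetry beats 60 -> negative gridness
  sqmap <- ideal_ratemap(cfg, function(x, y)
    10 * pmax(cos(2 * pi * x / 24) + cos(2 * pi * y / 24), 0) / 2)
  acsq <- spatial_autocorr(sqmap, max_lag = 24)
  expect_lt(gridness(acsq), 0)
  # single circular Gaussian: all rotations equivalent, gridness ~ 0
  gmap <- ideal_ratemap(cfg, function(x, y)
    10 * exp(-((x - 30)^2 + (y - 30)^2) / 128))
  acg <- spatial_autocorr(gmap, max_lag = 24)
  g0 <- gridness(acg)
  expect_lt(abs(g0), 0.3)
  # invariance under 60-degree rotation of an ideal lattice
  hex60 <- ideal_ratemap(cfg, hex_rate_fun(24, orient = 60))
  expect_equal(as.numeric(gridness(spatial_autocorr(hex60, max_lag = 24))),
               as.numeric(gridness(achex)), tolerance = 0.05)
})

test_that("grid scale recovers the generative spacing and is rate-scale invariant", {
  cfg <- quick_config(120)
  for (sp in c(18, 30)) {
    m <- ideal_ratemap(cfg, hex_rate_fun(sp))
    ac <- spatial_autocorr(m, max_lag = 24)
    expect_equal(grid_scale(ac), sp, tolerance = 1.5)
  }
  m <- ideal_ratemap(cfg, hex_rate_fun(24))
  m2 <- m; m2$rate <- m$rate * 5
  expect_identical(grid_scale(spatial_autocorr(m2, max_lag = 24)),
                   grid_scale(spatial_autocorr(m, max_lag = 24)))
})

test_that("map similarity behaves like a rotation-aware Pearson correlation", {
  cfg <- quick_config(300)
  tr <- simulate_trajectory(cfg, seed = 21)
  sp <- simulate_spikes(tr, cell_spec("place", peak_rate = 8,
                                      centers = c(20, 40)), seed = 22)
  m <- make_ratemap(tr, sp, cfg)
  expect_equal(map_similarity(m, m, 0), 1)
  # point-reflected copy matches itself under 180-degree rotation
  mr <- m
  mr$rate <- m$rate[nrow(m$rate):1, ncol(m$rate):1]
  expect_equal(map_similarity(m, mr, 180), 1)
  expect_equal(map_similarity(m, mr, 0), map_similarity(mr, m, 0)) # symmetry
  # independent random maps: near-zero correlation
  set.seed(23)
  ra <- m; ra$rate <- matrix(rexp(1600), 40, 40)
  rb <- m; rb$rate <- matrix(rexp(1600), 40, 40)
  expect_lt(abs(map_similarity(ra, rb, 0)), 3 / sqrt(1600))
})

test_that("per-field directional information separates field-specific tuning", {
  cfg <- quick_config(1200)
  tr <- simulate_trajectory(cfg, seed = 24)
  # two place fields with opposite preferred directions
  spec_a <- cell_spec("place", peak_rate = 10, centers = c(18, 18), sigma = 6,
                      dir_mod_depth = 0.9, dir_mod_mu = 0)
  spec_b <- cell_spec("place", peak_rate = 10, centers = c(42, 42), sigma = 6,
                      dir_mod_depth = 0.9, dir_mod_mu = 180)
  a <- simulate_spikes(tr, spec_a, seed = 25)
  b <- simulate_spikes(tr, spec_b, seed = 26)
  sp <- annotate_spikes(spike_train(sort(c(a$t, b$t))), tr)
  m <- make_ratemap(tr, sp, cfg)
  fs <- detect_fields(m)
  expect_equal(nrow(fs$fields), 2)
  per <- per_field_dir_info(tr, sp, fs, cfg)
  pooled <- directional_information(make_dir_tuning(tr, sp))
  expect_gt(min(per), pooled) # opposing tunings cancel in the pooled curve
  # a tiny field yields NaN with a warning
  fs_small <- fs
  fs_small$fields <- fs$fields[1, ]
  fs_small$labels[fs_small$labels == 1L] <- 0L
  keep <- which(fs$labels == 2L)[1:3]
  fs_small$labels[] <- 0L
  fs_small$labels[keep] <- 1L
  fs_small$fields$id <- 1L
  expect_warning(res <- per_field_dir_info(tr, sp, fs_small, cfg), "NaN|spikes")
  expect_true(is.nan(res))
})
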