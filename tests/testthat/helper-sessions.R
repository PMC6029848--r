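# Shared small fixtures, built in code at test time.

quick_config <- function(duration = 120, width = 60, ...) {
  session_config(arena_width = width, trial_duration = duration, ...)
}

# a short session with one cell of each main class
quick_session <- function(duration = 300, seed = 11) {
  cfg <- quick_config(duration)
  specs <- list(cell_spec("place", peak_rate = 8, centers = c(30, 30), sigma = 8),
                cell_spec("grid", peak_rate = 10, grid_spacing = 24,
                          centers = c(30, 30)),
                cell_spec("hd", peak_rate = 10, hd_mu = 90, hd_kappa = 3),
                cell_spec("speed", peak_rate = 2, speed_slope = 0.2),
                cell_spec("uniform", peak_rate = 2))
  simulate_session(cfg, specs, seed = seed)
}

# hand-built trajectory moving at constant velocity (vx, vy), reflecting off
# walls, for exact kinematic oracles
straight_trajectory <- function(cfg, start = c(5, 30), v = c(12, 0),
                                duration = cfg$trial_duration) {
  rate <- cfg$position_rate
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  w <- cfg$arena_width
  tri <- function(z) { # reflect coordinate into [0, w]
    z <- z %% (2 * w)
    ifelse(z > w, 2 * w - z, z)
  }
  x <- tri(start[1] + v[1] * t)
  y <- tri(start[2] + v[2] * t)
  dx <- c(x[2] - x[1], diff(x)); dy <- c(y[2] - y[1], diff(y))
  rd <- (atan2(dy, dx) * 180 / pi) %% 360
  traj <- data.frame(t = t, x = x, y = y, hd = rd,
                     speed = sqrt(dx^2 + dy^2) * rate, run_dir = rd,
                     valid = TRUE)
  attr(traj, "rate") <- rate
  attr(traj, "config") <- cfg
  traj
}

# an ideal rate map object built directly from an intensity function
ideal_ratemap <- function(cfg, rate_fun) {
  geom <- spatcell:::bin_geometry(cfg)
  ctr <- geom$centers
  r <- outer(ctr, ctr, rate_fun)
  r[!geom$mask] <- NA
  structure(list(rate = r, dwell = matrix(1, geom$n, geom$n),
                 spike_count = r, sm_dwell = matrix(1, geom$n, geom$n),
                 sm_spk = r, bin_size = cfg$bin_size, centers = ctr,
                 mask = geom$mask, kernel = 1), class = "ratemap")
}

hex_rate_fun <- function(spacing, peak = 10, center = c(30, 30), orient = 0) {
  kmag <- 4 * pi / (sqrt(3) * spacing)
  function(x, y) {
    g <- 0
    for (a in orient * pi / 180 + c(0, pi / 3, 2 * pi / 3)) {
      g <- g + cos(kmag * ((x - center[1]) * cos(a + pi / 2) +
                           (y - center[2]) * sin(a + pi / 2)))
    }
    peak * pmax((g + 1.5) / 4.5, 0)
  }
}

# slow, obviously-correct Pearson autocorrelogram used as the oracle for the
# compiled kernel
autocorr_ref <- function(r, L, min_overlap) {
  nx <- nrow(r); ny <- ncol(r)
  out <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  for (dx in -L:L) for (dy in -L:L) {
    i0 <- max(1, 1 - dx); i1 <- min(nx, nx - dx)
    j0 <- max(1, 1 - dy); j1 <- min(ny, ny - dy)
    if (i0 > i1 || j0 > j1) next
    a <- r[i0:i1, j0:j1]
    b <- r[(i0 + dx):(i1 + dx), (j0 + dy):(j1 + dy)]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_overlap) next
    if (stats::sd(a[ok]) < 1e-12 || stats::sd(b[ok]) < 1e-12) next
    out[L + 1 + dx, L + 1 + dy] <- stats::cor(a[ok], b[ok])
  }
  out
}
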