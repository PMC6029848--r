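#' Parametric tuning model of a simulated cell
#'
#' Describes the firing-intensity model of one synthetic neuron. Five kinds
#' are supported: `place` (Gaussian field(s)), `grid` (rectified three-cosine
#' hexagonal lattice), `hd` (von Mises head-direction tuning), `speed`
#' (linear speed-rate coupling) and `uniform` (homogeneous Poisson).
#' Any spatial kind can carry an additional multiplicative directional gain
#' `1 + dir_mod_depth * cos(hd - dir_mod_mu)` and, when a theta LFP is
#' supplied at spike-generation time, within-field theta phase precession
#' spanning `precession_range` degrees across each field traversal.
#'
#' @param kind One of "place", "grid", "hd", "speed", "uniform".
#' @param peak_rate Peak firing rate, Hz.
#' @param centers Field centre(s), a 2-column matrix or length-2 vector (cm).
#' @param sigma Gaussian field radius, cm.
#' @param grid_spacing Hexagonal lattice spacing, cm.
#' @param grid_orientation Lattice orientation, degrees.
#' @param hd_mu,hd_kappa von Mises preferred direction (deg) and concentration.
#' @param speed_slope Rate gain, Hz per cm/s.
#' @param dir_mod_depth Directional modulation depth in `[0, 1]`.
#' @param dir_mod_mu Preferred direction of the multiplicative gain, deg.
#' @param precession_range Phase swept across a field, degrees (0 = none).
#' @param baseline_rate Additive background rate, Hz.
#' @return Object of class `cell_spec`.
#' @export
cell_spec <- function(kind = c("place", "grid", "hd", "speed", "uniform"),
                      peak_rate = 5, centers = NULL, sigma = 8,
                      grid_spacing = 30, grid_orientation = 0,
                      hd_mu = 0, hd_kappa = 4,
                      speed_slope = 0.1, dir_mod_depth = 0, dir_mod_mu = 0,
                      precession_range = 0, baseline_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(peak_rate >= 0, baseline_rate >= 0, hd_kappa >= 0,
            dir_mod_depth >= 0, dir_mod_depth <= 1, sigma > 0, grid_spacing > 0)
  if (!is.null(centers)) centers <- matrix(centers, ncol = 2)
  structure(list(kind = kind, peak_rate = peak_rate, centers = centers,
                 sigma = sigma, grid_spacing = grid_spacing,
                 grid_orientation = grid_orientation, hd_mu = hd_mu,
                 hd_kappa = hd_kappa, speed_slope = speed_slope,
                 dir_mod_depth = dir_mod_depth, dir_mod_mu = dir_mod_mu,
                 precession_range = precession_range,
                 baseline_rate = baseline_rate),
            class = "cell_spec")
}

#' VR manipulation parameters
#'
#' The set of contrasts applied to a session when it is re-simulated in
#' virtual reality: spatial tuning expansion (locational fields by
#' `scale_factor`, default 1.44; grid spacing by `grid_scale_factor`,
#' default 1.42), added place-cell directionality, reduction of the
#' theta-frequency/running-speed slope, and rotation of all spatial tuning
#' (0 or 180 degrees) emulating the cue-rotation probe.
#'
#' @param scale_factor Locational field expansion (VR sigma / R sigma).
#' @param grid_scale_factor Grid spacing expansion (VR / R).
#' @param added_dir_mod Directional modulation depth added to place cells.
#' @param theta_slope_factor Multiplier in `(0, 1]` on the LFP
#'   theta-frequency speed slope.
#' @param rotation Rotation of all spatial/directional tuning, 0 or 180 deg.
#' @return Object of class `vr_manipulation`.
#' @export
vr_manipulation <- function(scale_factor = 1.44, grid_scale_factor = 1.42,
                            added_dir_mod = 0, theta_slope_factor = 1,
                            rotation = 0) {
  stopifnot(scale_factor > 0, grid_scale_factor > 0,
            added_dir_mod >= 0, added_dir_mod <= 1,
            theta_slope_factor > 0, theta_slope_factor <= 1,
            rotation %in% c(0, 180))
  structure(list(scale_factor = scale_factor,
                 grid_scale_factor = grid_scale_factor,
                 added_dir_mod = added_dir_mod,
                 theta_slope_factor = theta_slope_factor,
                 rotation = rotation),
            class = "vr_manipulation")
}

default_centers <- function(spec, config) {
  if (!is.null(spec$centers)) return(spec$centers)
  matrix(arena_center(config), ncol = 2)
}

# hexagonal lattice node positions covering the arena (plus a margin)
grid_lattice <- function(spec, config) {
  s <- spec$grid_spacing
  th <- deg2rad(spec$grid_orientation)
  a1 <- s * c(cos(th), sin(th))
  a2 <- s * c(cos(th + pi / 3), sin(th + pi / 3))
  c0 <- default_centers(spec, config)[1, ]
  r <- arena_range(config)
  kmax <- ceiling(2 * (r[2] - r[1]) / s) + 2
  ks <- -kmax:kmax
  combos <- expand.grid(i = ks, j = ks)
  pts <- cbind(c0[1] + combos$i * a1[1] + combos$j * a2[1],
               c0[2] + combos$i * a1[2] + combos$j * a2[2])
  keep <- pts[, 1] >= r[1] - s & pts[, 1] <= r[2] + s &
          pts[, 2] >= r[1] - s & pts[, 2] <= r[2] + s
  pts[keep, , drop = FALSE]
}

# firing intensity (Hz) of a cell spec at given behavioural states
cell_rate <- function(spec, x, y, hd, speed, config) {
  base <- switch(spec$kind,
    place = {
      cs <- default_centers(spec, config)
      g <- 0
      for (k in seq_len(nrow(cs))) {
        d2 <- (x - cs[k, 1])^2 + (y - cs[k, 2])^2
        g <- g + exp(-d2 / (2 * spec$sigma^2))
      }
      spec$peak_rate * pmin(g, 1)
    },
    grid = {
      th0 <- deg2rad(spec$grid_orientation)
      c0 <- default_centers(spec, config)[1, ]
      kmag <- 4 * pi / (sqrt(3) * spec$grid_spacing)
      g <- 0
      for (a in th0 + c(0, pi / 3, 2 * pi / 3)) {
        # wave vectors normal to the three lattice axes
        g <- g + cos(kmag * ((x - c0[1]) * cos(a + pi / 2) +
                             (y - c0[2]) * sin(a + pi / 2)))
      }
      spec$peak_rate * pmax((g + 1.5) / 4.5, 0)
    },
    hd = spec$peak_rate * exp(spec$hd_kappa * (cos(deg2rad(hd - spec$hd_mu)) - 1)),
    speed = spec$peak_rate + spec$speed_slope * speed,
    uniform = rep(spec$peak_rate, length(x)))
  if (spec$dir_mod_depth > 0 && spec$kind %in% c("place", "grid", "uniform")) {
    base <- base * (1 + spec$dir_mod_depth * cos(deg2rad(hd - spec$dir_mod_mu)))
  }
  pmax(base + spec$baseline_rate, 0)
}

#' Simulate a random-foraging trajectory
#'
#' Smoothed random walk on velocity: the velocity vector relaxes toward
#' `mean_speed` along the current heading while receiving Gaussian
#' accelerations of scale `smoothness` (cm/s^2); walls reflect specularly.
#' With `smoothness = 0` the path is straight-line billiard motion at
#' constant speed. `wall_follow_bias > 0` steers headings toward the nearest
#' wall axis when close to a wall, reproducing the wall-parallel running
#' seen in head-fixed VR. Head direction equals motion direction plus small
#' wrapped-normal noise (the head is restrained to horizontal rotation).
#'
#' @param config A [session_config()].
#' @param mean_speed Target mean running speed, cm/s.
#' @param smoothness Random-acceleration scale, cm/s^2.
#' @param wall_follow_bias Wall-following tendency in `[0, 1]`.
#' @param hd_noise_sd SD of head-direction noise about motion direction, deg.
#' @param seed Integer RNG seed.
#' @return Trajectory data frame (t, x, y, hd, speed, run_dir, valid) with
#'   attributes `rate` and `config`.
#' @export
simulate_trajectory <- function(config, mean_speed = 12, smoothness = 15,
                                wall_follow_bias = 0, hd_noise_sd = 8,
                                seed = 1) {
  if (wall_follow_bias < 0 || wall_follow_bias > 1) {
    warning("wall_follow_bias clamped to [0, 1]")
    wall_follow_bias <- min(max(wall_follow_bias, 0), 1)
  }
  if (smoothness < 0) { warning("smoothness clamped to 0"); smoothness <- 0 }
  set.seed(seed)
  rate <- config$position_rate
  dt <- 1 / rate
  n <- round(config$trial_duration * rate)
  r <- arena_range(config)
  w <- config$arena_width
  relax <- 2          # 1/s, speed relaxation toward the target
  turn_sd <- deg2rad(120) * (smoothness / 15) # heading diffusion, rad/sqrt(s)
  x <- numeric(n); y <- numeric(n)
  p <- arena_center(config) + c(0.25, -0.1) * w / 2
  psi <- stats::runif(1, 0, 2 * pi)
  sp <- mean_speed
  for (i in seq_len(n)) {
    sp <- sp + relax * (mean_speed - sp) * dt + smoothness * sqrt(dt) * stats::rnorm(1)
    if (sp < 0) sp <- -sp
    if (sp > 3.5 * mean_speed) sp <- 3.5 * mean_speed
    psi <- psi + turn_sd * sqrt(dt) * stats::rnorm(1)
    if (wall_follow_bias > 0 && config$arena_shape == "square") {
      dwall <- min(p[1] - r[1], r[2] - p[1], p[2] - r[1], r[2] - p[2])
      if (dwall < 0.15 * w) {
        # steer toward the wall-parallel direction closest to current heading
        axis <- if (min(p[1] - r[1], r[2] - p[1]) < min(p[2] - r[1], r[2] - p[2]))
          pi / 2 else 0
        cand <- c(axis, axis + pi)
        tgt <- cand[which.min(abs(wrap180(rad2deg(cand - psi))))]
        psi <- psi + wall_follow_bias * 8 * dt * deg2rad(wrap180(rad2deg(tgt - psi)))
      }
    }
    p_new <- p + sp * dt * c(cos(psi), sin(psi))
    # specular reflection at the boundary
    if (config$arena_shape == "square") {
      if (p_new[1] < r[1] || p_new[1] > r[2]) {
        p_new[1] <- if (p_new[1] < r[1]) 2 * r[1] - p_new[1] else 2 * r[2] - p_new[1]
        psi <- pi - psi
      }
      if (p_new[2] < r[1] || p_new[2] > r[2]) {
        p_new[2] <- if (p_new[2] < r[1]) 2 * r[1] - p_new[2] else 2 * r[2] - p_new[2]
        psi <- -psi
      }
      p_new <- pmin(pmax(p_new, r[1]), r[2])
    } else {
      R <- w / 2
      rr <- sqrt(sum(p_new^2))
      if (rr > R) {
        nrm <- p_new / rr
        p_new <- p_new - 2 * (rr - R) * nrm
        vdir <- c(cos(psi), sin(psi))
        vdir <- vdir - 2 * sum(vdir * nrm) * nrm
        psi <- atan2(vdir[2], vdir[1])
      }
    }
    p <- p_new
    x[i] <- p[1]; y[i] <- p[2]
  }
  t <- (seq_len(n) - 1) * dt
  dx <- c(x[2] - x[1], diff(x)); dy <- c(y[2] - y[1], diff(y))
  speed <- sqrt(dx^2 + dy^2) * rate
  run_dir <- wrap360(rad2deg(atan2(dy, dx)))
  hd <- wrap360(run_dir + stats::rnorm(n, 0, hd_noise_sd))
  traj <- data.frame(t = t, x = x, y = y, hd = hd, speed = speed,
                     run_dir = run_dir, valid = TRUE)
  attr(traj, "rate") <- rate
  attr(traj, "config") <- config
  traj
}

#' Simulate a speed-coupled theta LFP
#'
#' Phase-continuous oscillation whose instantaneous frequency is
#' `base_freq + speed_slope * v(t)` (running speed linearly interpolated to
#' the LFP grid), plus Gaussian broadband noise. The generative phase and
#' frequency are attached as attributes for recovery tests.
#'
#' @param traj Trajectory supplying `v(t)`.
#' @param base_freq Theta frequency at zero speed, Hz (6-10).
#' @param speed_slope Frequency gain, Hz per cm/s.
#' @param lfp_rate Output sampling rate, Hz.
#' @param noise_sd Noise SD relative to unit oscillation amplitude.
#' @param seed Integer RNG seed.
#' @return An [lfp_signal()].
#' @export
simulate_lfp <- function(traj, base_freq = 8, speed_slope = 0.05,
                         lfp_rate = 250, noise_sd = 0.3, seed = 1) {
  stopifnot(base_freq >= 6, base_freq <= 10)
  set.seed(seed)
  dur <- traj$t[nrow(traj)] + 1 / attr(traj, "rate")
  nl <- round(dur * lfp_rate)
  tl <- (seq_len(nl) - 1) / lfp_rate
  v <- stats::approx(traj$t, traj$speed, xout = tl, rule = 2)$y
  f <- base_freq + speed_slope * v
  if (lfp_rate < 4 * max(f)) stop("lfp_rate must be at least 4x the maximum instantaneous frequency")
  ph <- cumsum(2 * pi * f / lfp_rate)
  ph <- ph - ph[1]
  sig <- cos(ph) + noise_sd * stats::rnorm(nl)
  out <- lfp_signal(sig, rate = lfp_rate)
  attr(out, "gt_phase") <- wrap360(rad2deg(ph))
  attr(out, "gt_freq") <- f
  out
}

#' Simulate an inhomogeneous-Poisson spike train
#'
#' Evaluates the cell's intensity along the trajectory and draws spikes by
#' per-sample Poisson thinning (piecewise-constant intensity, uniform
#' placement within each sample interval). If the spec requests theta phase
#' precession and an LFP is supplied, thinning instead runs on the finer LFP
#' time grid with a unit-mean von Mises gate on theta phase whose preferred
#' phase sweeps linearly from late to early across each field traversal, so
#' spikes carry the phase-position relationship exactly at emission time.
#'
#' @param traj Trajectory.
#' @param spec A [cell_spec()].
#' @param lfp Optional [simulate_lfp()] output (needed for precession).
#' @param seed Integer RNG seed.
#' @param id Cell identifier.
#' @return An annotated [spike_train()].
#' @export
simulate_spikes <- function(traj, spec, lfp = NULL, seed = 1, id = "cell") {
  config <- attr(traj, "config")
  if (is.null(config)) stop("trajectory carries no session config")
  if (!all(in_arena(config, traj$x, traj$y) | !traj$valid))
    stop("trajectory positions fall outside the spec's arena")
  set.seed(seed)
  rate <- attr(traj, "rate")
  dt <- 1 / rate
  dur <- config$trial_duration
  lam <- cell_rate(spec, traj$x, traj$y, traj$hd, traj$speed, config)
  precess <- spec$precession_range > 0 && !is.null(lfp) &&
    spec$kind %in% c("place", "grid")
  if (!precess) {
    counts <- stats::rpois(length(lam), lam * dt)
    idx <- rep.int(seq_along(counts), counts)
    st <- traj$t[idx] + stats::runif(length(idx), 0, dt)
  } else {
    st <- precessing_spike_times(traj, spec, lam, lfp, config)
  }
  st <- pmin(st, dur - 1e-9)
  annotate_spikes(spike_train(sort(st), id = id), traj)
}

# Half-maximum radius of a single firing field -- the generative "field
# edge", matching the half-peak contour used by field detection. `smooth_w`
# (cm) accounts for the map boxcar: fields are operationally defined on the
# smoothed map, whose boxcar adds w^2/12 to the field variance.
field_halfmax_radius <- function(spec, smooth_w = 0) {
  infl <- 2 * log(2) * smooth_w^2 / 12
  if (spec$kind == "place")
    return(sqrt(2 * log(2) * spec$sigma^2 + infl))
  # grid: azimuthal mean of the half-max radius of the central lattice bump
  kmag <- 4 * pi / (sqrt(3) * spec$grid_spacing)
  prof <- function(r, a) {
    g <- 0
    for (ax in c(0, pi / 3, 2 * pi / 3))
      g <- g + cos(kmag * r * cos(a - (ax + pi / 2)))
    pmax((g + 1.5) / 4.5, 0)
  }
  dirs <- seq(0, pi / 3, length.out = 13)
  r0 <- mean(vapply(dirs, function(a) {
    stats::uniroot(function(r) prof(r, a) - 0.5, c(1e-6, spec$grid_spacing / 2))$root
  }, numeric(1)))
  sqrt(r0^2 + infl)
}

# Precession mechanism: the intensity is thinned on the (fine) LFP time
# grid with a von Mises gate on LFP theta phase whose preferred phase
# regresses from late to early as the animal traverses the field. The gate
# has unit mean over phase, so the spatial rate is preserved on average,
# and each spike carries the phase-position relationship exactly at its
# emission time. Traversal coordinate: displacement from the governing
# field centre projected on the instantaneous running direction, in units
# of the half-max field radius (the operational field-edge definition).
precessing_spike_times <- function(traj, spec, lam, lfp, config,
                                   kappa = 3, zone = 1.3) {
  centers <- if (spec$kind == "place") default_centers(spec, config)
             else grid_lattice(spec, config)
  extent <- field_halfmax_radius(spec, smooth_w = 5 * config$bin_size)
  ph <- attr(lfp, "gt_phase")
  if (is.null(ph)) stop("LFP carries no generative phase; use simulate_lfp()")
  nl <- length(lfp$v)
  dtl <- 1 / lfp$rate
  tl <- (seq_len(nl) - 1) * dtl
  lam_l <- stats::approx(traj$t, lam, xout = tl, rule = 2)$y
  xl <- stats::approx(traj$t, traj$x, xout = tl, rule = 2)$y
  yl <- stats::approx(traj$t, traj$y, xout = tl, rule = 2)$y
  rd <- deg2rad(traj$run_dir)
  dl <- atan2(stats::approx(traj$t, sin(rd), xout = tl, rule = 2)$y,
              stats::approx(traj$t, cos(rd), xout = tl, rule = 2)$y)
  d2 <- outer(xl, centers[, 1], `-`)^2 + outer(yl, centers[, 2], `-`)^2
  near <- max.col(-d2)
  dx <- xl - centers[near, 1]; dy <- yl - centers[near, 2]
  # phase is governed out to just beyond the half-max edge so spikes at the
  # detected field border continue the sweep
  infield <- sqrt(dx^2 + dy^2) <= zone * extent
  proj <- (dx * cos(dl) + dy * sin(dl)) / extent
  mu <- 180 - spec$precession_range / 2 * proj
  gate <- exp(kappa * cos(deg2rad(ph - mu))) / besselI(kappa, 0)
  gate[!infield] <- 1
  counts <- stats::rpois(nl, lam_l * gate * dtl)
  idx <- rep.int(seq_len(nl), counts)
  tl[idx] + stats::runif(length(idx), 0, dtl)
}

#' Simulate a complete session
#'
#' Convenience wrapper generating a trajectory, LFP, and one spike train per
#' cell spec; generative parameters are stored in `ground_truth`.
#'
#' @param config A [session_config()].
#' @param specs List of [cell_spec()]s.
#' @param seed Integer seed; trajectory, LFP and each cell use derived seeds.
#' @param mean_speed,smoothness,wall_follow_bias Trajectory parameters.
#' @param lfp_base_freq,lfp_speed_slope,lfp_noise_sd LFP parameters.
#' @return A `spat_session`.
#' @export
simulate_session <- function(config, specs, seed = 1, mean_speed = 12,
                             smoothness = 15, wall_follow_bias = 0,
                             lfp_base_freq = 8, lfp_speed_slope = 0.05,
                             lfp_noise_sd = 0.3) {
  traj <- simulate_trajectory(config, mean_speed = mean_speed,
                              smoothness = smoothness,
                              wall_follow_bias = wall_follow_bias,
                              seed = seed)
  lfp <- simulate_lfp(traj, base_freq = lfp_base_freq,
                      speed_slope = lfp_speed_slope,
                      lfp_rate = config$lfp_rate,
                      noise_sd = lfp_noise_sd, seed = seed + 1000L)
  cells <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    cells[[k]] <- simulate_spikes(traj, specs[[k]], lfp = lfp,
                                  seed = seed + 2000L + k,
                                  id = sprintf("cell%02d", k))
  }
  gt <- list(specs = lapply(specs, unclass),
             lfp = list(base_freq = lfp_base_freq,
                        speed_slope = lfp_speed_slope),
             mean_speed = mean_speed, seed = seed)
  session(config, traj, cells, lfp, ground_truth = gt)
}

rotate_about <- function(p, center, deg) {
  th <- deg2rad(deg)
  d <- cbind(p[, 1] - center[1], p[, 2] - center[2])
  cbind(center[1] + d[, 1] * cos(th) - d[, 2] * sin(th),
        center[2] + d[, 1] * sin(th) + d[, 2] * cos(th))
}

# apply a VR manipulation to one cell spec (ground-truth transformation)
transform_spec <- function(spec, manip, config) {
  out <- spec
  cen <- arena_center(config)
  if (!is.null(out$centers))
    out$centers <- rotate_about(out$centers, cen, manip$rotation)
  if (spec$kind == "place") {
    out$sigma <- spec$sigma * manip$scale_factor
    out$dir_mod_depth <- min(spec$dir_mod_depth + manip$added_dir_mod, 1)
  }
  if (spec$kind == "grid") {
    out$grid_spacing <- spec$grid_spacing * manip$grid_scale_factor
  }
  if (spec$kind %in% c("hd", "place", "grid")) {
    out$hd_mu <- wrap360(spec$hd_mu + manip$rotation)
    out$dir_mod_mu <- wrap360(out$dir_mod_mu + manip$rotation)
  }
  out
}

#' Generate a paired real/VR session
#'
#' The same cells are simulated in a real (R) and a virtual (VR) session.
#' The VR session applies the manipulation to every cell's generative
#' parameters: place-field sigma scaled by `scale_factor`, grid spacing by
#' `grid_scale_factor`, place-cell directional modulation increased by
#' `added_dir_mod`, the LFP theta-speed slope multiplied by
#' `theta_slope_factor`, and all spatial/directional tuning rotated by
#' `rotation` about the arena centre.
#'
#' @param base_specs List of [cell_spec()]s (the R-session ground truth).
#' @param manip A [vr_manipulation()].
#' @param config_r,config_vr Session configs for the two conditions.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_session()] (trajectory/LFP parameters).
#' @param lfp_speed_slope R-session theta-frequency speed slope, Hz/(cm/s).
#' @return List with elements `r` and `vr`, both `spat_session`s.
#' @export
make_vr_pair <- function(base_specs, manip, config_r, config_vr, seed = 1,
                         lfp_speed_slope = 0.05, ...) {
  vr_specs <- lapply(base_specs, transform_spec, manip = manip,
                     config = config_vr)
  s_r <- simulate_session(config_r, base_specs, seed = seed,
                          lfp_speed_slope = lfp_speed_slope, ...)
  s_vr <- simulate_session(config_vr, vr_specs, seed = seed + 1L,
                           lfp_speed_slope = lfp_speed_slope *
                             manip$theta_slope_factor, ...)
  s_r$ground_truth$manip <- s_vr$ground_truth$manip <- unclass(manip)
  list(r = s_r, vr = s_vr)
}

#' Simulate a direction-biased loop trajectory
#'
#' Motion around a ring of radius `loop_radius` about the arena centre,
#' mostly in one rotational sense (`p_reverse` controls occasional reversed
#' laps), with Ornstein-Uhlenbeck radial jitter. Any place field lying on
#' the ring is then traversed predominantly in a single running direction,
#' the sampling bias that makes purely locational firing look directional
#' in naive tuning curves - the confound the pxd model removes.
#'
#' @param config A [session_config()].
#' @param loop_radius Ring radius, cm (default 1/3 arena width).
#' @param mean_speed Tangential speed, cm/s.
#' @param p_reverse Probability per second of leaving the preferred lap
#'   sense; the reversed sense is abandoned ten times faster, so roughly
#'   90 percent of laps run in the preferred sense.
#' @param radial_sd Radial jitter SD, cm.
#' @param hd_noise_sd Head-direction noise about motion direction, deg.
#' @param seed Integer RNG seed.
#' @return Trajectory data frame as from [simulate_trajectory()].
#' @export
simulate_loop_trajectory <- function(config, loop_radius = config$arena_width / 3,
                                     mean_speed = 12, p_reverse = 0.005,
                                     radial_sd = 3, hd_noise_sd = 8, seed = 1) {
  set.seed(seed)
  rate <- config$position_rate
  dt <- 1 / rate
  n <- round(config$trial_duration * rate)
  ctr <- arena_center(config)
  ang <- stats::runif(1, 0, 2 * pi)
  sense <- 1
  rj <- 0
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    p_sw <- if (sense > 0) p_reverse else 10 * p_reverse
    if (stats::runif(1) < p_sw * dt) sense <- -sense
    ang <- ang + sense * mean_speed / loop_radius * dt
    rj <- rj + 1.5 * (0 - rj) * dt + radial_sd * sqrt(2 * 1.5) * sqrt(dt) * stats::rnorm(1)
    rr <- loop_radius + rj
    x[i] <- ctr[1] + rr * cos(ang)
    y[i] <- ctr[2] + rr * sin(ang)
  }
  r <- arena_range(config)
  x <- pmin(pmax(x, r[1]), r[2])
  y <- pmin(pmax(y, r[1]), r[2])
  t <- (seq_len(n) - 1) * dt
  dx <- c(x[2] - x[1], diff(x)); dy <- c(y[2] - y[1], diff(y))
  speed <- sqrt(dx^2 + dy^2) * rate
  run_dir <- wrap360(rad2deg(atan2(dy, dx)))
  hd <- wrap360(run_dir + stats::rnorm(n, 0, hd_noise_sd))
  traj <- data.frame(t = t, x = x, y = y, hd = hd, speed = speed,
                     run_dir = run_dir, valid = TRUE)
  attr(traj, "rate") <- rate
  attr(traj, "config") <- config
  traj
}
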