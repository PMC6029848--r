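#' Rayleigh vector length of running direction
#'
#' Length of the resultant of unit vectors at each valid sample's running
#' direction: 0 for uniformly distributed directions, 1 when all samples
#' share one direction. Computed on the behaviourally downsampled (2.5 Hz)
#' trajectory by convention.
#'
#' @param traj Trajectory (typically from [downsample_behavior()]).
#' @return Scalar in `[0, 1]`.
#' @export
running_dir_rayleigh <- function(traj) {
  rd <- traj$run_dir[traj$valid]
  rd <- rd[is.finite(rd)]
  if (length(rd) < 2) stop("need at least 2 valid direction samples")
  resultant_length(rd)
}

#' Mean absolute change of running direction
#'
#' Mean of the absolute wrapped difference (degrees, wrap to (-180, 180])
#' of running direction between consecutive valid samples — a tortuosity
#' measure; 0 for straight paths.
#'
#' @param traj Trajectory (typically 2.5 Hz).
#' @return Mean absolute direction change, deg/sample.
#' @export
mean_abs_direction_change <- function(traj) {
  rd <- traj$run_dir
  ok <- traj$valid & is.finite(rd)
  d <- abs(wrap180(diff(rd)))
  keep <- ok[-1] & ok[-length(ok)]
  mean(d[keep], na.rm = TRUE)
}

#' Path excess ratio
#'
#' Length of the path actually taken between two reward locations divided
#' by the straight-line distance between them; 1 for a direct run, larger
#' for detours.
#'
#' @param traj Trajectory.
#' @param start,goal Length-2 reward locations, cm.
#' @param t0,t1 Start and end times of the run, s.
#' @return Ratio `>= 1` (up to sampling discretisation).
#' @export
path_excess_ratio <- function(traj, start, goal, t0, t1) {
  stopifnot(t0 < t1)
  d <- sqrt(sum((goal - start)^2))
  if (d <= 0) stop("start and goal coincide")
  sel <- traj$t >= t0 & traj$t <= t1 & traj$valid
  x <- traj$x[sel]; y <- traj$y[sel]
  if (length(x) < 2) stop("no trajectory samples in [t0, t1]")
  plen <- sum(sqrt(diff(x)^2 + diff(y)^2))
  plen / d
}

#' Quadrant dwell fractions
#'
#' Fraction of valid samples spent in each quadrant of a square arena
#' (numbered counter-clockwise from the upper-right, matching the standard
#' heat-map layout: 1 = x > w/2, y > w/2). Samples exactly on a quadrant
#' boundary go to the lower/left quadrant (half-open convention).
#'
#' @param traj Trajectory.
#' @param intervals Optional 2-column matrix of time intervals (s) to
#'   restrict to (e.g. the periods between specific rewards); NULL = whole
#'   trial.
#' @return Numeric length-4 vector of fractions summing to 1.
#' @export
quadrant_dwell <- function(traj, intervals = NULL) {
  config <- attr(traj, "config")
  if (!is.null(config) && config$arena_shape != "square")
    stop("quadrant analysis requires a square arena")
  sel <- traj$valid
  if (!is.null(intervals)) {
    intervals <- matrix(intervals, ncol = 2)
    inwin <- rep(FALSE, nrow(traj))
    for (k in seq_len(nrow(intervals)))
      inwin <- inwin | (traj$t >= intervals[k, 1] & traj$t <= intervals[k, 2])
    sel <- sel & inwin
  }
  w <- if (!is.null(config)) config$arena_width else max(traj$x, traj$y)
  mid <- w / 2
  x <- traj$x[sel]; y <- traj$y[sel]
  right <- x > mid; top <- y > mid
  q <- ifelse(right & top, 1L, ifelse(!right & top, 2L,
       ifelse(!right & !top, 3L, 4L)))
  tabulate(q, nbins = 4) / length(q)
}

#' Behavioural summary of one session
#'
#' Computes the standard behavioural battery on the 2.5 Hz downsampled
#' trajectory: mean running speed, Rayleigh vector length of running
#' direction, mean absolute running-direction change, and (square arenas)
#' quadrant dwell fractions.
#'
#' @param s A `spat_session`.
#' @return A one-row data frame.
#' @export
behavior_summary <- function(s) {
  tr <- derive_kinematics(smooth_positions(s$trajectory))
  ds <- derive_kinematics(downsample_behavior(smooth_positions(s$trajectory)))
  qd <- if (s$config$arena_shape == "square") quadrant_dwell(tr) else rep(NA_real_, 4)
  data.frame(mean_speed = mean(tr$speed[tr$valid], na.rm = TRUE),
             dir_rayleigh = running_dir_rayleigh(ds),
             mean_abs_dir_change = mean_abs_direction_change(ds),
             q1 = qd[1], q2 = qd[2], q3 = qd[3], q4 = qd[4])
}

#' Wall-parallel running fraction
#'
#' Proxy for wall-following tendency in square arenas: the fraction of
#' valid samples whose running direction lies within `tol` degrees of one
#' of the two wall axes (0/180 or 90/270). Chance level is `4 * (2 * tol)
#' / 360`.
#'
#' @param traj Trajectory.
#' @param tol Angular tolerance around a wall axis, deg.
#' @return Fraction in `[0, 1]`.
#' @export
wall_following_fraction <- function(traj, tol = 15) {
  rd <- traj$run_dir[traj$valid]
  rd <- rd[is.finite(rd)]
  dev <- abs(wrap180(outer(rd, c(0, 90, 180, 270), `-`)))
  mean(apply(dev, 1, min) <= tol)
}
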