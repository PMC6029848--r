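#' Fill short tracking gaps by linear interpolation
#'
#' Tracking losses (flagged by `valid = FALSE`) of at most `max_gap` seconds
#' are filled linearly per coordinate channel; longer gaps remain masked and
#' are excluded from all downstream analyses.
#'
#' @param traj Trajectory with a `valid` mask.
#' @param max_gap Longest gap to interpolate, s.
#' @return Trajectory with short gaps filled and re-validated.
#' @export
interpolate_gaps <- function(traj, max_gap = 0.5) {
  if (!any(traj$valid)) stop("trajectory has no valid samples")
  if (all(traj$valid)) return(traj)
  rate <- attr(traj, "rate") %||% (1 / median(diff(traj$t)))
  max_len <- floor(max_gap * rate + 1e-9)
  r <- rle(!traj$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- traj
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if ((b - a + 1) > max_len) next
    if (a == 1 || b == nrow(traj)) next # edge gaps cannot be interpolated
    for (col in c("x", "y")) {
      out[[col]][a:b] <- stats::approx(x = traj$t[c(a - 1, b + 1)],
                                       y = traj[[col]][c(a - 1, b + 1)],
                                       xout = traj$t[a:b])$y
    }
    # angles interpolated along the shorter arc
    d <- wrap180(traj$hd[b + 1] - traj$hd[a - 1])
    f <- (traj$t[a:b] - traj$t[a - 1]) / (traj$t[b + 1] - traj$t[a - 1])
    out$hd[a:b] <- wrap360(traj$hd[a - 1] + f * d)
    out$valid[a:b] <- TRUE
  }
  out
}

#' Boxcar-smooth positions
#'
#' Moving average over a `window`-second boxcar (a symmetric 21-sample
#' window for the default 0.4 s at 50 Hz, so positions acquire no phase
#' shift), applied to x and y independently; the window is truncated at
#' trial edges and at masked samples.
#'
#' @param traj Trajectory.
#' @param window Boxcar width, s.
#' @return Trajectory with smoothed x, y.
#' @export
smooth_positions <- function(traj, window = 0.4) {
  rate <- attr(traj, "rate") %||% (1 / median(diff(traj$t)))
  k <- round(window * rate)
  if (k < 1) stop("smoothing window shorter than one sample period")
  # symmetric window (odd length) so smoothing introduces no phase shift
  h1 <- h2 <- floor(k / 2)
  n <- nrow(traj)
  out <- traj
  ok <- traj$valid
  for (col in c("x", "y")) {
    z <- ifelse(ok, traj[[col]], 0)
    cz <- c(0, cumsum(z))
    cn <- c(0, cumsum(as.numeric(ok)))
    lo <- pmax(seq_len(n) - h1, 1)
    hi <- pmin(seq_len(n) + h2, n)
    s <- cz[hi + 1] - cz[lo]
    m <- cn[hi + 1] - cn[lo]
    sm <- ifelse(m > 0, s / m, NA_real_)
    out[[col]] <- ifelse(ok, sm, traj[[col]])
  }
  out
}

#' Derive speed and running direction from positions
#'
#' Speed is the per-sample displacement times the sampling rate; running
#' direction is the displacement's atan2. Both are assigned to the later
#' sample of each pair and masked when either endpoint is invalid; running
#' direction is additionally undefined (NA) when the displacement is
#' numerically zero.
#'
#' @param traj Trajectory (positions ideally smoothed first).
#' @return Trajectory with `speed` and `run_dir` recomputed.
#' @export
derive_kinematics <- function(traj) {
  rate <- attr(traj, "rate") %||% (1 / median(diff(traj$t)))
  n <- nrow(traj)
  dx <- c(NA, diff(traj$x)); dy <- c(NA, diff(traj$y))
  disp <- sqrt(dx^2 + dy^2)
  speed <- disp * rate
  rd <- wrap360(rad2deg(atan2(dy, dx)))
  rd[disp < 1e-12] <- NA_real_
  pair_ok <- c(FALSE, traj$valid[-n] & traj$valid[-1])
  speed[!pair_ok] <- NA_real_
  rd[!pair_ok] <- NA_real_
  if (n >= 2) { speed[1] <- speed[2]; rd[1] <- rd[2] }
  out <- traj
  out$speed <- speed
  out$run_dir <- rd
  out
}

#' Downsample a trajectory for behavioural metrics
#'
#' Keeps every `position_rate / rate`-th sample (2.5 Hz default, i.e. every
#' 20th sample at 50 Hz), the sampling used for running-direction
#' statistics.
#'
#' @param traj Trajectory at the full position rate.
#' @param rate Target rate, Hz; must divide the position rate.
#' @return Downsampled trajectory (attribute `rate` updated).
#' @export
downsample_behavior <- function(traj, rate = 2.5) {
  r0 <- attr(traj, "rate") %||% (1 / median(diff(traj$t)))
  step <- r0 / rate
  if (abs(step - round(step)) > 1e-9)
    stop("target rate must divide the position sampling rate")
  step <- round(step)
  if (step == 1) return(traj)
  out <- traj[seq(1, nrow(traj), by = step), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rate") <- rate
  attr(out, "config") <- attr(traj, "config")
  out
}
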