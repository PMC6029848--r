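#' Extract field traversals normalised to the unit disc
#'
#' For each detected firing field, contiguous in-field trajectory segments
#' (passes) are extracted and mapped radially onto the unit circle: the
#' proportional distance between field peak (origin) and field edge
#' (radius 1, the half-max contour) is preserved along each ray. Each pass
#' is then rotated so that its average running direction is 0 degrees
#' (left to right).
#'
#' @param traj Trajectory.
#' @param fields A `field_set` from [detect_fields()].
#' @param config Session config.
#' @param map Optional `ratemap`; when supplied, the field edge is located
#'   with sub-bin precision by marching rays of the smoothed map from the
#'   peak to the half-max crossing. Otherwise the outermost in-field bin
#'   centre per angular sector is used.
#' @param min_samples Passes shorter than this are discarded.
#' @return List of passes; each is a list with `field`, `pass`, and a data
#'   frame `samples` (t, ux, uy, dir) in the normalised frame.
#' @export
extract_passes <- function(traj, fields, config = attr(traj, "config"),
                           map = NULL, min_samples = 3) {
  geom <- bin_geometry(config)
  sid <- bin_index(traj$x, traj$y, geom)
  passes <- list()
  for (k in seq_len(nrow(fields$fields))) {
    fid <- fields$fields$id[k]
    fbins <- which(fields$labels == fid)
    # the centroid is the origin: far less noisy than the argmax bin
    peak <- c(fields$fields$center_x[k], fields$fields$center_y[k])
    edge_r <- if (is.null(map)) {
      field_edge_radii(fbins, peak, geom)
    } else {
      field_edge_radii_map(map, peak,
                           0.5 * fields$fields$peak_rate_robust[k],
                           fbins, geom)
    }
    infield <- !is.na(sid) & (sid %in% fbins) & traj$valid
    r <- rle(infield)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    pid <- 0L
    for (seg in which(r$values)) {
      a <- starts[seg]; b <- ends[seg]
      if (b - a + 1 < min_samples) next
      ix <- a:b
      dx <- traj$x[ix] - peak[1]; dy <- traj$y[ix] - peak[2]
      rr <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      er <- edge_r(wrap360(rad2deg(th)))
      rn <- pmin(rr / er, 1.2) # in-field bins may slightly overhang the contour
      rd <- traj$run_dir[ix]
      if (all(!is.finite(rd))) next
      mdir <- circ_mean_deg(rd[is.finite(rd)])
      rot <- deg2rad(-mdir)
      ux <- rn * cos(th + rot)
      uy <- rn * sin(th + rot)
      pid <- pid + 1L
      passes[[length(passes) + 1L]] <-
        list(field = fid, pass = pid,
             samples = data.frame(t = traj$t[ix], ux = ux, uy = uy,
                                  dir = wrap360(rd - mdir)))
    }
  }
  passes
}

# per-ray field edge radius (10-degree sectors; empty sectors filled by
# circular linear interpolation), returned as a lookup function of angle
field_edge_radii <- function(fbins, peak, geom) {
  bi <- ((fbins - 1) %% geom$n) + 1
  bj <- ((fbins - 1) %/% geom$n) + 1
  dx <- geom$centers[bi] - peak[1]
  dy <- geom$centers[bj] - peak[2]
  # outermost in-field bin centre per sector; the sector max is already
  # outward-biased, so no half-bin margin is added
  rr <- sqrt(dx^2 + dy^2)
  ang <- wrap360(rad2deg(atan2(dy, dx)))
  sec <- floor(ang / 10) + 1
  er <- vapply(1:36, function(ss) {
    v <- rr[sec == ss]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  if (all(is.na(er))) er[] <- geom$bin_size
  if (any(is.na(er))) {
    cen <- (1:36 - 0.5) * 10
    known <- which(!is.na(er))
    er <- stats::approx(x = c(cen[known] - 360, cen[known], cen[known] + 360),
                        y = rep(er[known], 3), xout = cen)$y
  }
  er <- boxcar_circ(er, 5) # tame bin-noise dips in the contour
  function(a) er[pmin(floor(wrap360(a) / 10) + 1, 36)]
}

# sub-bin field edge: along each ray from the peak, the first half-max
# crossing of the bilinearly interpolated smoothed map
field_edge_radii_map <- function(map, peak, thr, fbins, geom) {
  bi <- ((fbins - 1) %% geom$n) + 1
  bj <- ((fbins - 1) %/% geom$n) + 1
  max_r <- sqrt(max((geom$centers[bi] - peak[1])^2 +
                    (geom$centers[bj] - peak[2])^2)) + 2 * geom$bin_size
  step <- geom$bin_size / 4
  rr <- seq(step, max_r, by = step)
  angs <- (1:72 - 0.5) * 5
  er <- vapply(angs, function(a) {
    th <- deg2rad(a)
    v <- bilinear_rate(map, peak[1] + rr * cos(th), peak[2] + rr * sin(th))
    # carry the last finite value across isolated unvisited-bin holes
    fin <- is.finite(v)
    if (!any(fin)) return(step / 2)
    locf <- cummax(ifelse(fin, seq_along(v), 0L))
    v <- ifelse(locf > 0, v[pmax(locf, 1)], v[which(fin)[1]])
    below <- which(v < thr)
    if (!length(below)) return(max_r)
    i <- below[1]
    if (i == 1) return(step / 2)
    f <- (v[i - 1] - thr) / max(v[i - 1] - v[i], 1e-12)
    r_first <- rr[i - 1] + min(max(f, 0), 1) * step
    # first passage under noise is inward-biased; averaging with the last
    # above-threshold radius symmetrises the crossing estimate
    j <- max(which(v >= thr))
    r_last <- rr[min(j + 1, length(rr))]
    (r_first + r_last) / 2
  }, numeric(1))
  er <- boxcar_circ(er, 5)
  function(a) er[pmin(floor(wrap360(a) / 5) + 1, 72)]
}

bilinear_rate <- function(map, x, y) {
  ctr <- map$centers
  bs <- map$bin_size
  n <- length(ctr)
  gx <- (x - ctr[1]) / bs
  gy <- (y - ctr[1]) / bs
  x0 <- pmin(pmax(floor(gx), 0), n - 2)
  y0 <- pmin(pmax(floor(gy), 0), n - 2)
  fx <- pmin(pmax(gx - x0, 0), 1)
  fy <- pmin(pmax(gy - y0, 0), 1)
  r <- map$rate
  v <- cbind(r[cbind(x0 + 1, y0 + 1)], r[cbind(x0 + 2, y0 + 1)],
             r[cbind(x0 + 1, y0 + 2)], r[cbind(x0 + 2, y0 + 2)])
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  w[!is.finite(v)] <- 0 # renormalise over finite corners
  v[!is.finite(v)] <- 0
  out <- rowSums(v * w) / rowSums(w)
  out[rowSums(w) == 0] <- NaN
  out
}

#' Per-spike distance through field and theta phase
#'
#' For spikes within one pass, computes pdcd — the normalised position
#' projected onto the instantaneous running direction, the signed distance
#' the animal has travelled through the field, in `[-1, 1]` (-1 entering
#' edge, 0 peak, +1 exiting edge) — and, when a theta signal is given, the
#' spike theta phase.
#'
#' @param pass One element of [extract_passes()].
#' @param spike_times Spike times, s.
#' @param theta Optional `theta_signal` for per-spike phase.
#' @return Data frame (pdcd, phase, field, pass), one row per in-pass
#'   spike; spikes at samples with undefined running direction are
#'   dropped.
#' @export
compute_pdcd <- function(pass, spike_times, theta = NULL) {
  sm <- pass$samples
  st <- spike_times[spike_times >= sm$t[1] & spike_times <= sm$t[nrow(sm)]]
  if (!length(st))
    return(data.frame(pdcd = numeric(0), phase = numeric(0),
                      field = integer(0), pass = integer(0)))
  ux <- stats::approx(sm$t, sm$ux, xout = st)$y
  uy <- stats::approx(sm$t, sm$uy, xout = st)$y
  ni <- nearest_sample(st, sm$t)
  dir <- sm$dir[ni]
  keep <- is.finite(dir)
  th <- deg2rad(dir[keep])
  pdcd <- ux[keep] * cos(th) + uy[keep] * sin(th)
  ph <- if (is.null(theta)) rep(NA_real_, sum(keep))
        else theta_phase_at(theta, st[keep])
  data.frame(pdcd = pdcd, phase = ph,
             field = pass$field, pass = pass$pass)
}

#' Circular-linear regression of phase on pdcd
#'
#' Fits phase = slope * pdcd + offset by maximising the resultant length
#' of the phase residuals over a bounded slope range (circular-linear
#' regression), and reports the circular-linear correlation between phase
#' and the fitted linear predictor with a permutation p-value.
#'
#' @param samples Data frame with `pdcd` and `phase` (deg) columns, e.g.
#'   pooled [compute_pdcd()] output.
#' @param slope_bounds Slope search range, deg per pdcd unit.
#' @param n_perm Permutations for the p-value.
#' @param n_boot Bootstrap resamples for the slope 95 percent CI.
#' @param min_spikes Fits with fewer samples return NaN.
#' @param seed Integer RNG seed.
#' @return Object of class `precession_fit`: `slope` (deg/pdcd unit),
#'   `slope_ci95`, `offset` (deg), `circ_lin_r`, `p`, `n_spikes`.
#' @export
fit_precession <- function(samples, slope_bounds = c(-720, 720),
                           n_perm = 100, n_boot = 100, min_spikes = 30,
                           seed = 1) {
  ok <- is.finite(samples$pdcd) & is.finite(samples$phase)
  x <- samples$pdcd[ok]
  ph <- deg2rad(samples$phase[ok])
  n <- length(x)
  if (n < min_spikes) {
    return(structure(list(slope = NaN, slope_ci95 = c(NaN, NaN), offset = NaN,
                          circ_lin_r = NaN, p = NaN, n_spikes = n),
                     class = "precession_fit"))
  }
  fit_slope <- function(phv, xv, step = 2) {
    R_of <- function(s) {
      res <- phv - deg2rad(s) * xv
      sqrt(mean(cos(res))^2 + mean(sin(res))^2)
    }
    # grid search by incremental complex rotation: advancing the slope by
    # `step` multiplies each residual phasor by a fixed per-sample rotor
    sgrid <- seq(slope_bounds[1], slope_bounds[2], by = step)
    u <- exp(1i * (phv - deg2rad(sgrid[1]) * xv))
    w <- exp(-1i * deg2rad(step) * xv)
    Rg <- numeric(length(sgrid))
    for (j in seq_along(sgrid)) {
      Rg[j] <- Mod(mean(u))
      u <- u * w
    }
    s0 <- sgrid[which.max(Rg)]
    stats::optimize(R_of, interval = c(s0 - step, s0 + step),
                    maximum = TRUE)$maximum
  }
  slope <- fit_slope(ph, x)
  res <- ph - deg2rad(slope) * x
  offset <- wrap360(rad2deg(atan2(mean(sin(res)), mean(cos(res)))))
  # correlate phase with |slope| x so the sign of r reflects the direction
  # of the phase shift (negative r = precession)
  r_obs <- circ_lin_corr(ph, deg2rad(abs(slope)) * x)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    php <- ph[sample.int(n)]
    sp <- fit_slope(php, x, step = 8)
    abs(circ_lin_corr(php, deg2rad(abs(sp)) * x))
  }, numeric(1))
  p <- (sum(perm >= abs(r_obs)) + 1) / (n_perm + 1)
  boot <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, replace = TRUE)
    fit_slope(ph[ix], x[ix], step = 4)
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(slope = slope, slope_ci95 = ci, offset = offset,
                 circ_lin_r = r_obs, p = p, n_spikes = n),
            class = "precession_fit")
}

#' @export
print.precession_fit <- function(x, ...) {
  cat(sprintf("<precession_fit> slope %.1f deg/pdcd, offset %.1f deg, r = %.3f (p = %.3g, n = %d)\n",
              x$slope, x$offset, x$circ_lin_r, x$p, x$n_spikes))
  invisible(x)
}

# circular-circular correlation between phase and fitted phase predictor
circ_lin_corr <- function(phi, psi) {
  mphi <- atan2(mean(sin(phi)), mean(cos(phi)))
  mpsi <- atan2(mean(sin(psi)), mean(cos(psi)))
  num <- sum(sin(phi - mphi) * sin(psi - mpsi))
  den <- sqrt(sum(sin(phi - mphi)^2) * sum(sin(psi - mpsi)^2))
  if (den < 1e-12) return(0)
  num / den
}

#' Two-dimensional theta phase precession of one cell
#'
#' Full pipeline: rate map, field detection, pass extraction and
#' normalisation, per-spike pdcd and theta phase, and a pooled
#' circular-linear fit across all fields of the cell.
#'
#' @param s A `spat_session` (must carry an LFP).
#' @param cell Cell index.
#' @param theta Optional precomputed `theta_signal`.
#' @param min_peak_rate Field-detection seed threshold, Hz.
#' @param ... Passed to [fit_precession()].
#' @return A `precession_fit` with the pooled samples in attribute
#'   `samples`.
#' @export
phase_precession <- function(s, cell = 1, theta = NULL, min_peak_rate = 1,
                             ...) {
  if (is.null(s$lfp) && is.null(theta)) stop("session has no LFP")
  theta <- theta %||% instantaneous_theta(s$lfp)
  spikes <- s$cells[[cell]]
  rm_ <- make_ratemap(s$trajectory, spikes, s$config)
  fs <- detect_fields(rm_, min_peak_rate = min_peak_rate)
  passes <- extract_passes(s$trajectory, fs, s$config, map = rm_)
  samp <- do.call(rbind, lapply(passes, compute_pdcd,
                                spike_times = spikes$t, theta = theta))
  if (is.null(samp)) samp <- data.frame(pdcd = numeric(0), phase = numeric(0),
                                        field = integer(0), pass = integer(0))
  fit <- fit_precession(samp, ...)
  attr(fit, "samples") <- samp
  fit
}
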