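# Spatial binning shared by rate maps and the shuffle classifiers.
# Returns per-sample bin index (column-major on an nx-by-nx grid) and grid
# geometry; samples outside the arena (possible after interpolation) get NA.
bin_geometry <- function(config) {
  nb <- n_bins(config)
  r <- arena_range(config)
  ctr <- (seq_len(nb) - 0.5) * config$bin_size + r[1]
  mask <- matrix(TRUE, nb, nb)
  if (config$arena_shape == "cylinder") {
    R <- config$arena_width / 2
    mask <- outer(ctr, ctr, function(x, y) x^2 + y^2 <= R^2)
  }
  list(n = nb, range = r, centers = ctr, mask = mask,
       bin_size = config$bin_size)
}

bin_index <- function(x, y, geom) {
  bx <- floor((x - geom$range[1]) / geom$bin_size) + 1
  by <- floor((y - geom$range[1]) / geom$bin_size) + 1
  bx <- pmin(pmax(bx, 1), geom$n)
  by <- pmin(pmax(by, 1), geom$n)
  id <- bx + (by - 1) * geom$n
  id[!geom$mask[cbind(bx, by)]] <- NA_integer_
  as.integer(id)
}

#' Locational firing-rate map
#'
#' Bins positions into `bin_size` square bins (1.5 cm default), assigns
#' spikes to bins via their annotated nearest position sample, smooths the
#' spike and dwell maps separately with a truncated, renormalised `kernel` x
#' `kernel` boxcar (mass-conserving, so smoothing preserves total spike
#' count and total dwell), and divides. Bins never visited are NaN.
#'
#' @param traj Trajectory.
#' @param spikes Annotated `spike_train`.
#' @param config Session config (defaults to the trajectory's).
#' @param kernel Boxcar side in bins (odd); 1 disables smoothing.
#' @return Object of class `ratemap`: list with `rate`, `dwell`,
#'   `spike_count` (unsmoothed), smoothed components, `bin_size`, `centers`.
#' @export
make_ratemap <- function(traj, spikes, config = attr(traj, "config"),
                         kernel = 5) {
  if (is.null(config)) stop("no session config available")
  if (!nrow(traj)) stop("empty trajectory")
  geom <- bin_geometry(config)
  dt <- 1 / (attr(traj, "rate") %||% config$position_rate)
  sid <- bin_index(traj$x, traj$y, geom)
  ok <- traj$valid & !is.na(sid)
  nb2 <- geom$n^2
  dwell <- matrix(tabulate(sid[ok], nbins = nb2) * dt, geom$n, geom$n)
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, traj)
  sp_ok <- spikes$ann$valid & ok[spikes$ann$sample]
  sp_bin <- sid[spikes$ann$sample[sp_ok]]
  spk <- matrix(tabulate(sp_bin, nbins = nb2), geom$n, geom$n)
  sm_dwell <- boxcar2d_mass(dwell, kernel, geom$mask)
  sm_spk <- boxcar2d_mass(spk, kernel, geom$mask)
  rate <- sm_spk / sm_dwell
  rate[dwell == 0] <- NA_real_
  rate[!geom$mask] <- NA_real_
  structure(list(rate = rate, dwell = dwell, spike_count = spk,
                 sm_dwell = sm_dwell, sm_spk = sm_spk,
                 bin_size = config$bin_size, centers = geom$centers,
                 mask = geom$mask, kernel = kernel),
            class = "ratemap")
}

#' @export
print.ratemap <- function(x, ...) {
  cat(sprintf("<ratemap> %dx%d bins of %g cm, peak %.2f Hz, %d spikes\n",
              nrow(x$rate), ncol(x$rate), x$bin_size,
              suppressWarnings(max(x$rate, na.rm = TRUE)), sum(x$spike_count)))
  invisible(x)
}

#' @export
plot.ratemap <- function(x, ...) {
  graphics::image(x$centers, x$centers, x$rate, asp = 1,
                  xlab = "x (cm)", ylab = "y (cm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Directional tuning curve
#'
#' Firing rate versus head direction: spike counts and occupancy binned at
#' `bin` degrees, each smoothed with a small circular boxcar, then divided.
#'
#' @param traj Trajectory.
#' @param spikes Annotated `spike_train`.
#' @param bin Directional bin width, deg (must divide 360).
#' @param kernel Circular boxcar length in bins (odd); 1 disables smoothing.
#' @param use Which per-spike angle to bin: head direction (`"hd"`, default)
#'   or running direction.
#' @return Object of class `dir_tuning`: `rate`, `occupancy` (s),
#'   `spike_count`, `bin_width`, `centers` (deg).
#' @export
make_dir_tuning <- function(traj, spikes, bin = 6, kernel = 5,
                            use = c("hd", "run_dir")) {
  use <- match.arg(use)
  nbd <- round(360 / bin)
  if (abs(nbd * bin - 360) > 1e-9) stop("bin width must divide 360 degrees")
  ang <- traj[[use]]
  ok <- traj$valid & is.finite(ang)
  if (!any(ok)) stop("no valid direction samples")
  dt <- 1 / (attr(traj, "rate") %||% (1 / stats::median(diff(traj$t))))
  db <- pmin(floor(wrap360(ang) / bin) + 1, nbd)
  occ <- tabulate(db[ok], nbins = nbd) * dt
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, traj)
  sp_ok <- spikes$ann$valid & ok[spikes$ann$sample]
  spk <- tabulate(db[spikes$ann$sample[sp_ok]], nbins = nbd)
  sm_occ <- boxcar_circ(occ, kernel)
  sm_spk <- boxcar_circ(spk, kernel)
  rate <- ifelse(sm_occ > 0, sm_spk / sm_occ, NA_real_)
  structure(list(rate = rate, occupancy = occ, spike_count = spk,
                 sm_occ = sm_occ, bin_width = bin,
                 centers = (seq_len(nbd) - 0.5) * bin),
            class = "dir_tuning")
}

#' @export
print.dir_tuning <- function(x, ...) {
  cat(sprintf("<dir_tuning> %d bins of %g deg, peak %.2f Hz, Rayleigh %.3f\n",
              length(x$rate), x$bin_width,
              suppressWarnings(max(x$rate, na.rm = TRUE)), rayleigh_vector(x)))
  invisible(x)
}

#' Detect firing fields on a smoothed rate map
#'
#' Two related outputs: `area_frac`, the fraction of arena bins with firing
#' above `threshold_frac` of the map peak (the field-size measure), and a
#' per-field segmentation. Fields are grown around local maxima in
#' descending peak order; each field is the connected component of
#' yet-unlabelled bins at or above `threshold_frac` of its own peak, so ties
#' go to the higher peak.
#'
#' @param map A `ratemap`.
#' @param threshold_frac Fraction of peak defining a field, default 0.5.
#' @param min_peak_rate Local maxima below this rate (Hz) do not seed fields.
#' @param min_peak_frac Local maxima below this fraction of the global map
#'   peak do not seed fields (suppresses noise blobs).
#' @param min_bins Fields smaller than this many bins are discarded.
#' @return Object of class `field_set`: `labels` (integer matrix, 0 =
#'   background), `fields` data frame (id, peak_x, peak_y, peak_rate,
#'   n_bins, area_frac), and scalar `area_frac`.
#' @export
detect_fields <- function(map, threshold_frac = 0.5, min_peak_rate = 1,
                          min_peak_frac = 0.2, min_bins = 5) {
  r <- map$rate
  if (all(!is.finite(r))) stop("all-NaN rate map")
  n_arena <- sum(map$mask)
  pk <- max(r, na.rm = TRUE)
  area_frac <- sum(r >= threshold_frac * pk, na.rm = TRUE) / n_arena
  nx <- nrow(r); ny <- ncol(r)
  fin <- is.finite(r)
  # 3x3-neighbourhood local maxima
  is_max <- fin & r >= pmax(min_peak_rate, min_peak_frac * pk, 1e-12)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, nx, ny)
    si <- max(1, 1 + di):min(nx, nx + di)
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    shifted[si, sj] <- r[si - di, sj - dj]
    shifted[!is.finite(shifted)] <- -Inf
    is_max <- is_max & (r >= shifted)
  }
  peaks <- which(is_max)
  peaks <- peaks[order(r[peaks], decreasing = TRUE)]
  labels <- matrix(0L, nx, ny)
  rows <- list()
  fid <- 0L
  # robust local peak: mean over the finite 3x3 neighbourhood, immune to
  # the upward selection bias of a single max bin
  robust_peak <- function(p) {
    pi <- ((p - 1L) %% nx) + 1L
    pj <- ((p - 1L) %/% nx) + 1L
    nb <- r[max(1, pi - 1):min(nx, pi + 1), max(1, pj - 1):min(ny, pj + 1)]
    mean(nb[is.finite(nb)])
  }
  for (p in peaks) {
    if (labels[p] != 0L) next
    thr <- threshold_frac * robust_peak(p)
    # breadth-first growth over 4-connected, unlabelled, above-threshold bins
    comp <- integer(0)
    frontier <- p
    labels[p] <- -1L
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nb <- c(frontier - 1L, frontier + 1L, frontier - nx, frontier + nx)
      ii <- ((frontier - 1L) %% nx) + 1L
      nb_ok <- c(ii > 1L, ii < nx, frontier > nx, frontier <= nx * (ny - 1L))
      nb <- nb[nb_ok]
      nb <- unique(nb[labels[nb] == 0L & fin[nb] & r[nb] >= thr])
      labels[nb] <- -1L
      frontier <- nb
    }
    if (length(comp) < min_bins) { labels[comp] <- -2L; next }
    # shoulders of an already-claimed field (adjacent components) are not
    # separate fields
    ri <- ((comp - 1L) %% nx) + 1L
    nb_all <- c(comp[ri > 1L] - 1L, comp[ri < nx] + 1L,
                comp[comp > nx] - nx, comp[comp <= nx * (ny - 1L)] + nx)
    if (any(labels[nb_all] > 0L)) { labels[comp] <- -2L; next }
    fid <- fid + 1L
    labels[comp] <- fid
    pi <- ((p - 1L) %% nx) + 1L
    pj <- ((p - 1L) %/% nx) + 1L
    # rate-weighted centroid: a sub-bin field centre much less noisy than
    # the argmax bin
    ci <- ((comp - 1L) %% nx) + 1L
    cj <- ((comp - 1L) %/% nx) + 1L
    wts <- r[comp]
    rows[[fid]] <- data.frame(id = fid,
                              peak_x = map$centers[pi],
                              peak_y = map$centers[pj],
                              center_x = sum(map$centers[ci] * wts) / sum(wts),
                              center_y = sum(map$centers[cj] * wts) / sum(wts),
                              peak_rate = r[p],
                              peak_rate_robust = robust_peak(p),
                              n_bins = length(comp),
                              area_frac = length(comp) / n_arena)
  }
  labels[labels < 0L] <- 0L
  structure(list(labels = labels,
                 fields = if (fid) do.call(rbind, rows) else
                   data.frame(id = integer(0), peak_x = numeric(0),
                              peak_y = numeric(0), center_x = numeric(0),
                              center_y = numeric(0), peak_rate = numeric(0),
                              peak_rate_robust = numeric(0),
                              n_bins = integer(0), area_frac = numeric(0)),
                 area_frac = area_frac, bin_size = map$bin_size,
                 centers = map$centers),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %d fields, half-peak area fraction %.3f\n",
              nrow(x$fields), x$area_frac))
  invisible(x)
}

#' Spatial autocorrelogram
#'
#' Pearson correlation of the rate map with itself at every integer-bin
#' offset, computed over the bins finite in both copies; offsets with fewer
#' than `min_overlap` overlapping bins are NaN. The correlogram is 1 at zero
#' offset and point-symmetric.
#'
#' @param map A `ratemap` (or a bare numeric matrix).
#' @param max_lag Largest offset in bins (default: full map extent).
#' @param min_overlap Minimum overlapping finite bins per offset.
#' @return Object of class `correlogram`: `ac` matrix of size
#'   `(2*max_lag+1)^2`, `bin_size`, `max_lag`.
#' @export
spatial_autocorr <- function(map, max_lag = NULL, min_overlap = 20) {
  r <- if (inherits(map, "ratemap")) map$rate else map
  bs <- if (inherits(map, "ratemap")) map$bin_size else 1
  fin <- is.finite(r)
  v <- stats::var(r[fin])
  if (!is.finite(v) || v < 1e-15) {
    warning("degenerate (constant) rate map; correlogram is NaN")
    ml <- max_lag %||% (max(dim(r)) - 1)
    return(structure(list(ac = matrix(NaN, 2 * ml + 1, 2 * ml + 1),
                          bin_size = bs, max_lag = ml),
                     class = "correlogram"))
  }
  ml <- max_lag %||% (max(dim(r)) - 1)
  ac <- autocorr_cpp(r, as.integer(ml), as.integer(min_overlap))
  structure(list(ac = ac, bin_size = bs, max_lag = ml),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> lags to %d bins (%g cm)\n",
              x$max_lag, x$max_lag * x$bin_size))
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  lag <- (-x$max_lag:x$max_lag) * x$bin_size
  graphics::image(lag, lag, x$ac, asp = 1, xlab = "lag (cm)",
                  ylab = "lag (cm)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}
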