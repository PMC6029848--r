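#' Time-shift shuffle of a spike train
#'
#' The standard null for spatial tuning: all spike times are rigidly
#' offset by a single uniform draw from `[min_offset, T - min_offset]` and
#' wrapped modulo the trial duration, preserving the spike count and the
#' inter-spike-interval structure (up to one wrap point) while destroying
#' the spike-position relationship. Annotations are recomputed against the
#' unshifted trajectory.
#'
#' @param spikes A `spike_train`.
#' @param traj Trajectory.
#' @param min_offset Minimum offset, s (default 4).
#' @param seed Integer RNG seed.
#' @param offset Explicit offset (overrides the random draw).
#' @return A shuffled, annotated `spike_train`.
#' @export
shuffle_spikes <- function(spikes, traj, min_offset = 4, seed = 1,
                           offset = NULL) {
  config <- attr(traj, "config")
  dur <- if (!is.null(config)) config$trial_duration
         else traj$t[nrow(traj)] + diff(traj$t[1:2])
  if (dur <= 2 * min_offset) stop("trial too short for the minimum shuffle offset")
  if (is.null(offset)) {
    set.seed(seed)
    offset <- stats::runif(1, min_offset, dur - min_offset)
  }
  st <- sort((spikes$t + offset) %% dur)
  annotate_spikes(spike_train(st, id = spikes$id), traj)
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf("<shuffle_result> %s: observed %.4f vs 99th pct %.4f (%d shuffles) -> %s\n",
              x$statistic, x$observed, x$percentile_99, length(x$null_values),
              if (isTRUE(x$passes)) "PASS" else "fail"))
  invisible(x)
}

shuffle_result <- function(statistic, observed, null_values, passes,
                           extra = list()) {
  structure(c(list(statistic = statistic, observed = observed,
                   null_values = null_values,
                   percentile_99 = stats::quantile(null_values, 0.99,
                                                   names = FALSE, na.rm = TRUE),
                   passes = passes), extra),
            class = "shuffle_result")
}

# Shared per-session precomputation for the shuffle classifiers.
classify_context <- function(s, kernel = 5) {
  cfg <- s$config
  traj <- s$trajectory
  geom <- bin_geometry(cfg)
  rate <- attr(traj, "rate") %||% cfg$position_rate
  dt <- 1 / rate
  sid <- bin_index(traj$x, traj$y, geom)
  ok <- traj$valid & !is.na(sid)
  nb2 <- geom$n^2
  dwell <- tabulate(sid[ok], nbins = nb2) * dt
  K <- boxcar_operator(geom$n, geom$n, kernel, geom$mask)
  sm_dwell <- as.vector(dwell %*% K)
  nbd <- round(360 / cfg$dir_bin)
  db <- pmin(floor(wrap360(traj$hd) / cfg$dir_bin) + 1, nbd)
  ok_d <- traj$valid & is.finite(traj$hd)
  occ_d <- tabulate(db[ok_d], nbins = nbd) * dt
  sm_occ <- boxcar_circ(occ_d, kernel)
  list(cfg = cfg, geom = geom, rate = rate, dt = dt, n_samp = nrow(traj),
       sid = sid, ok = ok, dwell = dwell, sm_dwell = sm_dwell, K = K,
       nbd = nbd, db = db, ok_d = ok_d, occ_d = occ_d, sm_occ = sm_occ,
       kernel = kernel, total_time = sum(dwell))
}

# uniform shuffle offsets in samples; first entry is the unshifted observed
shuffle_shifts <- function(ctx, n_shuffles, min_offset, seed) {
  dur <- ctx$cfg$trial_duration
  if (dur <= 2 * min_offset) stop("trial too short for the minimum shuffle offset")
  set.seed(seed)
  off <- stats::runif(n_shuffles, min_offset, dur - min_offset)
  c(0L, as.integer(round(off * ctx$rate)))
}

# sparse (n_shifts x n_bins) matrix of binned spike counts under circular
# sample shifts; bin assignment and validity are those of the unshifted
# trajectory at the landing sample
shifted_counts <- function(ctx, spikes, shifts, what = c("space", "dir")) {
  what <- match.arg(what)
  if (is.null(spikes$ann)) stop("spikes must be annotated")
  sidx <- spikes$ann$sample
  src <- (outer(sidx - 1L, shifts, `+`) %% ctx$n_samp) + 1L
  nshift <- length(shifts)
  row <- rep(seq_len(nshift), each = length(sidx))
  if (what == "space") {
    bin <- ctx$sid[src]
    keep <- ctx$ok[src]
    nb <- ctx$geom$n^2
  } else {
    bin <- ctx$db[src]
    keep <- ctx$ok_d[src]
    nb <- ctx$nbd
  }
  keep <- keep & !is.na(bin)
  Matrix::sparseMatrix(i = row[keep], j = bin[keep], x = 1,
                       dims = c(nshift, nb))
}

# Skaggs information per row of a smoothed spike-map matrix:
# sum_k (m/S) log2(m D / (d S)) expanded to avoid large temporaries
batch_spatial_info <- function(sm_spk, sm_dwell, total_time) {
  use <- sm_dwell > 0
  m <- sm_spk[, use, drop = FALSE]
  d <- sm_dwell[use]
  S <- rowSums(m)
  mlm <- m * log2(m)
  mlm[!is.finite(mlm)] <- 0
  (rowSums(mlm) - as.vector(m %*% log2(d))) / S + log2(total_time / S)
}

low_count_result <- function(statistic, n) {
  shuffle_result(statistic, NA_real_, NA_real_, NA,
                 extra = list(low_count = TRUE, n_spikes = n))
}

#' Classify a place cell by spatial-information shuffling
#'
#' A cell passes if its spatial information exceeds the 99th percentile of
#' the spatial information of `n_shuffles` time-shift shuffled copies
#' (offsets of at least `min_offset` s), and its smoothed-map peak rate
#' exceeds `peak_criterion` Hz.
#'
#' @param s A `spat_session`.
#' @param cell Cell index.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param min_offset Minimum time shift, s.
#' @param peak_criterion Peak-rate requirement, Hz.
#' @param min_spikes Below this spike count the cell is flagged
#'   `low_count` and not classified.
#' @param seed Integer RNG seed.
#' @param ctx Internal precomputed context (optional).
#' @param sm Precomputed smoothed shuffle spike-map matrix (internal).
#' @return A `shuffle_result`.
#' @export
classify_place <- function(s, cell = 1, n_shuffles = 1000, min_offset = 4,
                           peak_criterion = 2, min_spikes = 100, seed = 1,
                           ctx = NULL, sm = NULL) {
  ctx <- ctx %||% classify_context(s)
  spikes <- s$cells[[cell]]
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, s$trajectory)
  if (length(spikes$t) < min_spikes)
    return(low_count_result("spatial_info", length(spikes$t)))
  if (is.null(sm)) {
    shifts <- shuffle_shifts(ctx, n_shuffles, min_offset, seed)
    sm <- as.matrix(shifted_counts(ctx, spikes, shifts) %*% ctx$K)
  }
  info <- batch_spatial_info(sm, ctx$sm_dwell, ctx$total_time)
  peak <- max(sm[1, ctx$sm_dwell > 0] / ctx$sm_dwell[ctx$sm_dwell > 0])
  obs <- info[1]; null <- info[-1]
  thr <- stats::quantile(null, 0.99, names = FALSE, na.rm = TRUE)
  shuffle_result("spatial_info", obs, null,
                 passes = is.finite(obs) && obs > thr && peak > peak_criterion,
                 extra = list(peak_rate = peak))
}

#' Classify a grid cell by gridness shuffling
#'
#' As [classify_place()], with the gridness score of the spatial
#' autocorrelogram as the statistic (and the same peak-rate criterion).
#' Correlograms of the observed and shuffled maps are computed from the
#' smoothed rate estimate over all bins with smoothed dwell so that every
#' map shares a common support.
#'
#' @inheritParams classify_place
#' @param max_lag Correlogram window in bins (default: 60 percent of the
#'   arena's bin count).
#' @return A `shuffle_result`.
#' @export
classify_grid <- function(s, cell = 1, n_shuffles = 1000, min_offset = 4,
                          peak_criterion = 2, min_spikes = 100, seed = 1,
                          max_lag = NULL, ctx = NULL, sm = NULL) {
  ctx <- ctx %||% classify_context(s)
  spikes <- s$cells[[cell]]
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, s$trajectory)
  if (length(spikes$t) < min_spikes)
    return(low_count_result("gridness", length(spikes$t)))
  nb <- ctx$geom$n
  L <- max_lag %||% floor(0.6 * nb)
  if (is.null(sm)) {
    shifts <- shuffle_shifts(ctx, n_shuffles, min_offset, seed)
    sm <- as.matrix(shifted_counts(ctx, spikes, shifts) %*% ctx$K)
  }
  peak <- max(sm[1, ctx$sm_dwell > 0] / ctx$sm_dwell[ctx$sm_dwell > 0])
  dpos <- ctx$sm_dwell > 0
  rates <- sweep(sm[, dpos, drop = FALSE], 2, ctx$sm_dwell[dpos], `/`)
  if (all(dpos) && all(ctx$geom$mask)) {
    gvals <- gridness_batch(t(rates), nb, nb, L)
  } else {
    # masked support (cylinders, incomplete coverage): plain per-map path
    gvals <- apply(rates, 1, function(rv) {
      full <- rep(NA_real_, nb * nb)
      full[dpos] <- rv
      ac <- autocorr_cpp(matrix(full, nb, nb), as.integer(L), 20L)
      gridness_core(ac, L)$gridness
    })
  }
  obs <- gvals[1]; null <- gvals[-1]
  thr <- stats::quantile(null, 0.99, names = FALSE, na.rm = TRUE)
  shuffle_result("gridness", obs, null,
                 passes = is.finite(obs) && obs > thr && peak > peak_criterion,
                 extra = list(peak_rate = peak))
}

# R-side wrapper assembling the precomputed geometry for the C++ batch
# gridness kernel; maps is (n_bins x n_maps), every entry finite
gridness_batch <- function(maps, nx, ny, L) {
  g <- gridness_geom(L)
  n <- 2 * L + 1
  dxs <- ((g$idx - 1) %% n) - L
  dys <- ((g$idx - 1) %/% n) - L
  ring <- g$ring[g$idx]
  rp <- lapply(g$W, function(W) {
    Wt <- methods::as(W, "RsparseMatrix") # row-compressed
    list(p = Wt@p, j = Wt@j, x = Wt@x)
  })
  gridness_batch_cpp(maps, as.integer(nx), as.integer(ny), as.integer(L),
                     as.integer(dxs), as.integer(dys), g$rr,
                     as.integer(ring),
                     lapply(rp, `[[`, "p"), lapply(rp, `[[`, "j"),
                     lapply(rp, `[[`, "x"), 0.2, 30L)
}

#' Classify a head-direction cell by Rayleigh-vector shuffling
#'
#' The statistic is the Rayleigh vector length of the directional tuning
#' curve. With `mode = "population"` (default) the shuffled statistics of
#' all cells in the session are pooled into a single null distribution
#' whose 99th percentile is the common threshold; `mode = "cell"` uses
#' each cell's own null.
#'
#' @inheritParams classify_place
#' @param cells Cell indices to classify (population mode uses all of
#'   them for the pooled null).
#' @param mode "population" or "cell".
#' @return A list of `shuffle_result`, one per requested cell.
#' @export
classify_hd <- function(s, cells = seq_along(s$cells), n_shuffles = 1000,
                        min_offset = 4, min_spikes = 100, seed = 1,
                        mode = c("population", "cell"), ctx = NULL) {
  mode <- match.arg(mode)
  ctx <- ctx %||% classify_context(s)
  th <- deg2rad((seq_len(ctx$nbd) - 0.5) * ctx$cfg$dir_bin)
  circK <- boxcar_circulant(ctx$nbd, ctx$kernel)
  opos <- ctx$sm_occ > 0
  ray_batch <- function(counts) {
    tun <- as.matrix(counts %*% circK)
    tun <- sweep(tun[, opos, drop = FALSE], 2, ctx$sm_occ[opos], `/`)
    tot <- rowSums(tun)
    sqrt((tun %*% cos(th[opos]))^2 + (tun %*% sin(th[opos]))^2)[, 1] /
      ifelse(tot > 0, tot, NA)
  }
  res <- vector("list", length(cells))
  obs <- rep(NA_real_, length(cells))
  nulls <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    spikes <- s$cells[[cells[k]]]
    if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, s$trajectory)
    if (length(spikes$t) < min_spikes) { res[[k]] <- low_count_result("rayleigh", length(spikes$t)); next }
    shifts <- shuffle_shifts(ctx, n_shuffles, min_offset, seed + k - 1L)
    rv <- ray_batch(shifted_counts(ctx, spikes, shifts, what = "dir"))
    obs[k] <- rv[1]
    nulls[[k]] <- rv[-1]
  }
  pooled <- unlist(nulls)
  for (k in seq_along(cells)) {
    if (!is.null(res[[k]])) next
    null_k <- if (mode == "population") pooled else nulls[[k]]
    thr <- stats::quantile(null_k, 0.99, names = FALSE, na.rm = TRUE)
    res[[k]] <- shuffle_result("rayleigh", obs[k], null_k,
                               passes = is.finite(obs[k]) && obs[k] > thr,
                               extra = list(mode = mode))
  }
  if (length(cells) == 1) res[[1]] else res
}

# circulant mean-filter matrix for directional smoothing
boxcar_circulant <- function(n, k) {
  if (k <= 1) return(Matrix::Diagonal(n))
  h <- (k - 1) / 2
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- ((idx - 1) %% n) + 1
  Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                       x = 1 / k, dims = c(n, n))
}

#' Classify a speed-modulated cell
#'
#' The instantaneous firing rate (spikes per position sample divided by
#' the 0.02 s sample duration) is correlated with running speed across all
#' valid samples; the cell passes if the Pearson r exceeds the 99th
#' percentile of r-values from time-shift shuffled spike trains. All
#' circular shifts are evaluated at once via FFT cross-correlation.
#'
#' @inheritParams classify_place
#' @return A `shuffle_result`.
#' @export
classify_speed <- function(s, cell = 1, n_shuffles = 1000, min_offset = 4,
                           min_spikes = 100, seed = 1, ctx = NULL) {
  ctx <- ctx %||% classify_context(s)
  spikes <- s$cells[[cell]]
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, s$trajectory)
  if (length(spikes$t) < min_spikes)
    return(low_count_result("speed_r", length(spikes$t)))
  n <- ctx$n_samp
  traj <- s$trajectory
  cnt <- tabulate(spikes$ann$sample[spikes$ann$valid], nbins = n) / ctx$dt
  mc <- as.numeric(traj$valid)
  v <- traj$speed
  mv <- as.numeric(traj$valid & is.finite(v))
  if (sum(mv) < 2 || stats::sd(v[mv > 0]) < 1e-12) {
    return(shuffle_result("speed_r", NaN, rep(NaN, n_shuffles), NA))
  }
  v0 <- ifelse(mv > 0, v, 0)
  r_all <- shifted_pearson(cnt * mc, mc, v0, mv)
  shifts <- shuffle_shifts(ctx, n_shuffles, min_offset, seed) %% n
  rvals <- r_all[shifts + 1L]
  obs <- rvals[1]; null <- rvals[-1]
  thr <- stats::quantile(null, 0.99, names = FALSE, na.rm = TRUE)
  shuffle_result("speed_r", obs, null,
                 passes = is.finite(obs) && obs > thr)
}

# Pearson r between circularly shifted series a (validity ma) and fixed
# series b (validity mb), for every shift, via FFT cross-correlations.
# a must be zero where invalid; likewise b.
shifted_pearson <- function(a, ma, b, mb) {
  n <- length(a)
  conv <- function(x, y) Re(stats::fft(stats::fft(x) * Conj(stats::fft(y)),
                                       inverse = TRUE)) / n
  # index s+1 = sum_i x[(i+s-1) mod n + 1] * y[i]
  nn <- conv(ma, mb)
  sa <- conv(a, mb)
  sa2 <- conv(a^2, mb)
  sb <- conv(ma, b)
  sb2 <- conv(ma, b^2)
  sab <- conv(a, b)
  den <- (nn * sa2 - sa^2) * (nn * sb2 - sb^2)
  out <- (nn * sab - sa * sb) / sqrt(pmax(den, 0))
  out[den <= 1e-12] <- NaN
  out
}

#' Run all four shuffle classifiers on a session
#'
#' Orchestrates place, grid, head-direction and speed classification with
#' shared precomputation; HD classification uses the pooled population
#' null by default.
#'
#' @param s A `spat_session`.
#' @param cells Cell indices.
#' @param what Which classifiers to run.
#' @param n_shuffles,min_offset,seed Shuffle parameters.
#' @param hd_mode Null pooling for HD cells ("population" or "cell").
#' @param max_lag Correlogram window for gridness, bins.
#' @return Data frame with one row per cell: observed statistics,
#'   thresholds and pass flags; per-cell `shuffle_result`s in the
#'   `details` attribute.
#' @export
classify_cells <- function(s, cells = seq_along(s$cells),
                           what = c("place", "grid", "hd", "speed"),
                           n_shuffles = 1000, min_offset = 4, seed = 1,
                           hd_mode = "population", max_lag = NULL) {
  ctx <- classify_context(s)
  out <- data.frame(cell = cells,
                    id = vapply(s$cells[cells], function(x)
                      as.character(x$id %||% NA), character(1)))
  details <- list()
  for (w in intersect(what, c("place", "grid", "speed"))) details[[w]] <- list()
  for (k in seq_along(cells)) {
    spikes <- s$cells[[cells[k]]]
    if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, s$trajectory)
    # place and grid reuse the same smoothed shuffle maps
    sm <- NULL
    if (any(c("place", "grid") %in% what) && length(spikes$t) >= 100) {
      shifts <- shuffle_shifts(ctx, n_shuffles, min_offset, seed + 7L * k)
      sm <- as.matrix(shifted_counts(ctx, spikes, shifts) %*% ctx$K)
    }
    if ("place" %in% what)
      details$place[[k]] <- classify_place(s, cells[k], n_shuffles, min_offset,
                                           seed = seed + 7L * k, ctx = ctx,
                                           sm = sm)
    if ("grid" %in% what)
      details$grid[[k]] <- classify_grid(s, cells[k], n_shuffles, min_offset,
                                         seed = seed + 7L * k,
                                         max_lag = max_lag, ctx = ctx, sm = sm)
    if ("speed" %in% what)
      details$speed[[k]] <- classify_speed(s, cells[k], n_shuffles, min_offset,
                                           seed = seed + 7L * k, ctx = ctx)
  }
  for (w in intersect(what, c("place", "grid", "speed"))) {
    res <- details[[w]]
    out[[paste0(w, "_obs")]] <- vapply(res, function(x) x$observed, numeric(1))
    out[[paste0(w, "_thr")]] <- vapply(res, function(x) x$percentile_99, numeric(1))
    out[[paste0(w, "_pass")]] <- vapply(res, function(x) isTRUE(x$passes), logical(1))
  }
  if ("hd" %in% what) {
    res <- classify_hd(s, cells, n_shuffles, min_offset, seed = seed,
                       mode = hd_mode, ctx = ctx)
    if (inherits(res, "shuffle_result")) res <- list(res)
    out$hd_obs <- vapply(res, function(x) x$observed, numeric(1))
    out$hd_thr <- vapply(res, function(x) x$percentile_99, numeric(1))
    out$hd_pass <- vapply(res, function(x) isTRUE(x$passes), logical(1))
    details$hd <- res
  }
  attr(out, "details") <- details
  out
}
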