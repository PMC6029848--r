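#' Skaggs spatial information
#'
#' Information conveyed per spike about the animal's location:
#' `sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' `p_i` the (smoothed) dwell fraction per bin and `lambda_bar` the
#' dwell-weighted mean rate. NaN for a zero-spike map.
#'
#' @param map A `ratemap`.
#' @return Bits per spike (>= 0).
#' @export
spatial_information <- function(map) {
  d <- as.vector(map$sm_dwell)
  lam <- as.vector(map$sm_spk) / d
  ok <- is.finite(d) & is.finite(lam) & d > 0
  skaggs_info(lam[ok], d[ok])
}

skaggs_info <- function(lam, w) {
  p <- w / sum(w)
  lbar <- sum(p * lam)
  if (!is.finite(lbar) || lbar <= 0) return(NaN)
  x <- lam / lbar
  terms <- ifelse(x > 0, p * x * log2(x), 0)
  sum(terms)
}

#' Directional (head-direction) information
#'
#' The Skaggs information formula applied over direction bins, with the
#' smoothed directional occupancy as the weighting.
#'
#' @param tuning A `dir_tuning`.
#' @return Bits per spike.
#' @export
directional_information <- function(tuning) {
  ok <- is.finite(tuning$rate) & tuning$sm_occ > 0
  skaggs_info(tuning$rate[ok], tuning$sm_occ[ok])
}

#' Rayleigh vector length of a tuning curve
#'
#' Length of the rate-weighted resultant of the bin-centre unit vectors:
#' 0 for flat tuning, 1 when all firing is in a single bin.
#'
#' @param tuning A `dir_tuning`.
#' @return Scalar in `[0, 1]`, NaN for an all-zero curve.
#' @export
rayleigh_vector <- function(tuning) {
  ok <- is.finite(tuning$rate)
  r <- tuning$rate[ok]
  if (sum(r) <= 0) return(NaN)
  resultant_length(tuning$centers[ok], w = r)
}

#' Half-height directional tuning width
#'
#' Angular width of the contiguous region around the tuning peak where the
#' rate exceeds baseline + (peak - baseline)/2, the baseline being the
#' minimum of the smoothed curve; crossing points are linearly
#' interpolated. NaN for flat tuning.
#'
#' @param tuning A `dir_tuning`.
#' @return Width in degrees.
#' @export
tuning_width <- function(tuning) {
  r <- tuning$rate
  if (any(!is.finite(r))) return(NaN)
  n <- length(r)
  pk <- which.max(r)
  base <- min(r)
  amp <- r[pk] - base
  if (amp <= 1e-12) return(NaN)
  half <- base + amp / 2
  width <- 0
  for (step in c(1L, -1L)) {
    i <- pk
    repeat {
      j <- ((i - 1L + step) %% n) + 1L
      if (j == pk) return(360) # wrapped all the way round
      if (r[j] < half) {
        frac <- (r[i] - half) / (r[i] - r[j])
        width <- width + (abs(wrap180((i - pk) * tuning$bin_width)) +
                          frac * tuning$bin_width)
        break
      }
      i <- j
    }
  }
  width
}

# --- gridness ---------------------------------------------------------------

# Geometry cache for gridness/grid-scale on correlograms with max lag L:
# disc offsets sorted by radius, ring memberships, and sparse bilinear
# interpolation operators for the five annulus rotations.
.grid_geom_cache <- new.env(parent = emptyenv())

gridness_geom <- function(L) {
  key <- as.character(L)
  if (!is.null(.grid_geom_cache[[key]])) return(.grid_geom_cache[[key]])
  n <- 2 * L + 1
  dx <- rep(-L:L, times = n)
  dy <- rep(-L:L, each = n)
  rr <- sqrt(dx^2 + dy^2)
  keep <- rr <= L - 1 & rr > 1e-9
  idx <- which(keep)
  o <- order(rr[idx])
  idx <- idx[o]
  g <- list(L = L, idx = idx, rr = rr[idx], ring = round(rr))
  Ws <- list()
  for (phi in c(30, 60, 90, 120, 150)) {
    th <- deg2rad(phi)
    xr <- dx[idx] * cos(th) - dy[idx] * sin(th)
    yr <- dx[idx] * sin(th) + dy[idx] * cos(th)
    x0 <- floor(xr); y0 <- floor(yr)
    fx <- xr - x0; fy <- yr - y0
    m <- length(idx)
    cols <- cbind((x0 + L + 1) + (y0 + L) * n,
                  (x0 + L + 2) + (y0 + L) * n,
                  (x0 + L + 1) + (y0 + L + 1) * n,
                  (x0 + L + 2) + (y0 + L + 1) * n)
    w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    Ws[[as.character(phi)]] <- Matrix::sparseMatrix(
      i = rep(seq_len(m), 4), j = as.vector(cols), x = as.vector(w),
      dims = c(m, n * n))
  }
  g$W <- Ws
  .grid_geom_cache[[key]] <- g
  g
}

# gridness over expanding annuli from a correlogram vector; returns the
# maximum annulus gridness plus the inner radius used
gridness_core <- function(ac, L, inner = NULL, min_annulus = 30) {
  g <- gridness_geom(L)
  acv <- as.vector(ac)
  if (is.null(inner)) {
    # inner radius: first integer ring whose azimuthal mean drops below 0.2
    ringv <- g$ring[g$idx]
    mu <- vapply(1:(L - 1), function(k) {
      v <- acv[g$idx[ringv == k]]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    inner <- which(mu < 0.2)[1]
    if (is.na(inner)) return(list(gridness = NaN, inner = NA_real_))
  }
  v0 <- acv[g$idx]
  rot <- lapply(g$W, function(W) as.vector(W %*% ifelse(is.finite(acv), acv, NA)))
  # prefix sums over radius order, masking pairwise-incomplete cells
  cors <- sapply(rot, function(vp) {
    m <- is.finite(v0) & is.finite(vp)
    a <- ifelse(m, v0, 0); b <- ifelse(m, vp, 0)
    cm <- cumsum(m); ca <- cumsum(a); cb <- cumsum(b)
    ca2 <- cumsum(a^2); cb2 <- cumsum(b^2); cab <- cumsum(a * b)
    lo <- findInterval(inner, g$rr) # cells with rr <= inner excluded
    his <- which(g$rr >= inner + 2) # expanding outer radii
    if (!length(his)) return(rep(NA_real_, 0))
    nn <- cm[his] - cm[lo]
    s1 <- ca[his] - ca[lo]; s2 <- cb[his] - cb[lo]
    s11 <- ca2[his] - ca2[lo]; s22 <- cb2[his] - cb2[lo]
    s12 <- cab[his] - cab[lo]
    den <- (nn * s11 - s1^2) * (nn * s22 - s2^2)
    out <- ifelse(nn >= min_annulus & den > 1e-24,
                  (nn * s12 - s1 * s2) / sqrt(pmax(den, 1e-300)), NA_real_)
    out
  })
  if (!is.matrix(cors) || !nrow(cors)) return(list(gridness = NaN, inner = inner))
  gr <- pmin(cors[, "60"], cors[, "120"]) -
        pmax(cors[, "30"], cors[, "90"], cors[, "150"])
  if (all(!is.finite(gr))) return(list(gridness = NaN, inner = inner))
  list(gridness = max(gr, na.rm = TRUE), inner = inner)
}

#' Gridness score
#'
#' Rotational-symmetry statistic of the spatial autocorrelogram. An annulus
#' excluding the central peak (inner radius: first integer ring whose
#' azimuthal mean correlation falls below 0.2) is correlated with copies of
#' itself rotated by 30, 60, 90, 120 and 150 degrees; gridness is
#' `min(r60, r120) - max(r30, r90, r150)`. The outer radius expands over
#' all admissible values and the maximum annulus gridness is returned, a
#' deterministic rule applied identically to observed and shuffled maps.
#' Hexagonal firing gives large positive scores, square lattices negative
#' ones, rotationally symmetric fields ~0.
#'
#' @param acg A `correlogram` (from [spatial_autocorr()]).
#' @param inner Optional fixed inner radius in bins (default: automatic).
#' @return Gridness score (attribute `inner`: radius used); NaN when no
#'   central peak boundary is identifiable.
#' @export
gridness <- function(acg, inner = NULL) {
  res <- gridness_core(acg$ac, acg$max_lag, inner = inner)
  structure(res$gridness, inner = res$inner)
}

#' Grid scale
#'
#' Median distance from the correlogram centre to the six (at least three)
#' nearest local maxima outside the central peak, converted to cm.
#'
#' @param acg A `correlogram`.
#' @param inner Optional central-peak radius in bins (default: automatic,
#'   as in [gridness()]).
#' @return Grid spacing in cm; NaN with fewer than 3 surrounding peaks.
#' @export
grid_scale <- function(acg, inner = NULL) {
  ac <- acg$ac
  L <- acg$max_lag
  if (is.null(inner)) {
    inner <- gridness_core(ac, L)$inner
    if (!is.finite(inner)) return(NaN)
  }
  n <- 2 * L + 1
  fin <- is.finite(ac)
  is_max <- fin
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, n, n)
    si <- max(1, 1 + di):min(n, n + di)
    sj <- max(1, 1 + dj):min(n, n + dj)
    sh[si, sj] <- ac[si - di, sj - dj]
    sh[!is.finite(sh)] <- -Inf
    is_max <- is_max & (ac >= sh)
  }
  ii <- which(is_max)
  dx <- ((ii - 1) %% n) - L
  dy <- ((ii - 1) %/% n) - L
  rr <- sqrt(dx^2 + dy^2)
  keep <- rr > inner & rr <= L - 1 & ac[ii] > 0
  rr <- rr[keep]
  if (length(rr) < 3) return(NaN)
  rr <- sort(rr)[seq_len(min(6, length(rr)))]
  stats::median(rr) * acg$bin_size
}

#' Spatial correlation between two rate maps
#'
#' Pearson correlation over bins finite in both maps, optionally after
#' rotating the second map by 180 degrees (point reflection of the bin
#' grid) — the statistic of the cue-rotation probe.
#'
#' @param a,b `ratemap`s on the same grid.
#' @param rotation 0 or 180 degrees applied to `b`.
#' @param min_overlap Minimum overlapping finite bins.
#' @return Pearson correlation.
#' @export
map_similarity <- function(a, b, rotation = 0, min_overlap = 20) {
  stopifnot(all(dim(a$rate) == dim(b$rate)), rotation %in% c(0, 180))
  rb <- b$rate
  if (rotation == 180) rb <- rb[nrow(rb):1, ncol(rb):1]
  ok <- is.finite(a$rate) & is.finite(rb)
  if (sum(ok) < min_overlap) stop("fewer than ", min_overlap, " overlapping bins")
  stats::cor(a$rate[ok], rb[ok])
}

#' Directional information within individual firing fields
#'
#' Restricts the trajectory and spikes to the bins of each detected field
#' and recomputes directional information there, either by standard binning
#' or from a field-wise pxd fit (which controls for inhomogeneous sampling
#' of direction within the field).
#'
#' @param traj Trajectory.
#' @param spikes Annotated `spike_train`.
#' @param fields A `field_set` from [detect_fields()].
#' @param config Session config.
#' @param method "standard" or "pxd".
#' @param min_spikes Fields with fewer spikes give NaN (with a warning).
#' @return Numeric vector, one value per field.
#' @export
per_field_dir_info <- function(traj, spikes, fields,
                               config = attr(traj, "config"),
                               method = c("standard", "pxd"),
                               min_spikes = 50) {
  method <- match.arg(method)
  geom <- bin_geometry(config)
  sid <- bin_index(traj$x, traj$y, geom)
  if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, traj)
  out <- numeric(nrow(fields$fields))
  for (k in seq_len(nrow(fields$fields))) {
    fid <- fields$fields$id[k]
    fbins <- which(fields$labels == fid)
    insamp <- !is.na(sid) & sid %in% fbins
    tr <- traj
    tr$valid <- traj$valid & insamp
    spk_in <- spikes$ann$valid & insamp[spikes$ann$sample]
    if (sum(spk_in) < min_spikes) {
      warning(sprintf("field %d has %d spikes (< %d); NaN", fid,
                      sum(spk_in), min_spikes))
      out[k] <- NaN
      next
    }
    sub <- spike_train(sort(spikes$t[spk_in]), id = spikes$id)
    sub <- annotate_spikes(sub, tr)
    if (method == "standard") {
      out[k] <- directional_information(make_dir_tuning(tr, sub,
                                                        bin = config$dir_bin))
    } else {
      fit <- fit_pxd(tr, sub, config = config)
      out[k] <- pxd_dir_info(fit)
    }
  }
  out
}

#' Scalar metrics of one cell
#'
#' One row with the standard tuning metrics of a cell in a session: mean
#' and peak firing rate, spatial and directional information, gridness and
#' grid scale, Rayleigh vector length, tuning width and half-peak field
#' area fraction.
#'
#' @param s A `spat_session`.
#' @param cell Cell index or id.
#' @param max_lag Correlogram lag used for gridness/scale (bins).
#' @return A one-row data frame.
#' @export
cell_metrics <- function(s, cell = 1, max_lag = NULL) {
  sp <- if (is.character(cell)) {
    ids <- vapply(s$cells, function(x) x$id, character(1))
    s$cells[[match(cell, ids)]]
  } else s$cells[[cell]]
  rm_ <- make_ratemap(s$trajectory, sp, s$config)
  tun <- make_dir_tuning(s$trajectory, sp, bin = s$config$dir_bin)
  pxd <- fit_pxd(s$trajectory, sp, s$config)
  ml <- max_lag %||% floor(n_bins(s$config) * 0.6)
  acg <- spatial_autocorr(rm_, max_lag = ml)
  fs <- detect_fields(rm_)
  dur <- sum(s$trajectory$valid) / (attr(s$trajectory, "rate") %||% s$config$position_rate)
  data.frame(id = sp$id,
             n_spikes = length(sp$t),
             mean_rate = length(sp$t) / dur,
             peak_rate = suppressWarnings(max(rm_$rate, na.rm = TRUE)),
             spatial_info = spatial_information(rm_),
             dir_info = directional_information(tun),
             dir_info_pxd = if (pxd$converged) pxd_dir_info(pxd) else NaN,
             gridness = as.numeric(gridness(acg)),
             grid_scale = grid_scale(acg),
             rayleigh = rayleigh_vector(tun),
             tuning_width = tuning_width(tun),
             field_area_frac = fs$area_frac)
}

#' Gaussian field size
#'
#' Estimates a place field's spatial extent by least-squares fit of an
#' isotropic Gaussian to the smoothed rate map around the field centroid,
#' with the map-smoothing variance (boxcar width squared over 12)
#' subtracted from the fitted variance. Unlike half-max area counting,
#' the estimate does not depend on a noisy peak threshold or on where the
#' field is truncated, which makes ratios of field sizes between
#' conditions (e.g. VR/R expansion) far more stable.
#'
#' @param map A `ratemap`.
#' @param fields A `field_set` from [detect_fields()].
#' @param k Field row index (default: the largest field).
#' @param window Fit radius around the field centroid, cm.
#' @return Field sigma in cm (NaN if the fit fails).
#' @export
field_sigma <- function(map, fields, k = NULL, window = 30) {
  if (is.null(k)) k <- which.max(fields$fields$n_bins)
  cx <- fields$fields$center_x[k]
  cy <- fields$fields$center_y[k]
  n <- nrow(map$rate)
  bx <- rep(map$centers, times = n)
  by <- rep(map$centers, each = n)
  r <- as.vector(map$rate)
  sel <- is.finite(r) & sqrt((bx - cx)^2 + (by - cy)^2) < window
  if (sum(sel) < 20) return(NaN)
  d2 <- (bx[sel] - cx)^2 + (by[sel] - cy)^2
  rr <- r[sel]
  s2_0 <- max(sum(rr * d2) / sum(rr) / 2, 4)
  fit <- try(stats::nls(rr ~ A * exp(-d2 / (2 * s2)),
                        start = list(A = max(rr), s2 = s2_0),
                        control = stats::nls.control(warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NaN)
  s2 <- stats::coef(fit)[["s2"]] - (map$kernel * map$bin_size)^2 / 12
  sqrt(max(s2, 1e-2))
}
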