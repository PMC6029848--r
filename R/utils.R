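# Angle helpers. All public-facing angles are degrees in [0, 360),
# counter-clockwise, 0 = +x; differences wrap to (-180, 180].

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

wrap360 <- function(d) d %% 360

# wrapped difference a - b in (-180, 180]
wrap180 <- function(d) {
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# resultant length of a set of angles (deg), optionally weighted
resultant_length <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  ok <- is.finite(deg) & is.finite(w)
  deg <- deg[ok]; w <- w[ok]
  if (!length(deg) || sum(w) == 0) return(NA_real_)
  th <- deg2rad(deg)
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
}

circ_mean_deg <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  th <- deg2rad(deg)
  wrap360(rad2deg(atan2(sum(w * sin(th)), sum(w * cos(th)))))
}

# 2-D boxcar mean filter with edge truncation + renormalisation; NA cells are
# excluded from both numerator and kernel mass. Used for quantities that are
# already rates.
boxcar2d <- function(m, k = 5) {
  stopifnot(k %% 2 == 1)
  mask <- is.finite(m)
  m0 <- ifelse(mask, m, 0)
  num <- box_pass(box_pass(m0, k, by_row = FALSE), k, by_row = TRUE)
  den <- box_pass(box_pass(mask * 1, k, by_row = FALSE), k, by_row = TRUE)
  out <- num / den
  out[den == 0] <- NA_real_
  out[!mask] <- NA_real_
  out
}

# Mass-conserving boxcar: each cell's mass is spread uniformly over the
# in-mask part of its kernel window, so total spike count and total dwell are
# conserved exactly and the renormalisation cancels in the spikes/dwell
# ratio. Used for spike and dwell maps.
boxcar2d_mass <- function(m, k = 5, mask = NULL) {
  stopifnot(k %% 2 == 1)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  den <- box_pass(box_pass(mask * 1, k, by_row = FALSE), k, by_row = TRUE)
  z <- ifelse(mask, m, 0) / pmax(den, 1)
  out <- box_pass(box_pass(z, k, by_row = FALSE), k, by_row = TRUE)
  out[!mask] <- NA_real_
  out
}

# circular boxcar mean filter for directional tuning vectors
boxcar_circ <- function(v, k = 5) {
  if (k <= 1) return(v)
  h <- (k - 1) / 2
  n <- length(v)
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(v[idx], nrow = n))
}

# one-dimensional running-sum pass along rows or columns (truncated window)
box_pass <- function(m, k, by_row) {
  if (by_row) return(t(box_pass(t(m), k, by_row = FALSE)))
  h <- (k - 1) / 2
  n <- nrow(m)
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
}

# Sparse linear operator equivalent to boxcar2d_mass() on an nx-by-ny grid
# with a fixed validity mask; right-multiplying an (n_maps x n_bins) matrix
# of binned masses smooths thousands of shuffled spike maps at once.
boxcar_operator <- function(nx, ny, k = 5, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  h <- (k - 1) / 2
  idx <- which(mask)
  ii <- ((idx - 1) %% nx) + 1
  jj <- ((idx - 1) %/% nx) + 1
  den <- box_pass(box_pass(mask * 1, k, by_row = FALSE), k, by_row = TRUE)
  trip_i <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    i0 <- max(ii[q] - h, 1); i1 <- min(ii[q] + h, nx)
    j0 <- max(jj[q] - h, 1); j1 <- min(jj[q] + h, ny)
    nb <- as.vector(outer(i0:i1, (j0:j1 - 1) * nx, `+`))
    nb <- nb[mask[nb]]
    trip_i[[q]] <- cbind(src = idx[q], dst = nb)
  }
  tr <- do.call(rbind, trip_i)
  Matrix::sparseMatrix(i = tr[, "src"], j = tr[, "dst"],
                       x = 1 / den[tr[, "src"]],
                       dims = c(nx * ny, nx * ny))
}

# analytic signal via FFT (positive-frequency doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
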