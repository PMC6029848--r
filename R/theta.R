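#' Instantaneous theta phase and frequency
#'
#' Band-passes the LFP (zero-phase Butterworth via forward-backward
#' filtering), takes the analytic signal, and returns the instantaneous
#' phase and frequency. Phase convention: 0 degrees at the theta peak,
#' increasing through the cycle (precession slopes flip sign under the
#' opposite convention). Instantaneous frequency is the wrapped phase
#' derivative divided by 2 pi, median-filtered over ~0.25 s; samples whose
#' frequency falls outside the filter band are masked NaN.
#'
#' @param lfp An `lfp_signal`.
#' @param band Theta band, Hz (default 6-12).
#' @param order Butterworth order.
#' @return Object of class `theta_signal`: `phase` (deg, `[0, 360)`),
#'   `freq` (Hz, NaN where out of band), `amplitude`, `rate`, `band`.
#' @export
instantaneous_theta <- function(lfp, band = c(6, 12), order = 3) {
  nyq <- lfp$rate / 2
  if (band[2] >= nyq) stop("theta band exceeds the Nyquist frequency")
  if (lfp$rate < 4 * band[2])
    stop("LFP rate must be at least 4x the band upper edge")
  bf <- signal::butter(order, band / nyq, type = "pass")
  x <- signal::filtfilt(bf, lfp$v - mean(lfp$v))
  z <- analytic_signal(x)
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  f <- c(NA, dph) * lfp$rate / (2 * pi)
  k <- max(3, 2 * floor(0.125 * lfp$rate) + 1)
  f[is.na(f)] <- f[2]
  f <- stats::runmed(f, k, endrule = "median")
  f[f < band[1] | f > band[2]] <- NaN
  structure(list(phase = wrap360(rad2deg(ph)), freq = f, amplitude = Mod(z),
                 rate = lfp$rate, t0 = lfp$t0, band = band),
            class = "theta_signal")
}

#' Theta phase at arbitrary times
#'
#' Linear interpolation of the analytic phase (via its complex
#' representation, avoiding wrap artefacts).
#'
#' @param theta A `theta_signal`.
#' @param t Times, s.
#' @return Phase in degrees `[0, 360)`.
#' @export
theta_phase_at <- function(theta, t) {
  # the phase grid is regular: index arithmetic instead of approx()
  pos <- (t - theta$t0) * theta$rate
  i0 <- pmin(pmax(floor(pos), 0), length(theta$phase) - 2)
  f <- pmin(pmax(pos - i0, 0), 1)
  a <- deg2rad(theta$phase[i0 + 1])
  b <- deg2rad(theta$phase[i0 + 2])
  re <- (1 - f) * cos(a) + f * cos(b)
  im <- (1 - f) * sin(a) + f * sin(b)
  wrap360(rad2deg(atan2(im, re)))
}

#' Speed profile of theta frequency or firing rate
#'
#' Bins running speed (2.5 to 30 cm/s by default) and averages either the
#' instantaneous LFP theta frequency or a cell's instantaneous firing rate
#' (spike count per position sample / 0.02 s) within each bin, then fits a
#' count-weighted least-squares line through the bin means — the
#' theta-frequency/speed (or rate/speed) relationship.
#'
#' @param traj Trajectory.
#' @param lfp An `lfp_signal` (mutually exclusive with `spikes`).
#' @param spikes An annotated `spike_train`.
#' @param breaks Speed bin edges, cm/s.
#' @param band Theta band for the LFP branch.
#' @return Object of class `speed_profile`: `table` (bin centre, mean,
#'   sem, n), `slope`, `intercept`, `kind`.
#' @export
speed_profiles <- function(traj, lfp = NULL, spikes = NULL,
                           breaks = seq(2.5, 30, by = 2.5), band = c(6, 12)) {
  if (is.null(lfp) == is.null(spikes))
    stop("supply exactly one of lfp or spikes")
  rate <- attr(traj, "rate") %||% (1 / stats::median(diff(traj$t)))
  if (!is.null(lfp)) {
    th <- if (inherits(lfp, "theta_signal")) lfp else instantaneous_theta(lfp, band)
    ts <- th$t0 + (seq_along(th$freq) - 1) / th$rate
    y <- stats::approx(ts, th$freq, xout = traj$t, rule = 2)$y
    kind <- "theta_freq"
  } else {
    if (is.null(spikes$ann)) spikes <- annotate_spikes(spikes, traj)
    cnt <- tabulate(spikes$ann$sample[spikes$ann$valid], nbins = nrow(traj))
    y <- cnt * rate
    kind <- "firing_rate"
  }
  ok <- traj$valid & is.finite(traj$speed) & is.finite(y)
  sb <- cut(traj$speed[ok], breaks = breaks, include.lowest = FALSE)
  yv <- y[ok]
  agg <- data.frame(center = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    mean = as.vector(tapply(yv, sb, mean)),
                    sem = as.vector(tapply(yv, sb, function(z)
                      stats::sd(z) / sqrt(length(z)))),
                    n = as.vector(table(sb)))
  use <- is.finite(agg$mean) & agg$n > 0
  if (sum(use) < length(breaks) - 1)
    warning("empty speed bins dropped from the fit")
  if (sum(use) < 2) stop("fewer than 2 populated speed bins")
  fit <- stats::lm(mean ~ center, data = agg[use, ], weights = agg$n[use])
  structure(list(table = agg, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), kind = kind),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> %s: slope %.4f /(cm/s), intercept %.3f\n",
              x$kind, x$slope, x$intercept))
  invisible(x)
}

# normalised damped-cosine lag density on (0, w]
lag_density <- function(lag, a, f, tau, w, ngrid = 512) {
  g <- function(l) (1 + a * cos(2 * pi * f * l)) * exp(-l / tau)
  grid <- seq(0, w, length.out = ngrid)
  Z <- sum((g(grid)[-1] + g(grid)[-ngrid]) / 2) * (w / (ngrid - 1))
  g(lag) / Z
}

#' Theta modulation of a spike train
#'
#' Models the distribution of spike-time lags (the autocorrelogram) within
#' a 0-`window` s window as a damped cosine,
#' `(1 + a cos(2 pi f lag)) exp(-lag/tau)`, fitted by maximum likelihood
#' over the observed lags. The modulation depth `a` is the theta index and
#' `f` the cell's intrinsic theta frequency. Significance: `a` must exceed
#' the 95th percentile of theta indices from surrogate trains with permuted
#' inter-spike intervals, which preserve the ISI marginal while destroying
#' rhythmicity.
#'
#' @param spikes A `spike_train`.
#' @param window Lag window, s.
#' @param n_shuffles Surrogates for the null (default 100).
#' @param seed Integer RNG seed.
#' @param min_spikes Minimum spikes required.
#' @return Object of class `theta_modulation`: `theta_index`,
#'   `intrinsic_freq` (NaN when unmodulated), `tau`, `ci95` (the null 95th
#'   percentile), `is_theta_modulated`, `converged`, `n_lags`.
#' @export
theta_modulation <- function(spikes, window = 0.5, n_shuffles = 100,
                             seed = 1, min_spikes = 100) {
  t <- spikes$t
  if (length(t) < min_spikes) stop("need at least ", min_spikes, " spikes")
  fit1 <- fit_lag_model(spike_lags(t, window), window)
  set.seed(seed)
  isi <- diff(t)
  null_a <- vapply(seq_len(n_shuffles), function(i) {
    ts <- cumsum(c(t[1], sample(isi)))
    fit_lag_model(spike_lags(ts, window), window)$a
  }, numeric(1))
  ci95 <- stats::quantile(null_a, 0.95, names = FALSE, na.rm = TRUE)
  modulated <- isTRUE(fit1$converged) && is.finite(fit1$a) && fit1$a > ci95
  structure(list(theta_index = fit1$a,
                 intrinsic_freq = if (modulated) fit1$f else NaN,
                 tau = fit1$tau, ci95 = ci95,
                 is_theta_modulated = modulated,
                 converged = fit1$converged, n_lags = fit1$n),
            class = "theta_modulation")
}

#' @export
print.theta_modulation <- function(x, ...) {
  cat(sprintf("<theta_modulation> index %.3f (null 95%%: %.3f)%s\n",
              x$theta_index, x$ci95,
              if (x$is_theta_modulated)
                sprintf(", intrinsic %.2f Hz", x$intrinsic_freq) else
                " - not theta modulated"))
  invisible(x)
}

spike_lags <- function(t, window) {
  n <- length(t)
  out <- vector("list", n)
  j <- 1L
  for (i in seq_len(n - 1)) {
    hi <- t[i] + window
    j <- max(j, i + 1L)
    while (j <= n && t[j] <= hi) j <- j + 1L
    if (j - 1L > i) out[[i]] <- t[(i + 1L):(j - 1L)] - t[i]
  }
  lags <- unlist(out)
  lags[lags > 0]
}

fit_lag_model <- function(lags, window) {
  if (length(lags) < 20)
    return(list(a = NaN, f = NaN, tau = NaN, converged = FALSE, n = length(lags)))
  nll <- function(par) {
    d <- lag_density(lags, par[1], par[2], par[3], window)
    if (any(!is.finite(d) | d <= 0)) return(1e10)
    -sum(log(d))
  }
  best <- NULL
  for (f0 in c(7, 8.5, 10)) for (tau0 in c(0.3, 3)) {
    o <- try(stats::optim(c(0.3, f0, tau0), nll, method = "L-BFGS-B",
                          lower = c(0, 4, 0.05), upper = c(1, 14, 10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    return(list(a = NaN, f = NaN, tau = NaN, converged = FALSE, n = length(lags)))
  list(a = best$par[1], f = best$par[2], tau = best$par[3],
       converged = best$convergence == 0, n = length(lags))
}
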