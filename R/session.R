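#' Session configuration
#'
#' Describes one recording (or simulated) session: arena geometry, condition,
#' trial length and the sampling/binning parameters every downstream stage
#' uses. Defaults mirror the standard open-arena protocol: 50 Hz position
#' tracking, 1.5 cm square spatial bins and 6 degree directional bins.
#'
#' Coordinate convention: centimetres, origin at the arena corner for square
#' arenas (x, y in `[0, arena_width]`) and at the centre for cylinders
#' (x, y in `[-arena_width/2, arena_width/2]`). Head direction is in degrees
#' `[0, 360)`, counter-clockwise, 0 = +x.
#'
#' @param arena_shape "square" or "cylinder".
#' @param arena_width Arena width (square side or cylinder diameter), cm.
#' @param condition "R" (real) or "VR" (virtual reality).
#' @param trial_duration Trial length in seconds.
#' @param position_rate Position sampling rate, Hz.
#' @param lfp_rate LFP sampling rate, Hz.
#' @param bin_size Spatial bin side, cm.
#' @param dir_bin Directional bin width, degrees.
#' @param rng_seed Optional integer seed recorded with the session.
#' @return An object of class `spat_config`.
#' @export
session_config <- function(arena_shape = c("square", "cylinder"),
                           arena_width = 60,
                           condition = c("R", "VR"),
                           trial_duration = 1200,
                           position_rate = 50,
                           lfp_rate = 250,
                           bin_size = 1.5,
                           dir_bin = 6,
                           rng_seed = NULL) {
  arena_shape <- match.arg(arena_shape)
  condition <- match.arg(condition)
  stopifnot(arena_width > 0, trial_duration > 0, position_rate > 0,
            lfp_rate > 0, bin_size > 0, dir_bin > 0)
  cfg <- list(arena_shape = arena_shape,
              arena_width = as.numeric(arena_width),
              condition = condition,
              trial_duration = as.numeric(trial_duration),
              position_rate = as.numeric(position_rate),
              lfp_rate = as.numeric(lfp_rate),
              bin_size = as.numeric(bin_size),
              dir_bin = as.numeric(dir_bin),
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  class(cfg) <- "spat_config"
  cfg
}

#' @export
print.spat_config <- function(x, ...) {
  cat(sprintf("<spat_config> %s %gx%g cm, %s, %g s @%g Hz (bins %g cm / %g deg)\n",
              x$arena_shape, x$arena_width, x$arena_width, x$condition,
              x$trial_duration, x$position_rate, x$bin_size, x$dir_bin))
  invisible(x)
}

# number of spatial bins per axis
n_bins <- function(config) as.integer(ceiling(config$arena_width / config$bin_size))

# x/y range of the bin grid: [0, w] for square, [-w/2, w/2] for cylinder
arena_range <- function(config) {
  if (config$arena_shape == "square") c(0, config$arena_width)
  else c(-config$arena_width / 2, config$arena_width / 2)
}

arena_center <- function(config) {
  if (config$arena_shape == "square") rep(config$arena_width / 2, 2) else c(0, 0)
}

in_arena <- function(config, x, y) {
  r <- arena_range(config)
  if (config$arena_shape == "square") {
    x >= r[1] & x <= r[2] & y >= r[1] & y <= r[2]
  } else {
    x^2 + y^2 <= (config$arena_width / 2)^2
  }
}

#' Assemble a session
#'
#' Bundles a configuration, trajectory, spike trains and LFP into the single
#' container every analysis stage consumes. Invariants (spikes within the
#' trial, trajectory coverage, monotonic timestamps) are checked on
#' construction.
#'
#' @param config A [session_config()].
#' @param trajectory A trajectory as produced by [simulate_trajectory()] or
#'   read from disk (data frame with columns t, x, y, hd, speed, run_dir,
#'   valid).
#' @param cells List of spike trains ([spike_train()]).
#' @param lfp An [lfp_signal()] or NULL.
#' @param ground_truth Optional list of generative parameters (synthetic
#'   sessions only), stored for recovery tests.
#' @return An object of class `spat_session`.
#' @export
session <- function(config, trajectory, cells = list(), lfp = NULL,
                    ground_truth = NULL) {
  s <- structure(list(config = config, trajectory = trajectory,
                      cells = cells, lfp = lfp, ground_truth = ground_truth),
                 class = "spat_session")
  validate_session(s)
  s
}

#' @export
print.spat_session <- function(x, ...) {
  cat(sprintf("<spat_session> %s, %d cells, %d position samples%s\n",
              x$config$condition, length(x$cells), nrow(x$trajectory),
              if (is.null(x$lfp)) "" else sprintf(", LFP @%g Hz", x$lfp$rate)))
  invisible(x)
}

validate_session <- function(s) {
  cfg <- s$config
  tr <- s$trajectory
  need <- c("t", "x", "y", "hd", "valid")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trajectory is missing columns: ", paste(miss, collapse = ", "))
  if (any(diff(tr$t) <= 0)) stop("trajectory timestamps are not strictly increasing")
  n_expect <- round(cfg$trial_duration * cfg$position_rate)
  if (abs(nrow(tr) - n_expect) > 1)
    stop(sprintf("trajectory has %d samples; config implies %d", nrow(tr), n_expect))
  for (i in seq_along(s$cells)) {
    st <- s$cells[[i]]$t
    if (is.unsorted(st)) stop(sprintf("cell %d: spike times not sorted", i))
    if (length(st) && (st[1] < 0 || st[length(st)] > cfg$trial_duration))
      stop(sprintf("cell %d: spike times outside [0, trial_duration]", i))
  }
  invisible(TRUE)
}

#' Spike train of a single cell
#'
#' @param t Sorted spike times in seconds.
#' @param id Cell identifier.
#' @param ann Optional per-spike annotation data frame (filled by
#'   [annotate_spikes()]).
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(t, id = NA_character_, ann = NULL) {
  t <- as.numeric(t)
  if (is.unsorted(t)) stop("spike times must be sorted")
  structure(list(t = t, id = id, ann = ann), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes%s\n", x$id, length(x$t),
              if (is.null(x$ann)) "" else " (annotated)"))
  invisible(x)
}

#' Single-channel LFP signal
#'
#' @param v Voltage samples (arbitrary units).
#' @param rate Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @return Object of class `lfp_signal`.
#' @export
lfp_signal <- function(v, rate, t0 = 0) {
  stopifnot(rate > 0)
  structure(list(v = as.numeric(v), rate = as.numeric(rate), t0 = as.numeric(t0)),
            class = "lfp_signal")
}

#' Annotate spikes with behavioural state
#'
#' Attaches position, head direction, running direction and speed of the
#' nearest trajectory sample to each spike (at 50 Hz the nearest sample is
#' within 10 ms).
#'
#' @param spikes A `spike_train`.
#' @param traj Trajectory data frame.
#' @return The spike train with its `ann` data frame filled.
#' @export
annotate_spikes <- function(spikes, traj) {
  idx <- nearest_sample(spikes$t, traj$t)
  spikes$ann <- data.frame(sample = idx,
                           x = traj$x[idx], y = traj$y[idx],
                           hd = traj$hd[idx],
                           run_dir = traj$run_dir[idx],
                           speed = traj$speed[idx],
                           valid = traj$valid[idx])
  spikes
}

nearest_sample <- function(t, grid_t) {
  dt <- if (length(grid_t) > 1) grid_t[2] - grid_t[1] else 1
  idx <- round((t - grid_t[1]) / dt) + 1L
  pmin(pmax(idx, 1L), length(grid_t))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session container
#'
#' Writes a session as a directory of plain-text files: `config.yaml`,
#' `positions.tsv` (t, x, y, hd, speed, run_dir, valid), `spikes.tsv`
#' (cell, t), `lfp.tsv` and, for synthetic sessions, `ground_truth.yaml`.
#' Numeric columns are written with 17 significant digits so that
#' write/read round-trips are bit exact.
#'
#' @param s A `spat_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- s$config
  cfgl <- unclass(cfg)
  cfgl <- cfgl[!vapply(cfgl, is.null, logical(1))]
  yaml::write_yaml(cfgl, file.path(path, "config.yaml"))
  tr <- s$trajectory
  pos <- data.table::data.table(t = fmt_num(tr$t), x = fmt_num(tr$x),
                                y = fmt_num(tr$y), hd = fmt_num(tr$hd),
                                speed = fmt_num(tr$speed),
                                run_dir = fmt_num(tr$run_dir),
                                valid = as.integer(tr$valid))
  data.table::fwrite(pos, file.path(path, "positions.tsv"), sep = "\t")
  if (length(s$cells)) {
    sp <- data.table::rbindlist(lapply(s$cells, function(cl)
      data.table::data.table(cell = cl$id, t = fmt_num(cl$t))))
  } else {
    sp <- data.table::data.table(cell = character(0), t = character(0))
  }
  data.table::fwrite(sp, file.path(path, "spikes.tsv"), sep = "\t")
  if (!is.null(s$lfp)) {
    data.table::fwrite(data.table::data.table(v = fmt_num(s$lfp$v)),
                       file.path(path, "lfp.tsv"), sep = "\t")
  }
  if (!is.null(s$ground_truth)) {
    yaml::write_yaml(s$ground_truth, file.path(path, "ground_truth.yaml"))
  }
  invisible(path)
}

#' Read a session container
#'
#' Inverse of [write_session()]. All session invariants are re-checked on
#' load; a missing component or non-monotonic timestamps raise an error
#' naming the offending file or cell.
#'
#' @param path Directory written by [write_session()].
#' @return A validated `spat_session`.
#' @export
read_session <- function(path) {
  need <- c("config.yaml", "positions.tsv", "spikes.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("session container at ", path, " is missing component: ", f)
  }
  cfgl <- yaml::read_yaml(file.path(path, "config.yaml"))
  cfg <- session_config(arena_shape = cfgl$arena_shape,
                        arena_width = cfgl$arena_width,
                        condition = cfgl$condition,
                        trial_duration = cfgl$trial_duration,
                        position_rate = cfgl$position_rate,
                        lfp_rate = cfgl$lfp_rate,
                        bin_size = cfgl$bin_size,
                        dir_bin = cfgl$dir_bin,
                        rng_seed = cfgl$rng_seed)
  pos <- data.table::fread(file.path(path, "positions.tsv"), sep = "\t")
  if (any(diff(pos$t) <= 0))
    stop("positions.tsv: timestamps are not strictly increasing")
  tr <- data.frame(t = pos$t, x = pos$x, y = pos$y, hd = pos$hd,
                   speed = pos$speed, run_dir = pos$run_dir,
                   valid = as.logical(pos$valid))
  attr(tr, "rate") <- cfg$position_rate
  sp <- data.table::fread(file.path(path, "spikes.tsv"), sep = "\t",
                          colClasses = c(cell = "character", t = "numeric"))
  cells <- list()
  if (nrow(sp)) {
    for (id in unique(sp$cell)) {
      st <- sp$t[sp$cell == id]
      if (is.unsorted(st)) stop("spikes.tsv: unsorted spike times for cell ", id)
      if (st[1] < 0 || st[length(st)] > cfg$trial_duration)
        stop("spikes.tsv: spike times outside trial for cell ", id)
      cells[[length(cells) + 1L]] <- annotate_spikes(spike_train(st, id = id), tr)
    }
  }
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.tsv"))) {
    lv <- data.table::fread(file.path(path, "lfp.tsv"), sep = "\t")
    lfp <- lfp_signal(lv$v, rate = cfg$lfp_rate)
  }
  gt <- NULL
  if (file.exists(file.path(path, "ground_truth.yaml"))) {
    gt <- yaml::read_yaml(file.path(path, "ground_truth.yaml"))
  }
  session(cfg, tr, cells, lfp, ground_truth = gt)
}
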