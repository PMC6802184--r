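#' @name synthio
#' @title Synthetic sessions with planted ground truth
#' @description
#' Generators for synthetic linear-track imaging sessions (hippocampal-style
#' direction-selective place cells plus drink/turn cells, or cingulate-style
#' trajectory-phase cells whose tuning is identical for both running
#' directions), head-direction electrophysiology sessions with wake and REM
#' epochs, GCaMP6-like fluorescence traces, and multiday session sets with
#' partial cell turnover. Every generator plants an explicit per-neuron ground
#' truth so downstream stages can be validated without external recordings.
NULL

# ---- behavior ---------------------------------------------------------------

# Simulate back-and-forth running on a linear track. Traversals follow a
# triangular speed profile (accelerate to the peak speed at mid-track, then
# decelerate), separated by drinking and turning pauses at the track ends.
simulate_track_behavior <- function(duration, frame_rate, track_length = 96,
                                    peak_speed = 40, drink_mean = 3,
                                    turn_mean = 1.5, rear_prob = 0) {
  dt <- 1 / frame_rate
  n_frames <- round(duration * frame_rate)
  pos <- numeric(0); spd <- numeric(0); lab <- character(0); dir <- character(0)
  side <- "L" # current end of the track
  repeat {
    if (length(pos) >= n_frames) break
    # drink at the current end
    nd <- max(2L, round(rlnorm(1, log(drink_mean), 0.25) * frame_rate))
    p <- if (side == "L") 0 else track_length
    pos <- c(pos, rep(p, nd)); spd <- c(spd, rep(0, nd))
    lab <- c(lab, rep(paste0("drink_", side), nd)); dir <- c(dir, rep("none", nd))
    # occasional rearing bout at the end of the track
    if (rear_prob > 0 && runif(1) < rear_prob) {
      nr <- max(2L, round(rlnorm(1, log(1.5), 0.25) * frame_rate))
      pos <- c(pos, rep(p, nr)); spd <- c(spd, rep(0, nr))
      lab <- c(lab, rep("rear", nr)); dir <- c(dir, rep("none", nr))
    }
    # turn
    nt <- max(2L, round(rlnorm(1, log(turn_mean), 0.25) * frame_rate))
    pos <- c(pos, rep(p, nt)); spd <- c(spd, rep(0, nt))
    lab <- c(lab, rep(paste0("turn_", side), nt)); dir <- c(dir, rep("none", nt))
    # run to the other end: trapezoid-like speed profile (brisk start and
    # stop at v_min, peak at mid-traversal)
    vpk <- peak_speed * runif(1, 0.7, 1.3)
    vmin <- 0.2 * peak_speed
    Tt <- 2 * track_length / (vpk + vmin)
    nrun <- max(4L, round(Tt * frame_rate))
    tt <- (seq_len(nrun) - 0.5) / nrun # fraction of traversal time
    v <- vmin + (vpk - vmin) * (1 - abs(2 * tt - 1))
    dist <- cumsum(v * dt)
    dist <- dist / dist[nrun] * track_length # exact arrival at the far end
    run_dir <- if (side == "L") "right" else "left"
    prun <- if (side == "L") dist else track_length - dist
    pos <- c(pos, pmin(pmax(prun, 0), track_length))
    spd <- c(spd, v)
    lab <- c(lab, rep("run", nrun)); dir <- c(dir, rep(run_dir, nrun))
    side <- if (side == "L") "R" else "L"
  }
  keep <- seq_len(n_frames)
  b <- data.frame(
    time = (keep - 1) * dt,
    position = pos[keep],
    head_direction = NA_real_,
    running_direction = factor(dir[keep], levels = c("left", "right", "none")),
    speed = spd[keep],
    behavior_label = factor(lab[keep], levels = c(
      "drink_L", "turn_L", "run", "turn_R", "drink_R", "rear")),
    episode = factor(rep("wake", n_frames), levels = c("wake", "rem")))
  attr(b, "track_length") <- track_length
  attr(b, "frame_rate") <- frame_rate
  attr(b, "track_mode") <- "linear"
  class(b) <- c("behavior_track", "data.frame")
  b
}

#' Per-frame traversal descriptors of a linear-track behavior record
#'
#' For every running frame, the trajectory phase (distance from the start
#' point of the current traversal), the time since the traversal started, the
#' traversal id, and the sign of the egocentric acceleration. Non-running
#' frames are `NA`.
#'
#' @param b a `behavior_track` from [gen_linear_track_session()].
#' @return data.frame with columns `phase` (cm), `t_start` (s),
#'   `traversal`, `accel_sign`.
#' @export
traversal_info <- function(b) {
  L <- attr(b, "track_length")
  run <- b$running_direction != "none"
  # traversal id: runs of consecutive running frames
  trav <- rep(NA_integer_, nrow(b))
  r <- rle(as.vector(run))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tid <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    tid <- tid + 1L
    trav[starts[i]:ends[i]] <- tid
  }
  phase <- ifelse(b$running_direction == "right", b$position, L - b$position)
  phase[!run] <- NA_real_
  t_start <- rep(NA_real_, nrow(b))
  accel <- rep(NA_real_, nrow(b))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    t_start[idx] <- b$time[idx] - b$time[idx[1]]
    v <- b$speed[idx]
    accel[idx] <- if (length(idx) > 1) sign(c(diff(v), tail(diff(v), 1)))
      else 0
  }
  data.frame(phase = phase, t_start = t_start, traversal = trav,
             accel_sign = accel)
}

# ---- planted tuning ---------------------------------------------------------

make_linear_truth <- function(mode, n_neurons, track_length, params) {
  frac <- params$fractions %||% if (mode == "ca1") {
    c(place = 0.6, phase = 0, drink = 0.1, turn = 0.1, untuned = 0.2)
  } else {
    c(place = 0, phase = 0.55, drink = 0.12, turn = 0.13, untuned = 0.2)
  }
  n_by <- round(frac * n_neurons)
  n_by["untuned"] <- n_neurons - sum(n_by[names(n_by) != "untuned"])
  cls <- rep(names(n_by), n_by)
  truth <- data.frame(
    neuron = seq_len(n_neurons), class = cls,
    pref = NA_real_, width = NA_real_, peak_rate = NA_real_,
    direction = "none", stringsAsFactors = FALSE)
  pk_range <- params$peak_rate %||% c(2, 4)
  wd_range <- params$field_width %||% c(6, 10)
  is_pl <- cls == "place"
  truth$pref[is_pl] <- runif(sum(is_pl), 0.04 * track_length,
                             0.96 * track_length)
  truth$width[is_pl] <- runif(sum(is_pl), wd_range[1], wd_range[2])
  truth$peak_rate[is_pl] <- runif(sum(is_pl), pk_range[1], pk_range[2])
  # a minority of place fields are direction-independent, as on real tracks
  bidir <- params$bidirectional_frac %||% 0.3
  truth$direction[is_pl] <- sample(c("left", "right", "both"), sum(is_pl),
                                   replace = TRUE,
                                   prob = c((1 - bidir) / 2, (1 - bidir) / 2,
                                            bidir))
  is_ph <- cls == "phase"
  truth$pref[is_ph] <- runif(sum(is_ph), 0.04 * track_length,
                             0.96 * track_length)
  truth$width[is_ph] <- runif(sum(is_ph), wd_range[1], wd_range[2])
  truth$peak_rate[is_ph] <- runif(sum(is_ph), pk_range[1], pk_range[2])
  for (cl in c("drink", "turn")) {
    is_c <- cls == cl
    truth$width[is_c] <- 1
    truth$peak_rate[is_c] <- runif(sum(is_c), pk_range[1], pk_range[2])
    # ca1: tuned to one end of the track; acc: same response at both ends
    truth$direction[is_c] <- if (mode == "ca1") {
      sample(c("left", "right"), sum(is_c), replace = TRUE)
    } else "none"
    truth$pref[is_c] <- ifelse(truth$direction[is_c] == "left", 0,
                               ifelse(truth$direction[is_c] == "right",
                                      track_length, NA_real_))
  }
  is_u <- cls == "untuned"
  truth$peak_rate[is_u] <- params$untuned_rate %||% 0.1
  truth
}

# Per-frame event rate (events/s) for every neuron given behavior and truth.
linear_rates <- function(behavior, truth, mode, params) {
  L <- attr(behavior, "track_length")
  base <- params$baseline_rate %||% 0.02
  asym <- params$direction_asymmetry %||% 0.1
  n_frames <- nrow(behavior)
  tinfo <- traversal_info(behavior)
  run <- behavior$running_direction != "none"
  rates <- matrix(base, nrow(truth), n_frames)
  lab <- as.character(behavior$behavior_label)
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class[i]
    if (cl == "place") {
      g <- exp(-(behavior$position - truth$pref[i])^2 /
                 (2 * truth$width[i]^2))
      sel <- if (truth$direction[i] == "both") as.numeric(run) else
        ifelse(as.character(behavior$running_direction) ==
                 truth$direction[i], 1,
               ifelse(run, asym, 0))
      rates[i, ] <- rates[i, ] + truth$peak_rate[i] * g * sel
    } else if (cl == "phase") {
      g <- exp(-(tinfo$phase - truth$pref[i])^2 / (2 * truth$width[i]^2))
      g[is.na(g)] <- 0
      rates[i, ] <- rates[i, ] + truth$peak_rate[i] * g
    } else if (cl == "drink") {
      on <- if (truth$direction[i] == "none") {
        lab %in% c("drink_L", "drink_R")
      } else {
        lab == paste0("drink_", if (truth$direction[i] == "left") "L" else "R")
      }
      # licking-related cells turn on only after arrival at the water port
      lat <- round((params$drink_onset_latency %||% 0.5) *
                     (attr(behavior, "frame_rate") %||% 20))
      if (lat > 0 && any(on)) {
        rr <- rle(on)
        re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1
        for (bi in which(rr$values)) {
          cut <- rs[bi]:min(re[bi], rs[bi] + lat - 1)
          on[cut] <- FALSE
        }
      }
      rates[i, on] <- rates[i, on] + truth$peak_rate[i]
    } else if (cl == "turn") {
      on <- if (truth$direction[i] == "none") {
        lab %in% c("turn_L", "turn_R", "rear")
      } else {
        lab == paste0("turn_", if (truth$direction[i] == "left") "L" else "R")
      }
      rates[i, on] <- rates[i, on] + truth$peak_rate[i]
    } else {
      rates[i, ] <- truth$peak_rate[i]
    }
  }
  rates
}

# Bernoulli events from rates; each event marks two consecutive frames active,
# mirroring the rise-time convention of the Ca2+ event detector.
rates_to_raster <- function(rates, dt, two_frame = TRUE) {
  p <- pmin(rates * dt, 1)
  ev <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p))
  if (two_frame && ncol(ev) > 1) {
    act <- ev
    act[, -1] <- pmax(act[, -1, drop = FALSE], ev[, -ncol(ev), drop = FALSE])
  } else act <- ev
  list(events = ev, active = act)
}

# ---- session generators -----------------------------------------------------

#' Generate a synthetic linear-track Ca2+ imaging session
#'
#' Simulates back-and-forth running on a 96 cm linear track with drinking and
#' turning pauses at both ends, and a population of neurons with planted
#' tuning. In `"ca1"` mode the tuned cells are direction-selective place cells
#' plus drink/turn cells responsive at one end only; in `"acc"` mode they are
#' trajectory-phase cells (tuning identical for the two running directions)
#' plus drink/turn cells responsive at both ends. Events are Bernoulli per
#' frame with probability rate x bin width; each event marks two consecutive
#' frames active, matching the event-detection convention downstream.
#'
#' @param mode `"ca1"` or `"acc"`.
#' @param n_neurons number of neurons (default 500).
#' @param duration session length in seconds (default 1080 s, i.e. six 3-min
#'   trials).
#' @param frame_rate imaging rate in Hz (20 for ca1, 10 for acc).
#' @param seed integer session seed; all randomness derives from it.
#' @param params optional list overriding generator defaults: `track_length`
#'   (96 cm), `peak_speed` (40 cm/s), `fractions`, `peak_rate`, `field_width`,
#'   `baseline_rate`, `direction_asymmetry`, `drink_mean`, `turn_mean`,
#'   `rear_prob`.
#' @return list with class `synthetic_session`: `behavior` (a
#'   `behavior_track` data.frame), `activity` (an [activity_matrix()]),
#'   `truth` (per-neuron planted tuning), `events` (the event raster before
#'   two-frame marking), `mode`, `seed`.
#' @export
gen_linear_track_session <- function(mode = c("ca1", "acc"), n_neurons = 500,
                                     duration = 1080,
                                     frame_rate = if (mode == "ca1") 20 else 10,
                                     seed = 1, params = list()) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (n_neurons < 1) stop("need at least one neuron")
  seeds <- split_seed(seed, 3)
  track_length <- params$track_length %||% 96
  set.seed(seeds[1])
  behavior <- simulate_track_behavior(
    duration, frame_rate, track_length,
    peak_speed = params$peak_speed %||% 40,
    drink_mean = params$drink_mean %||% 3,
    turn_mean = params$turn_mean %||% 1.5,
    rear_prob = params$rear_prob %||% 0)
  set.seed(seeds[2])
  truth <- make_linear_truth(mode, n_neurons, track_length, params)
  rates <- linear_rates(behavior, truth, mode, params)
  set.seed(seeds[3])
  rr <- rates_to_raster(rates, 1 / frame_rate)
  activity <- activity_matrix(rr$active, 1 / frame_rate, "imaging")
  structure(list(behavior = behavior, activity = activity, truth = truth,
                 events = rr$events, mode = mode, seed = seed),
            class = "synthetic_session")
}

#' Generate a synthetic head-direction electrophysiology session
#'
#' Heading follows a bounded-speed random walk on the circle during wake. REM
#' episodes freeze the actual head direction but drive the same cells with a
#' faster "virtual" heading trajectory following the same law. Spikes are
#' Poisson from von Mises-shaped tuning curves, binned (100 ms default) and
#' binarized; the ephys activity filter retains bins with at least 15 active
#' cells.
#'
#' @param n_neurons number of cells (default 50).
#' @param duration session length in seconds (default 1800).
#' @param bin_width bin width in seconds (default 0.1).
#' @param seed integer session seed.
#' @param rem_fraction fraction of the session spent in REM episodes, in
#'   `[0, 1)`.
#' @param params overrides: `peak_rate` range (Hz), `kappa` range (von Mises
#'   concentration), `base_rate`, `omega_max` (wake angular speed bound,
#'   rad/s), `rem_speed_factor` (default 2), `rem_episode` (s).
#' @return `synthetic_session` list: `behavior` (with `head_direction` the
#'   actual heading, `drive_direction` the heading driving the cells --
#'   identical during wake, virtual during REM), `activity`, `truth`.
#' @export
gen_hd_session <- function(n_neurons = 50, duration = 1800, bin_width = 0.1,
                           seed = 1, rem_fraction = 0.25, params = list()) {
  if (rem_fraction < 0 || rem_fraction >= 1)
    stop("rem_fraction must be in [0, 1)")
  if (bin_width <= 0) stop("bin_width must be positive")
  n_bins <- round(duration / bin_width)
  seeds <- split_seed(seed, 3)
  if (n_bins == 0) {
    b <- data.frame(time = numeric(0), position = numeric(0),
                    head_direction = numeric(0),
                    drive_direction = numeric(0),
                    running_direction = factor(character(0),
                      levels = c("left", "right", "none")),
                    speed = numeric(0),
                    behavior_label = factor(character(0)),
                    episode = factor(character(0), levels = c("wake", "rem")))
    class(b) <- c("behavior_track", "data.frame")
    truth <- data.frame(neuron = integer(0))
    return(structure(list(
      behavior = b,
      activity = activity_matrix(matrix(0L, n_neurons, 0), bin_width, "ephys"),
      truth = truth, mode = "hd", seed = seed), class = "synthetic_session"))
  }
  omega_max <- params$omega_max %||% 3
  rem_factor <- params$rem_speed_factor %||% 2
  rem_len <- params$rem_episode %||% 60
  # episode layout: REM bouts of ~rem_len seconds spread through the session
  episode <- rep("wake", n_bins)
  if (rem_fraction > 0) {
    n_rem_bins <- round(rem_fraction * n_bins)
    bout <- max(1L, round(rem_len / bin_width))
    n_bouts <- max(1L, round(n_rem_bins / bout))
    starts <- round(seq(0.2, 0.95, length.out = n_bouts) * n_bins - bout)
    for (s in starts) {
      idx <- pmax(1L, s):min(n_bins, s + bout - 1L)
      episode[idx] <- "rem"
    }
  }
  set.seed(seeds[1])
  # bounded-speed angular random walk; the same law (x rem_factor) during REM
  omega <- numeric(n_bins)
  theta_drive <- numeric(n_bins)
  sig <- params$omega_sd %||% 0.6
  th <- runif(1, 0, 2 * pi)
  om <- 0
  for (t in seq_len(n_bins)) {
    om <- 0.97 * om + rnorm(1, 0, sig)
    om <- pmin(pmax(om, -omega_max), omega_max)
    fac <- if (episode[t] == "rem") rem_factor else 1
    th <- (th + fac * om * bin_width) %% (2 * pi)
    omega[t] <- om
    theta_drive[t] <- th
  }
  head_dir <- theta_drive
  # actual head direction is frozen during sleep
  for (t in seq_len(n_bins)) {
    if (episode[t] == "rem") head_dir[t] <- head_dir[max(1, t - 1)]
  }
  set.seed(seeds[2])
  kappa <- params$kappa %||% c(2, 5)
  peak <- params$peak_rate %||% c(20, 45)
  truth <- data.frame(
    neuron = seq_len(n_neurons), class = "hd",
    pref = runif(n_neurons, 0, 2 * pi),
    width = runif(n_neurons, kappa[1], kappa[2]),
    peak_rate = runif(n_neurons, peak[1], peak[2]),
    direction = "none", stringsAsFactors = FALSE)
  base <- params$base_rate %||% 1
  set.seed(seeds[3])
  rates <- base + truth$peak_rate *
    exp(truth$width * (cos(outer(truth$pref, theta_drive, function(p, th)
      th - p)) - 1))
  spikes <- matrix(rpois(length(rates), rates * bin_width),
                   nrow(rates), ncol(rates))
  activity <- activity_matrix(matrix(as.integer(spikes > 0), nrow(spikes),
                                     ncol(spikes)), bin_width, "ephys")
  b <- data.frame(
    time = (seq_len(n_bins) - 1) * bin_width,
    position = NA_real_,
    head_direction = head_dir,
    drive_direction = theta_drive,
    running_direction = factor(rep("none", n_bins),
                               levels = c("left", "right", "none")),
    speed = abs(omega),
    behavior_label = factor(rep("run", n_bins), levels = c(
      "drink_L", "turn_L", "run", "turn_R", "drink_R", "rear")),
    episode = factor(episode, levels = c("wake", "rem")))
  attr(b, "track_mode") <- "ring"
  attr(b, "frame_rate") <- 1 / bin_width
  class(b) <- c("behavior_track", "data.frame")
  structure(list(behavior = b, activity = activity, truth = truth,
                 spikes = spikes, mode = "hd", seed = seed),
            class = "synthetic_session")
}

#' Synthesize GCaMP6-like fluorescence traces from an event raster
#'
#' Convolves the event train of each neuron with a rise-plus-exponential-decay
#' transient kernel, then adds slow baseline drift and white noise. The decay
#' time constant defaults to the indicator's nominal value (600 ms GCaMP6s,
#' 200 ms GCaMP6f).
#'
#' @param events an [activity_matrix()] or binary matrix of event onsets.
#' @param indicator `"GCaMP6s"` or `"GCaMP6f"`.
#' @param noise_sd white-noise SD in dF/F0 units (default 0.01).
#' @param seed integer seed.
#' @param amplitude mean event peak amplitude in dF/F0 units (default 0.1);
#'   per-event amplitudes are lognormal around it.
#' @param decay decay time constant in seconds (default by indicator).
#' @param rise rise time constant in seconds (default 0.05).
#' @param drift_sd SD of the slow baseline drift (default 0.005).
#' @return a `fluorescence_traces` object: list with `traces` (neurons x
#'   frames dF/F0), `frame_rate`, `indicator`.
#' @export
gen_fluorescence_traces <- function(events, indicator = c("GCaMP6s", "GCaMP6f"),
                                    noise_sd = 0.01, seed = 1,
                                    amplitude = 0.1, decay = NULL,
                                    rise = 0.05, drift_sd = 0.005) {
  indicator <- match.arg(indicator)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (inherits(events, "activity_matrix")) {
    frame_rate <- 1 / events$bin_width
    ev <- events$values
  } else {
    frame_rate <- attr(events, "frame_rate") %||% 20
    ev <- events
  }
  decay <- decay %||% if (indicator == "GCaMP6s") 0.6 else 0.2
  dt <- 1 / frame_rate
  klen <- ceiling(6 * decay / dt)
  tk <- (0:klen) * dt
  kern <- (1 - exp(-tk / rise)) * exp(-tk / decay)
  kern <- kern / max(kern)
  set.seed(as.integer(seed))
  n <- nrow(ev); K <- ncol(ev)
  traces <- matrix(0, n, K)
  for (i in seq_len(n)) {
    tr <- numeric(K + klen)
    at <- which(ev[i, ] != 0)
    if (length(at)) {
      amps <- rlnorm(length(at), log(amplitude), 0.2)
      for (a in seq_along(at)) {
        idx <- at[a]:(at[a] + klen)
        tr[idx] <- tr[idx] + amps[a] * kern
      }
    }
    drift <- cumsum(rnorm(K, 0, drift_sd * dt))
    drift <- drift - mean(drift)
    traces[i, ] <- tr[seq_len(K)] + drift + rnorm(K, 0, noise_sd)
  }
  structure(list(traces = traces, frame_rate = frame_rate,
                 indicator = indicator), class = "fluorescence_traces")
}

#' Generate multiday sessions with partial cell turnover
#'
#' Repeats a linear-track session on several days. The planted tuning of every
#' neuron is generated once and preserved; on each day only a subset of the
#' master population is active (detected), emulating day-to-day turnover of
#' the imaged roster. A neuron active on one day is active on another with
#' probability equal to that day's overlap level, so the measured pairwise
#' roster overlap matches the requested value in expectation.
#'
#' @param base list of arguments for [gen_linear_track_session()] (`mode`,
#'   `n_neurons`, `duration`, `frame_rate`, `params`).
#' @param n_days number of days (at least 2).
#' @param overlap either a single fraction in (0, 1] or a range (default
#'   `c(0.41, 0.64)`) from which each day's roster inclusion probability is
#'   drawn.
#' @param seed integer master seed.
#' @return list of `synthetic_session`s, each with an extra `roster` element
#'   (indices of active neurons that day); rows of inactive neurons are zero.
#' @export
gen_multiday_sessions <- function(base = list(), n_days = 4,
                                  overlap = c(0.41, 0.64), seed = 1) {
  if (n_days < 2) stop("need at least 2 days")
  if (any(overlap <= 0) || any(overlap > 1))
    stop("overlap must be in (0, 1]")
  mode <- base$mode %||% "ca1"
  n_neurons <- base$n_neurons %||% 500
  frame_rate <- base$frame_rate %||% if (mode == "ca1") 20 else 10
  duration <- base$duration %||% 1080
  params <- base$params %||% list()
  track_length <- params$track_length %||% 96
  seeds <- split_seed(seed, 2 * n_days + 2)
  set.seed(seeds[1])
  truth <- make_linear_truth(mode, n_neurons, track_length, params)
  set.seed(seeds[2])
  q <- if (length(overlap) == 1) rep(overlap, n_days) else
    runif(n_days, overlap[1], overlap[2])
  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    set.seed(seeds[2 * d + 1])
    roster <- which(runif(n_neurons) < q[d])
    behavior <- simulate_track_behavior(
      duration, frame_rate, track_length,
      peak_speed = params$peak_speed %||% 40,
      drink_mean = params$drink_mean %||% 3,
      turn_mean = params$turn_mean %||% 1.5,
      rear_prob = params$rear_prob %||% 0)
    rates <- linear_rates(behavior, truth, mode, params)
    off <- setdiff(seq_len(n_neurons), roster)
    rates[off, ] <- 0
    set.seed(seeds[2 * d + 2])
    rr <- rates_to_raster(rates, 1 / frame_rate)
    out[[d]] <- structure(
      list(behavior = behavior,
           activity = activity_matrix(rr$active, 1 / frame_rate, "imaging"),
           truth = truth, events = rr$events, roster = roster,
           mode = mode, seed = seed, day = d),
      class = "synthetic_session")
  }
  out
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> mode=%s, %d neurons, %d frames, seed=%d\n",
              x$mode, x$activity$n_neurons, x$activity$n_bins, x$seed))
  invisible(x)
}

# ---- plain-text session I/O -------------------------------------------------

#' Write / read a synthetic session as CSV + JSON
#'
#' Long-format event list (`neuron`, `frame`), per-frame behavior table, the
#' planted-tuning table, and a JSON metadata sidecar.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @return `write_session_csv` returns `dir` invisibly; `read_session_csv`
#'   returns a `synthetic_session`.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- which(session$activity$values != 0, arr.ind = TRUE)
  utils::write.csv(data.frame(neuron = ev[, 1], frame = ev[, 2]),
                   file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$behavior),
                   file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(session$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  meta <- list(mode = session$mode, seed = session$seed,
               n_neurons = session$activity$n_neurons,
               n_bins = session$activity$n_bins,
               bin_width = session$activity$bin_width,
               modality = session$activity$modality,
               track_length = attr(session$behavior, "track_length"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  m <- build_activity_matrix(ev, meta$bin_width, meta$modality,
                             n_neurons = meta$n_neurons,
                             n_bins = meta$n_bins)
  behavior$running_direction <- factor(behavior$running_direction,
                                       levels = c("left", "right", "none"))
  behavior$episode <- factor(behavior$episode, levels = c("wake", "rem"))
  attr(behavior, "track_length") <- meta$track_length
  class(behavior) <- c("behavior_track", "data.frame")
  structure(list(behavior = behavior, activity = m, truth = truth,
                 mode = meta$mode, seed = meta$seed),
            class = "synthetic_session")
}
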