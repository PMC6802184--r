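#' Reconstruct the encoded variable from ordered states
#'
#' Parameterizes the network states: in linear mode the ordered sub-cluster
#' `k` of `M` receives the internal position `(k-1)/(M-1)` in `[0, 1]`; in
#' circular mode cluster `k` receives the internal angle `2*pi*k/M`, and the
#' per-frame angle series is smoothed with a truncated Gaussian kernel
#' (sigma = 2 frames, 5-frame support) applied to the unit vectors. When an
#' external reference is supplied, the residual gauge freedom (reflection for
#' a line; rotation and reflection for a ring) is fixed by minimizing the
#' global mean squared error, and the per-frame mismatch is reported --
#' `x_hat - x` for positions, `mod(theta_hat - theta + pi, 2*pi) - pi` for
#' angles.
#'
#' @param labels per-frame state ids.
#' @param ordering state ordering from [order_states()] (vector of state ids).
#' @param mode `"linear"` or `"circular"`.
#' @param frame_index original frame index per label.
#' @param external optional per-frame external variable (same length as
#'   `labels`): position (any units, rescaled to `[0, 1]`) or angle in
#'   radians.
#' @param smooth_sigma,smooth_size temporal smoothing kernel (circular mode).
#' @return an `internal_trajectory`: list with `value` (per frame), `mode`,
#'   `state_rank` (pre-smoothing ordinal state), `gauge` (list `reflected`,
#'   `rotation`), `error_series`, `frame_index`, `M`.
#' @export
reconstruct_internal_variable <- function(labels, ordering,
                                          mode = c("linear", "circular"),
                                          frame_index = seq_along(labels),
                                          external = NULL, smooth_sigma = 2,
                                          smooth_size = 5) {
  mode <- match.arg(mode)
  if (is.null(ordering)) stop("state ordering is required")
  ordering <- if (is.list(ordering)) ordering$ordering else ordering
  M <- length(ordering)
  rank_of <- integer(max(ordering))
  rank_of[ordering] <- seq_len(M)
  state_rank <- ifelse(is.na(labels), NA_integer_, rank_of[labels])
  gauge <- list(reflected = FALSE, rotation = 0)
  err <- NULL
  if (mode == "linear") {
    value <- (state_rank - 1) / (M - 1)
    if (!is.null(external)) {
      ok <- !is.na(value) & !is.na(external)
      lo <- min(external[ok]); hi <- max(external[ok])
      xs <- if (hi > lo) (external - lo) / (hi - lo) else external * 0
      mse_id <- mean((value[ok] - xs[ok])^2)
      mse_rf <- mean((1 - value[ok] - xs[ok])^2)
      if (mse_rf < mse_id) {
        value <- 1 - value
        gauge$reflected <- TRUE
      }
      err <- value - xs
    }
  } else {
    theta <- 2 * pi * state_rank / M
    value <- smooth_circular_series(theta, smooth_sigma, smooth_size)
    if (!is.null(external)) {
      ok <- !is.na(value) & !is.na(external)
      fit <- best_circular_gauge(value[ok], external[ok])
      gauge <- fit$gauge
      value <- apply_circular_gauge(value, gauge)
      err <- circ_diff(value, external)
      err[!ok] <- NA_real_
    }
  }
  structure(list(value = value, mode = mode, state_rank = state_rank,
                 gauge = gauge, error_series = err,
                 frame_index = frame_index, M = M),
            class = "internal_trajectory")
}

apply_circular_gauge <- function(theta, gauge) {
  s <- if (gauge$reflected) -1 else 1
  (s * theta + gauge$rotation) %% (2 * pi)
}

# grid search over rotation x reflection minimizing circular MSE
best_circular_gauge <- function(theta_hat, theta, n_grid = 360) {
  offs <- 2 * pi * (seq_len(n_grid) - 1) / n_grid
  best <- list(mse = Inf)
  for (refl in c(FALSE, TRUE)) {
    base <- if (refl) -theta_hat else theta_hat
    for (o in offs) {
      e <- circ_diff(base + o, theta)
      m <- mean(e^2)
      if (m < best$mse) best <- list(mse = m,
                                     gauge = list(reflected = refl,
                                                  rotation = o))
    }
  }
  best
}

new_tuning_curve <- function(bin_centers, occupancy, counts, rate, rate_raw,
                             mode, source, neuron = NA_integer_,
                             excluded = FALSE, reason = NULL) {
  structure(list(bin_centers = bin_centers, occupancy = occupancy,
                 counts = counts, rate = rate, rate_raw = rate_raw,
                 mode = mode, source = source,
                 n_events = sum(counts, na.rm = TRUE), neuron = neuron,
                 excluded = excluded, reason = reason),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<tuning_curve> neuron %s excluded (%s)\n", x$neuron,
                x$reason))
  } else {
    cat(sprintf(
      "<tuning_curve> %s/%s: %d bins, %d events, peak %.3g events/s\n",
      x$source, x$mode, length(x$bin_centers), x$n_events,
      max(x$rate, na.rm = TRUE)))
  }
  invisible(x)
}

smooth_map <- function(x, sigma = 1.5, size = 5, circular = FALSE) {
  smooth_series(x, sigma, size, circular)
}

#' Internal tuning curve of one neuron
#'
#' Event rate of a neuron as a function of the internal state of the network.
#' Linear mode: occupancy and event counts are accumulated per ordered
#' sub-cluster, interpolated (linearly in ordered-state index) to `n_bins`
#' spatial bins, smoothed with a truncated Gaussian kernel (sigma = 1.5 bins,
#' 5-bin support), and divided. Circular mode: the smoothed internal angle is
#' binned into 40 bins of 9 degrees and the rate is counts over occupancy.
#' Neurons with 5 or fewer events within the relevant states are excluded.
#'
#' @param m an [activity_matrix()].
#' @param traj an `internal_trajectory` from
#'   [reconstruct_internal_variable()].
#' @param neuron neuron index.
#' @param n_bins output bins for the linear variant (20 by the track-bin
#'   convention; circular always uses 40).
#' @param min_events exclusion threshold (more than 5 events required).
#' @param frames optional subset of original bin indices (e.g. only REM
#'   frames) over which occupancy and events are accumulated.
#' @return a `tuning_curve` (`excluded` set when the neuron has too few
#'   events).
#' @export
internal_tuning_curve <- function(m, traj, neuron, n_bins = 20,
                                  min_events = 6, frames = NULL) {
  if (!is.null(frames)) {
    keep <- traj$frame_index %in% frames
    traj$frame_index <- traj$frame_index[keep]
    traj$value <- traj$value[keep]
    traj$state_rank <- traj$state_rank[keep]
  }
  act <- m$values[neuron, traj$frame_index]
  n_ev <- sum(act, na.rm = TRUE)
  if (n_ev < min_events) {
    return(new_tuning_curve(numeric(0), numeric(0), numeric(0), numeric(0),
                            numeric(0), traj$mode, "internal", neuron,
                            excluded = TRUE,
                            reason = sprintf("%d events < %d", n_ev,
                                             min_events)))
  }
  if (traj$mode == "linear") {
    M <- traj$M
    occ <- counts <- numeric(M)
    for (k in seq_len(M)) {
      sel <- which(traj$state_rank == k)
      occ[k] <- length(sel) * m$bin_width
      counts[k] <- sum(act[sel])
    }
    pos_states <- (seq_len(M) - 1) / (M - 1)
    centers <- (seq_len(n_bins) - 0.5) / n_bins
    occ_i <- approx(pos_states, occ, xout = centers, rule = 2)$y
    cnt_i <- approx(pos_states, counts, xout = centers, rule = 2)$y
    occ_s <- smooth_map(occ_i)
    cnt_s <- smooth_map(cnt_i)
    rate <- ifelse(occ_s > 0, cnt_s / occ_s, NA_real_)
    rate_raw <- ifelse(occ_i > 0, cnt_i / occ_i, NA_real_)
    new_tuning_curve(centers, occ_i, cnt_i, rate, rate_raw, "linear",
                     "internal", neuron)
  } else {
    nb <- 40
    br <- seq(0, 2 * pi, length.out = nb + 1)
    bin <- findInterval(traj$value %% (2 * pi), br, rightmost.closed = TRUE)
    occ <- counts <- numeric(nb)
    for (k in seq_len(nb)) {
      sel <- which(bin == k)
      occ[k] <- length(sel) * m$bin_width
      counts[k] <- sum(act[sel])
    }
    rate <- ifelse(occ > 0, counts / occ, NA_real_)
    centers <- (br[-1] + br[-(nb + 1)]) / 2
    new_tuning_curve(centers, occ, counts, rate, rate, "circular",
                     "internal", neuron)
  }
}

#' External tuning curve of one neuron
#'
#' Classical tuning to a measured variable. Position: per running direction,
#' the track is divided into 24 bins (4 cm each), the last 2 bins at both
#' ends are excluded, only frames with speed above 1 cm/s count, and the
#' occupancy and event-count maps are smoothed (truncated Gaussian,
#' sigma = 1.5 bins, 5-bin support) before division. Phase: both running
#' directions are pooled after flipping the positional indexing of one
#' direction, same binning. Angle: head direction in 40 bins of 9 degrees,
#' no edge exclusion or smoothing.
#'
#' @param m an [activity_matrix()].
#' @param b a `behavior_track`.
#' @param neuron neuron index.
#' @param variable `"position"`, `"phase"`, or `"angle"`.
#' @param direction `"right"`, `"left"` (position only), or `"both"` (returns
#'   a list of the two per-direction curves).
#' @param frames optional frame subset (e.g. wake episodes for angle curves).
#' @param n_bins track bins before edge exclusion (24).
#' @param edge_bins bins excluded at each end (2).
#' @param speed_threshold running-speed filter in cm/s (1).
#' @return a `tuning_curve`, or a list `right`/`left` when
#'   `direction = "both"`.
#' @export
external_tuning_curve <- function(m, b, neuron,
                                  variable = c("position", "phase", "angle"),
                                  direction = "both", frames = NULL,
                                  n_bins = 24, edge_bins = 2,
                                  speed_threshold = 1) {
  variable <- match.arg(variable)
  L <- attr(b, "track_length") %||% 96
  act <- m$values[neuron, ]
  if (variable == "angle") {
    nb <- 40
    idx <- frames %||% seq_len(nrow(b))
    br <- seq(0, 2 * pi, length.out = nb + 1)
    bin <- findInterval(b$head_direction[idx] %% (2 * pi), br,
                        rightmost.closed = TRUE)
    occ <- counts <- numeric(nb)
    for (k in seq_len(nb)) {
      sel <- idx[which(bin == k)]
      occ[k] <- length(sel) * m$bin_width
      counts[k] <- sum(act[sel])
    }
    rate <- ifelse(occ > 0, counts / occ, NA_real_)
    centers <- (br[-1] + br[-(nb + 1)]) / 2
    return(new_tuning_curve(centers, occ, counts, rate, rate, "circular",
                            "external", neuron))
  }
  if (variable == "position" && identical(direction, "both")) {
    return(list(
      right = external_tuning_curve(m, b, neuron, "position", "right",
                                    frames, n_bins, edge_bins,
                                    speed_threshold),
      left = external_tuning_curve(m, b, neuron, "position", "left", frames,
                                   n_bins, edge_bins, speed_threshold)))
  }
  running <- b$running_direction != "none" & b$speed > speed_threshold
  if (!is.null(frames)) running <- running & seq_len(nrow(b)) %in% frames
  if (variable == "position") {
    sel <- which(running & b$running_direction == direction)
    x <- b$position[sel]
  } else {
    sel <- which(running)
    x <- ifelse(b$running_direction[sel] == "right", b$position[sel],
                L - b$position[sel])
  }
  keep_bins <- (edge_bins + 1):(n_bins - edge_bins)
  br <- seq(0, L, length.out = n_bins + 1)
  centers_all <- (br[-1] + br[-(n_bins + 1)]) / 2
  if (!length(sel)) {
    k <- length(keep_bins)
    return(new_tuning_curve(centers_all[keep_bins], rep(0, k), rep(0, k),
                            rep(NA_real_, k), rep(NA_real_, k), "linear",
                            "external", neuron, excluded = TRUE,
                            reason = "no running frames"))
  }
  bin <- findInterval(pmin(pmax(x, 0), L), br, rightmost.closed = TRUE)
  occ <- counts <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    ss <- sel[bin == k]
    occ[k] <- length(ss) * m$bin_width
    counts[k] <- sum(act[ss])
  }
  occ <- occ[keep_bins]; counts <- counts[keep_bins]
  occ_s <- smooth_map(occ); cnt_s <- smooth_map(counts)
  rate <- ifelse(occ_s > 0, cnt_s / occ_s, NA_real_)
  rate_raw <- ifelse(occ > 0, counts / occ, NA_real_)
  new_tuning_curve(centers_all[keep_bins], occ, counts, rate, rate_raw,
                   "linear", "external", neuron)
}

#' Information per event of a tuning curve, with shuffle significance
#'
#' Computes `sum_i p_i (r_i / rbar) log2(r_i / rbar)` in bits per event on
#' the unsmoothed rate map, where `p_i` is the occupancy probability of bin
#' `i`, `r_i` the event rate in bin `i`, and `rbar` the overall mean rate.
#' The shuffle null redraws each event's bin from the occupancy
#' distribution (accounting for coverage statistics); a cell is significant
#' when its information exceeds strictly more than 95% of its shuffles.
#'
#' @param curve a `tuning_curve` (needs raw `occupancy` and `counts`).
#' @param n_shuffles number of shuffles (1000).
#' @param seed integer seed.
#' @param min_events minimum events (5).
#' @return list with `information` (bits/event), `p_value`, `significant`,
#'   `shuffles`.
#' @export
information_per_event <- function(curve, n_shuffles = 1000, seed = 1,
                                  min_events = 5) {
  occ <- curve$occupancy; counts <- curve$counts
  ok <- occ > 0
  n_ev <- sum(counts)
  if (n_ev < min_events || !any(ok))
    return(list(information = NA_real_, p_value = NA_real_,
                significant = NA, shuffles = numeric(0)))
  info_of <- function(cnt) {
    p <- occ[ok] / sum(occ[ok])
    r <- cnt[ok] / occ[ok]
    rbar <- sum(cnt[ok]) / sum(occ[ok])
    term <- p * (r / rbar) * log2(r / rbar)
    sum(term[r > 0])
  }
  obs <- info_of(counts)
  set.seed(as.integer(seed))
  p_occ <- occ / sum(occ)
  shuf <- vapply(seq_len(n_shuffles), function(s) {
    info_of(as.numeric(stats::rmultinom(1, n_ev, p_occ)))
  }, numeric(1))
  list(information = obs,
       p_value = (1 + sum(shuf >= obs)) / (n_shuffles + 1),
       significant = mean(shuf < obs) > 0.95,
       shuffles = shuf)
}

#' Field width and Rayleigh vector of a tuning curve
#'
#' Width: number of bins contiguous with the peak whose rate exceeds half the
#' maximum (wrapping around for circular curves). For circular curves, the
#' Rayleigh vector `sum_k r(theta_k) e^(i theta_k) / sum_k r(theta_k)` gives
#' the preferred direction (its angle) and the directionality (its length).
#'
#' @param curve a `tuning_curve`.
#' @return list with `width` (bins), `peak_bin`, `rayleigh_length`,
#'   `preferred` (radians; circular curves only).
#' @export
field_stats <- function(curve) {
  r <- curve$rate
  if (!length(r) || all(is.na(r)) || all(r == 0, na.rm = TRUE))
    return(list(width = NA_integer_, peak_bin = NA_integer_,
                rayleigh_length = NA_real_, preferred = NA_real_))
  r0 <- ifelse(is.na(r), 0, r)
  pk <- which.max(r0)
  half <- r0[pk] / 2
  nb <- length(r0)
  width <- 1L
  if (curve$mode == "circular") {
    i <- pk
    repeat {
      i <- (i %% nb) + 1
      if (i == pk || r0[i] <= half) break
      width <- width + 1L
    }
    i <- pk
    repeat {
      i <- ((i - 2) %% nb) + 1
      if (i == pk || r0[i] <= half) break
      width <- width + 1L
    }
    width <- min(width, nb)
    th <- curve$bin_centers
    len <- Mod(sum(r0 * exp(1i * th))) / sum(r0)
    pref <- atan2(sum(r0 * sin(th)), sum(r0 * cos(th))) %% (2 * pi)
  } else {
    i <- pk
    while (i < nb && r0[i + 1] > half) { width <- width + 1L; i <- i + 1 }
    i <- pk
    while (i > 1 && r0[i - 1] > half) { width <- width + 1L; i <- i - 1 }
    len <- NA_real_; pref <- NA_real_
  }
  list(width = width, peak_bin = pk, rayleigh_length = len, preferred = pref)
}

#' Bidirectionality of a cell's rate maps
#'
#' Normalized overlap between the rate maps of the two running directions:
#' `2 sum_i min(Pr(i), Pl(i)) / sum_i (Pr(i) + Pl(i))` with
#' `P(i) = N_bins r(i) / sum_i r(i)`. The value is 1 for identical
#' normalized maps and 0 for disjoint supports. The phase-flipped variant
#' reverses the bin order of one direction first, testing trajectory-phase
#' coding.
#'
#' @param map_right,map_left `tuning_curve`s of the two running directions.
#' @param variant `"position"` or `"phase-flipped"`.
#' @param min_events minimum events per direction (5).
#' @return overlap value in `[0, 1]`, or `NA` when a map is undefined.
#' @export
bidirectionality <- function(map_right, map_left,
                             variant = c("position", "phase-flipped"),
                             min_events = 5) {
  variant <- match.arg(variant)
  r <- map_right$rate; l <- map_left$rate
  if (variant == "phase-flipped") l <- rev(l)
  r[is.na(r)] <- 0; l[is.na(l)] <- 0
  if (sum(map_right$counts) < min_events ||
      sum(map_left$counts) < min_events || sum(r) == 0 || sum(l) == 0)
    return(NA_real_)
  nb <- length(r)
  Pr <- nb * r / sum(r)
  Pl <- nb * l / sum(l)
  2 * sum(pmin(Pr, Pl)) / sum(Pr + Pl)
}

#' Leave-one-out internal information of a neuron
#'
#' Embeds the population while excluding the neuron from the activity
#' vectors, clusters the reduced space into `n_states` network states
#' (K-means), computes the information between the held-out neuron's events
#' and the state occupancy (same expression as spatial information), and
#' subtracts the average information of time-shuffled versions of the cell,
#' correcting for state-dwell statistics.
#'
#' @param m an [activity_matrix()].
#' @param neuron held-out neuron index.
#' @param n_states number of internal states (8, matching 8 external bins).
#' @param n_shuffles shuffles of the held-out cell (100).
#' @param p1,p2 embedding neighbor fractions.
#' @param seed integer seed.
#' @param min_events minimum events within the embedded frames (5).
#' @return list with `information` (raw bits/event), `corrected`
#'   (shuffle-subtracted), `shuffles`, `labels`.
#' @export
internal_information_loo <- function(m, neuron, n_states = 8,
                                     n_shuffles = 100, p1 = 0.00375,
                                     p2 = 0.1125, seed = 1, min_events = 5) {
  v <- m$values[-neuron, , drop = FALSE]
  m_loo <- activity_matrix(v, m$bin_width, m$modality)
  emb <- embed_two_stage(m_loo, p1, p2)
  s <- cluster_states(emb, "kmeans", k = n_states, seed = seed)
  act <- m$values[neuron, emb$frame_index]
  if (sum(act) < min_events)
    return(list(information = NA_real_, corrected = NA_real_,
                shuffles = numeric(0), labels = s$labels))
  occ <- vapply(seq_len(n_states),
                function(k) sum(s$labels == k) * m$bin_width, numeric(1))
  cnt_of <- function(a) vapply(seq_len(n_states),
                               function(k) sum(a[s$labels == k]), numeric(1))
  info_of <- function(cnt) {
    ok <- occ > 0
    p <- occ[ok] / sum(occ[ok])
    r <- cnt[ok] / occ[ok]
    rbar <- sum(cnt[ok]) / sum(occ[ok])
    if (rbar == 0) return(0)
    term <- p * (r / rbar) * log2(r / rbar)
    sum(term[r > 0])
  }
  obs <- info_of(cnt_of(act))
  set.seed(as.integer(seed))
  n_fr <- length(act); n_act <- sum(act)
  shuf <- vapply(seq_len(n_shuffles), function(i) {
    a <- integer(n_fr)
    a[sample.int(n_fr, n_act)] <- 1L
    info_of(cnt_of(a))
  }, numeric(1))
  list(information = obs, corrected = obs - mean(shuf), shuffles = shuf,
       labels = s$labels)
}
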