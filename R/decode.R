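new_decode_result <- function(decoded, actual, mode, gauge = NULL,
                              explained_variance = NULL) {
  err <- if (!is.null(actual)) {
    if (mode == "circular") circ_diff(decoded, actual) else decoded - actual
  }
  mse <- if (!is.null(err)) mean(err^2, na.rm = TRUE)
  structure(list(decoded = decoded, actual = actual, error_series = err,
                 mse = mse, explained_variance = explained_variance,
                 gauge = gauge, shuffle_p = NULL, mode = mode),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s: %d frames, mse = %.4g%s%s\n", x$mode,
              length(x$decoded), x$mse %||% NA,
              if (!is.null(x$explained_variance))
                sprintf(", EV = %.3f", x$explained_variance) else "",
              if (!is.null(x$shuffle_p))
                sprintf(", p = %.4g", x$shuffle_p) else ""))
  invisible(x)
}

# reflect a linear decode expressed on bin values in [lo, hi]
reflect_linear <- function(x, lo, hi) hi + lo - x

fit_decode_gauge <- function(decoded, actual, mode, bin_values = NULL) {
  if (mode == "circular") {
    offs <- if (!is.null(bin_values)) bin_values - bin_values[1] else
      2 * pi * (0:359) / 360
    best <- list(mse = Inf)
    for (refl in c(FALSE, TRUE)) {
      base <- if (refl) -decoded else decoded
      for (o in offs) {
        e <- circ_diff(base + o, actual)
        msev <- mean(e^2, na.rm = TRUE)
        if (msev < best$mse)
          best <- list(mse = msev, decoded = (base + o) %% (2 * pi),
                       gauge = list(reflected = refl, rotation = o))
      }
    }
    best
  } else {
    lo <- min(bin_values %||% decoded, na.rm = TRUE)
    hi <- max(bin_values %||% decoded, na.rm = TRUE)
    cand <- list(list(mse = mean((decoded - actual)^2, na.rm = TRUE),
                      decoded = decoded,
                      gauge = list(reflected = FALSE, rotation = 0)),
                 list(mse = mean((reflect_linear(decoded, lo, hi) - actual)^2,
                                 na.rm = TRUE),
                      decoded = reflect_linear(decoded, lo, hi),
                      gauge = list(reflected = TRUE, rotation = 0)))
    cand[[which.min(c(cand[[1]]$mse, cand[[2]]$mse))]]
  }
}

#' Maximum-likelihood population decoder
#'
#' Decodes the encoded variable frame by frame from a set of tuning curves,
#' assuming independent Poisson event counts: the decoded bin maximizes
#' `sum_i [n_i log(lambda_i(b) dt) - lambda_i(b) dt]` with a small rate floor.
#' Tuning curves may come from any source -- external wake curves for
#' decoding REM "virtual" trajectories, or internal REM curves for decoding
#' wake behavior. When a comparison series is supplied, the residual gauge
#' (rotation and reflection for a ring, reflection for a line) is fixed by
#' minimizing the mean squared error.
#'
#' @param test an [activity_matrix()] or binary matrix (neurons x frames).
#' @param curves matrix of rates (neurons x bins, events/s) or list of
#'   `tuning_curve`s over a common bin grid.
#' @param mode `"circular"` or `"linear"`.
#' @param bin_values values of the decoder bins (default: the curves' bin
#'   centers).
#' @param actual optional per-frame comparison series for gauge fixing and
#'   error statistics.
#' @param frames frame subset of `test` to decode.
#' @param bin_width bin width in seconds (taken from `test` if available).
#' @param rate_floor minimum rate in events/s (1e-3).
#' @return a `decode_result`; frames with no active neuron decode to `NA` and
#'   are excluded from error statistics.
#' @export
ml_decode <- function(test, curves, mode = c("circular", "linear"),
                      bin_values = NULL, actual = NULL, frames = NULL,
                      bin_width = NULL, rate_floor = 1e-3) {
  mode <- match.arg(mode)
  if (inherits(test, "activity_matrix")) {
    bin_width <- bin_width %||% test$bin_width
    X <- test$values
  } else X <- test
  bin_width <- bin_width %||% 1
  if (is.list(curves) && !is.matrix(curves)) {
    bin_values <- bin_values %||% curves[[1]]$bin_centers
    curves <- do.call(rbind, lapply(curves, function(cv) cv$rate))
  }
  if (is.null(bin_values)) stop("bin_values required for matrix curves")
  curves[is.na(curves)] <- 0
  lam <- pmax(curves, rate_floor) * bin_width
  if (!is.null(frames)) X <- X[, frames, drop = FALSE]
  ll <- crossprod(X, log(lam)) # frames x bins
  ll <- sweep(ll, 2, colSums(lam))
  dec_bin <- max.col(ll, ties.method = "first")
  decoded <- bin_values[dec_bin]
  empty <- colSums(X) == 0
  decoded[empty] <- NA_real_
  gauge <- NULL
  if (!is.null(actual)) {
    fit <- fit_decode_gauge(decoded, actual, mode, bin_values)
    decoded <- fit$decoded
    gauge <- fit$gauge
  }
  new_decode_result(decoded, actual, mode, gauge)
}

#' Across-structure (across-mice / across-days) decoder
#'
#' Uses the analogy between two internal structures: each test frame's
#' internal coordinate is matched -- under the best element of the internal
#' symmetry group (reflection for a line, rotation and reflection for a
#' ring) -- to the reference session's internal coordinate, and the decoded
#' value is the external value associated with that part of the reference
#' structure.
#'
#' @param test_internal per-frame internal coordinate of the test session
#'   (`[0, 1]` linear, radians circular).
#' @param ref_internal,ref_external per-frame internal coordinate and
#'   external variable of the reference session.
#' @param mode `"linear"` or `"circular"` (both sessions must match).
#' @param actual optional external truth of the test session, used to select
#'   the symmetry element by minimal MSE.
#' @param n_bins resolution of the internal-to-external association (20).
#' @return a `decode_result`.
#' @export
across_structure_decode <- function(test_internal, ref_internal,
                                    ref_external,
                                    mode = c("linear", "circular"),
                                    actual = NULL, n_bins = 20) {
  mode <- match.arg(mode)
  ok <- !is.na(ref_internal) & !is.na(ref_external)
  if (mode == "linear") {
    br <- seq(0, 1, length.out = n_bins + 1)
    bin_of <- function(x) pmin(pmax(findInterval(x, br,
                                                 rightmost.closed = TRUE),
                                    1L), n_bins)
    lut <- rep(NA_real_, n_bins)
    rb <- bin_of(ref_internal[ok])
    for (k in seq_len(n_bins))
      if (any(rb == k)) lut[k] <- mean(ref_external[ok][rb == k])
    # fill empty bins from the nearest defined bin
    def <- which(!is.na(lut))
    for (k in which(is.na(lut))) lut[k] <- lut[def[which.min(abs(def - k))]]
    cands <- list(identity = test_internal,
                  reflected = 1 - test_internal)
  } else {
    br <- seq(0, 2 * pi, length.out = n_bins + 1)
    bin_of <- function(x) pmin(pmax(findInterval(x %% (2 * pi), br,
                                                 rightmost.closed = TRUE),
                                    1L), n_bins)
    lut <- rep(NA_real_, n_bins)
    rb <- bin_of(ref_internal[ok])
    for (k in seq_len(n_bins))
      if (any(rb == k)) lut[k] <- circ_mean(ref_external[ok][rb == k])
    def <- which(!is.na(lut))
    for (k in which(is.na(lut))) lut[k] <- lut[def[which.min(abs(def - k))]]
    offs <- 2 * pi * (seq_len(n_bins) - 1) / n_bins
    cands <- list()
    for (refl in c(FALSE, TRUE)) for (o in offs) {
      nm <- sprintf("%s%.4f", if (refl) "r" else "i", o)
      cands[[nm]] <- ((if (refl) -test_internal else test_internal) + o) %%
        (2 * pi)
    }
  }
  best <- NULL
  for (nm in names(cands)) {
    dec <- lut[bin_of(cands[[nm]])]
    if (!is.null(actual)) {
      e <- if (mode == "circular") circ_diff(dec, actual) else dec - actual
      msev <- mean(e^2, na.rm = TRUE)
    } else msev <- 0
    if (is.null(best) || msev < best$mse)
      best <- list(mse = msev, decoded = dec, gauge = nm)
    if (is.null(actual)) break
  }
  new_decode_result(best$decoded, actual,
                    if (mode == "circular") "circular" else "linear",
                    gauge = best$gauge)
}

#' Nearest-neighbor trajectory-phase decoder
#'
#' For each test frame (running in one direction), finds its nearest neighbor
#' in the reduced activity space among the frames of the opposite running
#' direction and returns that frame's trajectory phase. Ties are broken by
#' the earliest training frame.
#'
#' @param test_coords embedding coordinates of the test-direction frames.
#' @param train_coords embedding coordinates of the opposite direction.
#' @param train_phase per-frame phase of the training direction.
#' @param actual optional test-frame phase truth.
#' @return a `decode_result` (linear mode).
#' @export
nn_phase_decode <- function(test_coords, train_coords, train_phase,
                            actual = NULL) {
  if (!nrow(train_coords)) stop("empty training direction")
  nn <- cpp_nn_index(as.matrix(test_coords), as.matrix(train_coords))
  new_decode_result(train_phase[nn], actual, "linear")
}

# per-frame bin labels on a 20-bin axis for phase / time / speed-by-accel
template_bins <- function(b, variable, n_bins = 20, edge = 8,
                          max_speed = 40) {
  ti <- traversal_info(b)
  L <- attr(b, "track_length") %||% 96
  run <- !is.na(ti$traversal)
  lab <- rep(NA_integer_, nrow(b))
  if (variable == "phase") {
    x <- ti$phase
    inr <- run & x >= edge & x <= L - edge
    br <- seq(edge, L - edge, length.out = n_bins + 1)
    lab[inr] <- pmin(pmax(findInterval(x[inr], br, rightmost.closed = TRUE),
                          1L), n_bins)
  } else if (variable == "time") {
    tmax <- max(ti$t_start[run], na.rm = TRUE)
    br <- seq(0, tmax, length.out = n_bins + 1)
    lab[run] <- pmin(pmax(findInterval(ti$t_start[run], br,
                                       rightmost.closed = TRUE), 1L), n_bins)
  } else { # speed_by_accel
    half <- n_bins / 2
    sp <- pmin(b$speed, max_speed)
    up <- run & ti$accel_sign >= 0
    dn <- run & ti$accel_sign < 0
    lab[up] <- pmin(pmax(ceiling(sp[up] / (max_speed / half)), 1L), half)
    lab[dn] <- pmin(pmax(n_bins + 1 - ceiling(sp[dn] / (max_speed / half)),
                         half + 1L), n_bins)
  }
  lab
}

#' Template-correlation decoder for phase, time, or speed-by-acceleration
#'
#' Splits the session into training (odd minutes) and test (even minutes)
#' halves, averages the training activity vectors within each of 20 bins of
#' the target variable, and decodes each test frame as the bin whose template
#' has the highest Pearson correlation with the frame's activity vector. The
#' explained variance is `1 - MSE(data) / MSE(shuffle)`, where the shuffle
#' MSE permutes the test labels while preserving their overall probabilities.
#' Variables: trajectory phase (20 bins, 8 cm excluded per side); time from
#' traversal start (20 bins to the longest traversal); speed by acceleration
#' (10 speeding-up bins 0-40 cm/s, then 10 slowing-down bins 40-0 cm/s).
#'
#' @param m an [activity_matrix()].
#' @param b a `behavior_track`.
#' @param variable `"phase"`, `"time"`, or `"speed_by_accel"`.
#' @param n_bins number of bins (20).
#' @param n_shuffles label shuffles for the explained-variance denominator.
#' @param seed integer seed.
#' @return a `decode_result` on the bin-index scale, with
#'   `explained_variance`.
#' @export
template_decode <- function(m, b,
                            variable = c("phase", "time", "speed_by_accel"),
                            n_bins = 20, n_shuffles = 1000, seed = 1) {
  variable <- match.arg(variable)
  frame_rate <- attr(b, "frame_rate") %||% (1 / m$bin_width)
  if (nrow(b) < 2 * 60 * frame_rate) stop("session shorter than 2 minutes")
  lab <- template_bins(b, variable, n_bins)
  minute <- floor((seq_len(nrow(b)) - 1) / (60 * frame_rate)) + 1
  train <- which(!is.na(lab) & minute %% 2 == 1)
  test <- which(!is.na(lab) & minute %% 2 == 0)
  templ <- matrix(NA_real_, m$n_neurons, n_bins)
  for (k in seq_len(n_bins)) {
    fr <- train[lab[train] == k]
    if (length(fr)) templ[, k] <- rowMeans(m$values[, fr, drop = FALSE])
  }
  have <- which(colSums(is.na(templ)) == 0 &
                  apply(templ, 2, function(z) var(z) > 0))
  if (length(have) < n_bins)
    warning(sprintf("%d bins had no training frames and were excluded",
                    n_bins - length(have)))
  X <- m$values[, test, drop = FALSE]
  C <- suppressWarnings(cor(X, templ[, have, drop = FALSE]))
  dec <- rep(NA_real_, length(test))
  okf <- rowSums(is.na(C)) < length(have)
  dec[okf] <- have[max.col(replace(C, is.na(C), -Inf),
                           ties.method = "first")[okf]]
  actual <- lab[test]
  err <- dec - actual
  mse <- mean(err^2, na.rm = TRUE)
  set.seed(as.integer(seed))
  mse_sh <- vapply(seq_len(n_shuffles), function(s)
    mean((dec - sample(actual))^2, na.rm = TRUE), numeric(1))
  ev <- 1 - mse / mean(mse_sh)
  out <- new_decode_result(dec, actual, "linear",
                           explained_variance = ev)
  out$mse <- mse
  out
}

#' Shuffle test for decoding accuracy
#'
#' Compares the decoder's mean squared error to the errors of shuffled
#' decoded series: each shuffle permutes the decoded values across time bins
#' and then re-fits the gauge degrees of freedom (rotation and reflection for
#' angles, reflection for positions) to minimize its own MSE, so the null is
#' conservative.
#'
#' @param r a `decode_result` with `actual`.
#' @param n_shuffles number of shuffles (at least 100; default 1000).
#' @param seed integer seed.
#' @return the `decode_result` with `shuffle_p` set:
#'   `(1 + #\{null <= observed\}) / (n_shuffles + 1)`.
#' @export
shuffle_test_decoding <- function(r, n_shuffles = 1000, seed = 1) {
  stopifnot(inherits(r, "decode_result"), !is.null(r$actual))
  if (n_shuffles < 100) stop("need at least 100 shuffles")
  ok <- !is.na(r$decoded) & !is.na(r$actual)
  dec <- r$decoded[ok]; act <- r$actual[ok]
  if (length(unique(dec)) < 2)
    warning("constant decoded series: shuffle null is degenerate")
  mode <- if (r$mode == "circular") "circular" else "linear"
  obs <- mean(if (mode == "circular") circ_diff(dec, act)^2 else
    (dec - act)^2)
  set.seed(as.integer(seed))
  bv <- sort(unique(dec))
  null <- vapply(seq_len(n_shuffles), function(s) {
    d <- sample(dec)
    fit_decode_gauge(d, act, mode, bv)$mse
  }, numeric(1))
  r$shuffle_p <- (1 + sum(null <= obs)) / (n_shuffles + 1)
  r$null_mse <- null
  r
}

#' Phase-versus-time variability of one neuron
#'
#' Event rates for each combination of trajectory phase and time from the
#' start of a traversal (20 x 20 bins). `SD_T` is the occupancy-weighted
#' average over phases of the SD of rates across times -- variability in
#' WHEN the cell is active; `SD_P` is the symmetric quantity across phases.
#' A phase-coding cell has `SD_P > SD_T`; a time-coding cell the reverse.
#'
#' @param m an [activity_matrix()].
#' @param b a `behavior_track`.
#' @param neuron neuron index.
#' @param n_bins bins per axis (20).
#' @param min_events minimum events during running (10).
#' @return list with `joint_rate_map` (phase x time), `SD_T`, `SD_P`,
#'   `n_events`, or `NULL`-like excluded marker.
#' @export
phase_time_variability <- function(m, b, neuron, n_bins = 20,
                                   min_events = 10) {
  ti <- traversal_info(b)
  run <- which(!is.na(ti$traversal))
  act <- m$values[neuron, ]
  n_ev <- sum(act[run])
  if (n_ev < min_events)
    return(list(joint_rate_map = NULL, SD_T = NA_real_, SD_P = NA_real_,
                n_events = n_ev, excluded = TRUE))
  L <- attr(b, "track_length") %||% 96
  pb <- pmin(pmax(ceiling(ti$phase[run] / (L / n_bins)), 1L), n_bins)
  tmax <- max(ti$t_start[run])
  tb <- pmin(pmax(ceiling(ti$t_start[run] / (tmax / n_bins)), 1L), n_bins)
  occ <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  for (i in seq_along(run)) {
    occ[pb[i], tb[i]] <- occ[pb[i], tb[i]] + m$bin_width
    cnt[pb[i], tb[i]] <- cnt[pb[i], tb[i]] + act[run[i]]
  }
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  sd_rows <- apply(rate, 1, sd, na.rm = TRUE) # across time, fixed phase
  sd_cols <- apply(rate, 2, sd, na.rm = TRUE) # across phase, fixed time
  w_phase <- rowSums(occ); w_time <- colSums(occ)
  okr <- !is.na(sd_rows); okc <- !is.na(sd_cols)
  SD_T <- sum(w_phase[okr] * sd_rows[okr]) / sum(w_phase[okr])
  SD_P <- sum(w_time[okc] * sd_cols[okc]) / sum(w_time[okc])
  list(joint_rate_map = rate, SD_T = SD_T, SD_P = SD_P, n_events = n_ev,
       excluded = FALSE)
}
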