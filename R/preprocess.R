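#' Event-detection configuration
#'
#' Thresholds for Ca2+ transient detection from dF/F0 traces. Defaults follow
#' the indicator: GCaMP6s uses a 4-MAD detection threshold, a 2-MAD
#' next-peak prominence and a 600 ms minimum decay time constant; GCaMP6f
#' uses 5 MAD, 2.5 MAD and 200 ms.
#'
#' @param indicator `"GCaMP6s"` or `"GCaMP6f"`.
#' @param mad_threshold detection threshold in MADs of the filtered trace.
#' @param next_peak_threshold prominence (MADs) a peak must exceed the next
#'   peak by within the same candidate event.
#' @param min_decay minimum indicator decay time constant in seconds.
#' @param lowpass_cutoff low-pass cutoff in Hz.
#' @param median_window sliding-median baseline window in seconds.
#' @param min_event_rate minimum per-neuron event rate in Hz; quieter neurons
#'   are discarded.
#' @param min_event_amplitude minimum mean event amplitude in dF/F0 units.
#' @param active_frames number of frames marked active per accepted event.
#' @return list of thresholds (class `event_detection_config`).
#' @export
event_detection_config <- function(indicator = c("GCaMP6s", "GCaMP6f"),
                                   mad_threshold = NULL,
                                   next_peak_threshold = NULL,
                                   min_decay = NULL,
                                   lowpass_cutoff = 2,
                                   median_window = 20,
                                   min_event_rate = 0.01,
                                   min_event_amplitude = 0.01,
                                   active_frames = 2) {
  indicator <- match.arg(indicator)
  s <- indicator == "GCaMP6s"
  cfg <- list(indicator = indicator,
              mad_threshold = mad_threshold %||% if (s) 4 else 5,
              next_peak_threshold = next_peak_threshold %||% if (s) 2 else 2.5,
              min_decay = min_decay %||% if (s) 0.6 else 0.2,
              lowpass_cutoff = lowpass_cutoff,
              median_window = median_window,
              min_event_rate = min_event_rate,
              min_event_amplitude = min_event_amplitude,
              active_frames = active_frames)
  stopifnot(all(unlist(cfg[-1]) > 0))
  class(cfg) <- "event_detection_config"
  cfg
}

# local maxima (strict rise before, fall-or-end after) of a numeric vector
local_peaks <- function(x) {
  n <- length(x)
  if (n == 1) return(1L)
  up <- c(TRUE, diff(x) > 0)
  down <- c(diff(x) < 0, TRUE)
  which(up & down)
}

#' Detect Ca2+ events in fluorescence traces
#'
#' Per neuron: subtract the sliding-median baseline (20 s window), low-pass
#' filter at 2 Hz (zero-phase second-order Butterworth), threshold at
#' `mad_threshold` MADs of the filtered trace, and keep candidate transients
#' whose decay is slow enough for the indicator: the time the trace takes to
#' fall to half the peak amplitude must reach half of `min_decay` (the
#' half-life of an exponential with time constant `min_decay` is
#' ln(2) x `min_decay`, so this accepts transients with time constants down to
#' ~0.72 of nominal, leaving noise margin). Within a candidate event,
#' secondary peaks are accepted only if they rise `mad_threshold` MADs above
#' the preceding peak and exceed the following peak by `next_peak_threshold`
#' MADs, so one transient yields one event. Each accepted event marks two
#' consecutive frames active at its peak. Finally, neurons with an event rate
#' below 0.01 Hz or a mean event amplitude below 1% dF/F0 are discarded.
#'
#' @param traces a `fluorescence_traces` object (or dF/F0 matrix with a
#'   `frame_rate` attribute).
#' @param config an [event_detection_config()]; default derives from the
#'   trace's indicator.
#' @param neighbor_pairs optional 2-column matrix of neuron index pairs that
#'   are spatial neighbors; within any 200 ms window only the neighbor with
#'   the highest peak keeps its event (crosstalk control).
#' @return an [activity_matrix()] (imaging modality) with extra fields
#'   `events` (data.frame `neuron`, `frame`, `amplitude`) and `kept_neurons`
#'   (logical; discarded neurons have all-zero rows).
#' @export
detect_ca_events <- function(traces, config = NULL, neighbor_pairs = NULL) {
  if (inherits(traces, "fluorescence_traces")) {
    tr <- traces$traces
    fs <- traces$frame_rate
    config <- config %||% event_detection_config(traces$indicator)
  } else {
    tr <- traces
    fs <- attr(traces, "frame_rate") %||% 20
    config <- config %||% event_detection_config()
  }
  if (!all(is.finite(tr))) stop("traces must be finite")
  if (fs < 2 * config$lowpass_cutoff)
    stop("frame rate too low for the low-pass filter")
  n <- nrow(tr); K <- ncol(tr)
  bf <- signal::butter(2, config$lowpass_cutoff / (fs / 2), type = "low")
  medwin <- round(config$median_window * fs)
  if (medwin %% 2 == 0) medwin <- medwin + 1
  medwin <- min(medwin, if (K %% 2 == 1) K else K - 1)
  ev_neuron <- integer(0); ev_frame <- integer(0); ev_amp <- numeric(0)
  for (i in seq_len(n)) {
    x <- tr[i, ]
    if (K > 2 && medwin >= 3) x <- x - stats::runmed(x, medwin)
    x <- as.numeric(signal::filtfilt(bf, x))
    s <- mad(x)
    if (s == 0) next
    thr <- config$mad_threshold * s
    above <- x > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      idx <- starts[seg]:ends[seg]
      pk_rel <- local_peaks(x[idx])
      pk <- idx[pk_rel]
      amps <- x[pk]
      acc <- logical(length(pk))
      for (p in seq_along(pk)) {
        ok_prev <- p == 1 ||
          amps[p] - min(amps[seq_len(p - 1)]) >= config$mad_threshold * s ||
          amps[p] >= max(amps[seq_len(p - 1)]) + config$mad_threshold * s
        ok_next <- p == length(pk) ||
          amps[p] >= amps[p + 1] + config$next_peak_threshold * s
        acc[p] <- (p == 1 && ok_next) || (p > 1 && ok_prev && ok_next)
      }
      for (p in which(acc)) {
        # decay check: half-amplitude crossing time -> time constant
        half <- amps[p] / 2
        after <- x[pk[p]:K]
        cross <- which(after < half)
        t_half <- if (length(cross)) (cross[1] - 1) / fs else (K - pk[p]) / fs
        # a transient with time constant min_decay has half-life
        # ln(2)*min_decay ~ 0.69*min_decay; requiring half of min_decay
        # leaves noise margin while still rejecting fast blips
        if (t_half < 0.5 * config$min_decay) next
        ev_neuron <- c(ev_neuron, i)
        ev_frame <- c(ev_frame, pk[p])
        ev_amp <- c(ev_amp, amps[p])
      }
    }
  }
  events <- data.frame(neuron = ev_neuron, frame = ev_frame,
                       amplitude = ev_amp)
  # crosstalk control among declared neighbors: one event per 200 ms window
  if (!is.null(neighbor_pairs) && nrow(events) > 1) {
    win <- round(0.2 * fs)
    drop <- rep(FALSE, nrow(events))
    for (r in seq_len(nrow(neighbor_pairs))) {
      a <- neighbor_pairs[r, 1]; b <- neighbor_pairs[r, 2]
      ia <- which(events$neuron == a & !drop)
      ib <- which(events$neuron == b & !drop)
      for (ea in ia) for (eb in ib) {
        if (abs(events$frame[ea] - events$frame[eb]) <= win) {
          drop[if (events$amplitude[ea] >= events$amplitude[eb]) eb else ea] <-
            TRUE
        }
      }
    }
    events <- events[!drop, , drop = FALSE]
  }
  # neuron-level quality filters
  dur <- K / fs
  kept <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ei <- events$neuron == i
    rate <- sum(ei) / dur
    mamp <- if (any(ei)) mean(events$amplitude[ei]) else 0
    if (rate < config$min_event_rate || mamp < config$min_event_amplitude)
      kept[i] <- FALSE
  }
  events <- events[kept[events$neuron], , drop = FALSE]
  values <- matrix(0L, n, K)
  if (nrow(events)) {
    for (f in 0:(config$active_frames - 1)) {
      fr <- pmin(events$frame + f, K)
      values[cbind(events$neuron, fr)] <- 1L
    }
  }
  out <- activity_matrix(values, 1 / fs, "imaging")
  out$events <- events
  out$kept_neurons <- kept
  out
}
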