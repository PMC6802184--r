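#' Binary population activity matrix
#'
#' The universal pipeline input: a binary neurons-by-time-bins raster with its
#' bin width, recording modality, and the set of time bins that pass the
#' modality-specific population-activity filter. Imaging data retain bins with
#' more than one active neuron; electrophysiology data retain bins with at
#' least 15 active neurons.
#'
#' @param values binary matrix, neurons x time bins.
#' @param bin_width bin width in seconds.
#' @param modality `"imaging"` or `"ephys"`; selects the activity filter.
#' @return an `activity_matrix` object: a list with elements `values`,
#'   `bin_width`, `modality`, `retained_frames` (indices of bins passing the
#'   filter), `n_neurons`, `n_bins`.
#' @export
activity_matrix <- function(values, bin_width,
                            modality = c("imaging", "ephys")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values), bin_width > 0)
  values <- matrix(as.integer(values != 0), nrow(values), ncol(values))
  active <- colSums(values)
  retained <- if (modality == "imaging") which(active > 1) else
    which(active >= 15)
  structure(
    list(values = values, bin_width = bin_width, modality = modality,
         retained_frames = as.integer(retained),
         n_neurons = nrow(values), n_bins = ncol(values)),
    class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf(
    "<activity_matrix> %d neurons x %d bins (%.3g s bins, %s); %d/%d frames retained\n",
    x$n_neurons, x$n_bins, x$bin_width, x$modality,
    length(x$retained_frames), x$n_bins))
  invisible(x)
}

#' Build a binary activity matrix from events or spike trains
#'
#' Bins events and binarizes: a neuron-bin entry is 1 if the neuron emitted at
#' least one event (Ca2+ event or spike) in that bin. The modality filter marks
#' retained frames (imaging: more than one active neuron; ephys: at least 15
#' active neurons); the original bin indices are preserved so frames can be
#' aligned with behavior.
#'
#' @param events either a data.frame with columns `neuron` and `frame` (bin
#'   index) or `neuron` and `time` (seconds), or a list of per-neuron numeric
#'   spike-time vectors (seconds).
#' @param bin_width bin width in seconds (0.1 s for binned spike trains).
#' @param modality `"imaging"` or `"ephys"`.
#' @param n_neurons,n_bins optional dimensions (inferred from the data when
#'   omitted).
#' @return an [activity_matrix()].
#' @export
build_activity_matrix <- function(events, bin_width,
                                  modality = c("imaging", "ephys"),
                                  n_neurons = NULL, n_bins = NULL) {
  modality <- match.arg(modality)
  stopifnot(bin_width > 0)
  if (is.list(events) && !is.data.frame(events)) {
    n_neurons <- n_neurons %||% length(events)
    tmax <- suppressWarnings(max(unlist(events), -Inf))
    n_bins <- n_bins %||% if (is.finite(tmax)) ceiling(tmax / bin_width) else 0L
    df <- data.frame(
      neuron = rep(seq_along(events), lengths(events)),
      frame = pmin(floor(unlist(events) / bin_width) + 1L, n_bins))
  } else {
    df <- as.data.frame(events)
    if (!"frame" %in% names(df) && "time" %in% names(df))
      df$frame <- floor(df$time / bin_width) + 1L
    n_neurons <- n_neurons %||% if (nrow(df)) max(df$neuron) else 0L
    n_bins <- n_bins %||% if (nrow(df)) max(df$frame) else 0L
  }
  values <- matrix(0L, n_neurons, max(n_bins, 0L))
  if (nrow(df) > 0) {
    df <- df[df$frame >= 1 & df$frame <= n_bins & df$neuron >= 1 &
               df$neuron <= n_neurons, , drop = FALSE]
    values[cbind(df$neuron, df$frame)] <- 1L
  }
  activity_matrix(values, bin_width, modality)
}

#' Shuffle controls for population structure
#'
#' Two null models that destroy the correlational structure of the population
#' while preserving marginal activity statistics. The time shuffle redraws the
#' active time bins of each cell independently, keeping the number of active
#' bins per cell (row sums). The cell shuffle redraws the identities of the
#' active cells in each time bin, keeping the number of active cells per bin
#' (column sums).
#'
#' @param m an [activity_matrix()].
#' @param mode `"time"` or `"cell"`.
#' @param seed integer seed.
#' @return a new [activity_matrix()] with the same bin width and modality.
#' @export
shuffle_control <- function(m, mode = c("time", "cell"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "activity_matrix"))
  set.seed(as.integer(seed))
  v <- m$values
  K <- ncol(v)
  out <- matrix(0L, nrow(v), K)
  if (mode == "time") {
    for (i in seq_len(nrow(v))) {
      k <- sum(v[i, ])
      if (k > 0) out[i, sample.int(K, k)] <- 1L
    }
  } else {
    N <- nrow(v)
    for (j in seq_len(K)) {
      k <- sum(v[, j])
      if (k > 0) out[sample.int(N, k), j] <- 1L
    }
  }
  activity_matrix(out, m$bin_width, m$modality)
}
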