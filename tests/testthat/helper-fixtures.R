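# Shared end-to-end fixtures for the acceptance suite. Each fixture runs the
# full pipeline once on a synthetic session and is cached for the rest of
# the test run. Session sizes: 900 s linear-track sessions with 500 neurons
# (about 45 left-right running cycles) and 30-min head-direction sessions
# with 50 cells at 100 ms bins.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

count_behavior_cycles <- function(b) {
  r <- rle(as.character(b$running_direction) != "none")
  floor(sum(r$values) / 2)
}

fx_hd <- function(seed) {
  fixture(paste0("hd", seed), function() {
    ses <- gen_hd_session(n_neurons = 50, duration = 1800, bin_width = 0.1,
                          seed = seed)
    res <- analyze_ring_session(ses$activity, ses$behavior)
    list(ses = ses, res = res)
  })
}

fx_linear <- function(mode, seed) {
  fixture(paste0(mode, seed), function() {
    ses <- gen_linear_track_session(mode, n_neurons = 500, duration = 900,
                                    seed = seed)
    res <- analyze_linear_session(ses$activity, ses$behavior)
    list(ses = ses, res = res)
  })
}

# Segment-level state sequence for the cycle-motif analysis. With
# split_runs = TRUE (hippocampal-style data), locomotion segments are
# relabeled by their direction group, reproducing the canonical 6-state
# cycle; with FALSE (cingulate-style data, where the run states are shared
# by the two directions), the raw state sequence is used and the cycle is
# traversed twice per behavioral cycle.
motif_sequence <- function(res, split_runs = TRUE) {
  if (!split_runs) {
    segs <- res$segments[order(res$segments$start_idx), , drop = FALSE]
    ids <- sort(unique(segs$state))
    return(list(states = match(segs$state, ids), n_states = length(ids)))
  }
  segs <- res$segments[order(res$segments$start_idx), , drop = FALSE]
  is_run <- segs$state %in% res$running_states
  run_segs <- res$running_segments[order(res$running_segments$start_idx), ,
                                   drop = FALSE]
  pause_states <- sort(setdiff(unique(segs$state), res$running_states))
  groups <- setdiff(unique(run_segs$group), c(NA, "none"))
  ids <- seq_along(pause_states)
  names(ids) <- pause_states
  gid <- length(pause_states) + seq_along(groups)
  names(gid) <- groups
  seqv <- integer(nrow(segs))
  ri <- 0L
  for (i in seq_len(nrow(segs))) {
    if (is_run[i]) {
      ri <- ri + 1L
      g <- run_segs$group[ri]
      seqv[i] <- if (g %in% groups) gid[[g]] else NA_integer_
    } else {
      seqv[i] <- ids[[as.character(segs$state[i])]]
    }
  }
  list(states = seqv[!is.na(seqv)], n_states = length(pause_states) +
         length(groups))
}

# median peak mismatch (in 4-cm track bins) and internal/external curve
# correlations for the planted tuned cells of one direction group
internal_recovery <- function(ses, res, group = "right") {
  sub <- res$sub[[group]]
  b <- ses$behavior
  m <- ses$activity
  truth <- ses$truth
  pos_range <- range(b$position[sub$frames])
  lo <- pos_range[1]; hi <- pos_range[2]
  tuned <- which(truth$class == "place" & truth$direction %in%
                   c(group, "both"))
  mism <- cors <- c()
  for (i in tuned) {
    ic <- internal_tuning_curve(m, sub$trajectory, i, n_bins = 20)
    if (ic$excluded) next
    ec <- external_tuning_curve(m, b, i, "position", group)
    if (ec$excluded || sum(ec$counts) < 6) next
    pred_pos <- lo + ic$bin_centers[which.max(ic$rate)] * (hi - lo)
    mism <- c(mism, abs(pred_pos - truth$pref[i]) / 4)
    # internal rate interpolated at the external bin centers
    xi <- (ec$bin_centers - lo) / (hi - lo)
    ri <- approx(ic$bin_centers, ic$rate, xout = pmin(pmax(xi, 0), 1),
                 rule = 2)$y
    cors <- c(cors, suppressWarnings(cor(ri, ec$rate)))
  }
  list(mismatch_bins = mism, correlations = cors[!is.na(cors)])
}

# sleep-trained maximum-likelihood decoder on the head-direction fixture:
# internal tuning curves from REM frames only, tested on wake frames
sleep_to_wake_decode <- function(ses, res) {
  m <- ses$activity
  rem_frames <- which(ses$behavior$episode == "rem")
  wake_frames <- intersect(res$res$trajectory$frame_index,
                           which(ses$behavior$episode == "wake"))
  curves <- lapply(seq_len(m$n_neurons), function(i)
    internal_tuning_curve(m, res$res$trajectory, i, frames = rem_frames))
  keep <- !vapply(curves, `[[`, logical(1), "excluded")
  rates <- do.call(rbind, lapply(curves[keep], `[[`, "rate"))
  rates[is.na(rates)] <- 0
  ml_decode(m$values[keep, wake_frames, drop = FALSE], rates, "circular",
            bin_values = curves[keep][[1]]$bin_centers,
            actual = ses$behavior$head_direction[wake_frames],
            bin_width = m$bin_width)
}
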