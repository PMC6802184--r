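#' Behavioral-state labels for stability analysis
#'
#' Maps frame-level behavior labels to the five network states used for
#' across-day comparisons: drinking at each edge, turning at each edge, and
#' running. Rearing is merged with turning at the same position, since the
#' neural code for the two behaviors at one location is similar.
#'
#' @param b a `behavior_track`.
#' @param merge_turn_rear merge rearing into the turning state (default).
#' @return integer state per frame (1 = drink_L, 2 = turn_L, 3 = run,
#'   4 = turn_R, 5 = drink_R) with attribute `reflection` giving the state
#'   permutation under track reflection.
#' @export
behavior_states <- function(b, merge_turn_rear = TRUE) {
  lab <- as.character(b$behavior_label)
  if (merge_turn_rear && any(lab == "rear")) {
    L <- attr(b, "track_length") %||% 96
    side_left <- b$position < L / 2
    lab[lab == "rear"] <- ifelse(side_left[lab == "rear"], "turn_L", "turn_R")
  }
  states <- c(drink_L = 1L, turn_L = 2L, run = 3L, turn_R = 4L,
              drink_R = 5L)
  out <- unname(states[lab])
  attr(out, "reflection") <- c(5L, 4L, 3L, 2L, 1L)
  attr(out, "n_states") <- 5L
  out
}

spearman <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))

#' Code and structure stability across days
#'
#' Code stability: Spearman correlation between the ensemble activity
#' vectors (mean event rate per neuron) of the same behavioral state on two
#' different days, averaged over states weighted by the time spent in each
#' state; only neurons detected on both days enter a pair's correlation.
#' Structure stability: Spearman correlation between the upper triangles of
#' the two days' state-centroid distance matrices in their (independently
#' computed) embeddings. Both measures take, for each day pair, the maximal
#' correlation over the two track orientations (reflection symmetry).
#' Significance of each pair's structure correlation comes from shuffling the
#' state identities of one day (all permutations, each evaluated at its best
#' orientation). Correlations are also normalized to the value at the
#' minimal elapsed time and fit linearly against elapsed days.
#'
#' @param sessions list of day sessions from [gen_multiday_sessions()] (each
#'   with `behavior`, `activity`, `roster`).
#' @param embeddings optional list of per-day `embedding`s (computed with
#'   [embed_two_stage()] when omitted).
#' @param day_times numeric acquisition day of each session (default
#'   `2 * (0:(n-1))`, i.e. every other day).
#' @param p1,p2 embedding parameters when embeddings are computed here.
#' @return a `stability_result`: data.frames `code` and `structure` (per
#'   pair: days, elapsed, correlation, `p` for structure), `slopes` (linear
#'   fits of the normalized correlations vs elapsed time with 95% CI).
#' @export
stability_analysis <- function(sessions, embeddings = NULL, day_times = NULL,
                               p1 = 0.00375, p2 = 0.1125) {
  n_days <- length(sessions)
  stopifnot(n_days >= 2)
  day_times <- day_times %||% (2 * (seq_len(n_days) - 1))
  states_by_day <- lapply(sessions, function(s) behavior_states(s$behavior))
  n_states <- 5L
  refl <- attr(states_by_day[[1]], "reflection")
  if (is.null(embeddings))
    embeddings <- lapply(sessions, function(s)
      embed_two_stage(s$activity, p1, p2))
  # per-day ensemble vectors and state centroids
  ens <- lapply(seq_len(n_days), function(d) {
    s <- sessions[[d]]; st <- states_by_day[[d]]
    dur <- s$activity$bin_width
    sapply(seq_len(n_states), function(k) {
      fr <- which(st == k)
      if (!length(fr)) return(rep(NA_real_, s$activity$n_neurons))
      rowSums(s$activity$values[, fr, drop = FALSE]) / (length(fr) * dur)
    })
  })
  dwell <- lapply(seq_len(n_days), function(d)
    tabulate(states_by_day[[d]], n_states))
  centroids <- lapply(seq_len(n_days), function(d) {
    e <- embeddings[[d]]
    st <- states_by_day[[d]][e$frame_index]
    t(sapply(seq_len(n_states), function(k) {
      fr <- which(st == k)
      if (!length(fr)) return(rep(NA_real_, ncol(e$coords)))
      colMeans(e$coords[fr, , drop = FALSE])
    }))
  })
  dist_upper <- function(cm, perm = seq_len(n_states)) {
    dm <- as.matrix(dist(cm[perm, , drop = FALSE]))
    dm[upper.tri(dm)]
  }
  pairs <- utils::combn(n_days, 2)
  code_rows <- structure_rows <- list()
  all_perms5 <- all_perms(n_states)
  for (pidx in seq_len(ncol(pairs))) {
    d1 <- pairs[1, pidx]; d2 <- pairs[2, pidx]
    shared <- intersect(sessions[[d1]]$roster %||%
                          seq_len(sessions[[d1]]$activity$n_neurons),
                        sessions[[d2]]$roster %||%
                          seq_len(sessions[[d2]]$activity$n_neurons))
    # code: weighted mean of per-state Spearman, best orientation
    corr_orient <- vapply(list(seq_len(n_states), refl), function(perm) {
      cs <- ws <- numeric(0)
      for (k in seq_len(n_states)) {
        v1 <- ens[[d1]][shared, k]
        v2 <- ens[[d2]][shared, perm[k]]
        if (all(is.na(v1)) || all(is.na(v2))) next
        cs <- c(cs, spearman(v1, v2))
        ws <- c(ws, dwell[[d1]][k] + dwell[[d2]][perm[k]])
      }
      sum(cs * ws) / sum(ws)
    }, numeric(1))
    code_rows[[pidx]] <- data.frame(
      day1 = d1, day2 = d2,
      elapsed = abs(day_times[d2] - day_times[d1]),
      corr = max(corr_orient))
    # structure: distance-matrix upper triangles, best orientation;
    # null = all state-identity permutations of day 2
    du1 <- dist_upper(centroids[[d1]])
    obs <- max(spearman(du1, dist_upper(centroids[[d2]])),
               spearman(du1, dist_upper(centroids[[d2]], refl)))
    null <- apply(all_perms5, 1, function(perm)
      spearman(du1, dist_upper(centroids[[d2]], perm)))
    p <- mean(null >= obs)
    structure_rows[[pidx]] <- data.frame(
      day1 = d1, day2 = d2,
      elapsed = abs(day_times[d2] - day_times[d1]),
      corr = obs, p = p)
  }
  code <- do.call(rbind, code_rows)
  struc <- do.call(rbind, structure_rows)
  fit_slope <- function(df) {
    agg <- stats::aggregate(corr ~ elapsed, df, mean)
    agg$norm <- agg$corr / agg$corr[which.min(agg$elapsed)]
    if (nrow(agg) < 2)
      return(list(slope = NA_real_, ci = c(NA_real_, NA_real_), data = agg))
    fit <- lm(norm ~ elapsed, agg)
    ci <- if (nrow(agg) > 2) {
      tryCatch(confint(fit)["elapsed", ], error = function(e)
        c(NA_real_, NA_real_))
    } else c(NA_real_, NA_real_)
    list(slope = unname(coef(fit)["elapsed"]), ci = unname(ci), data = agg)
  }
  structure(list(code = code, structure = struc,
                 slopes = list(code = fit_slope(code),
                               structure = fit_slope(struc))),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> %d day pairs; mean code corr %.3f, structure corr %.3f\n",
    nrow(x$code), mean(x$code$corr), mean(x$structure$corr)))
  invisible(x)
}
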