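#' Full unsupervised analysis of a linear-track session
#'
#' Runs the complete internal-structure pipeline on an imaging session:
#' two-stage spectral embedding of the retained activity vectors, topological
#' clustering into network states (components with at least `min_points`
#' points), temporal segmentation with data-driven thresholds, and
#' segment-level PCA subtype splits of the locomotion states. The frames of
#' each locomotion subtype group are then re-embedded separately, sub-
#' clustered with K-means, ordered linearly from their transition
#' probabilities (ends constrained by the sub-clusters most frequent at
#' segment starts and ends), and parameterized as an internal position in
#' `[0, 1]`.
#'
#' Identifying which network states correspond to locomotion is done -- as in
#' any application of the method to recordings -- by sorting behavior by
#' state after the fact: when `behavior` is given, states whose frames are
#' mostly running are selected and subtypes across states are grouped by
#' running direction. Without behavior, the largest state is taken as
#' locomotion and its own subtypes form the groups. The behavior never
#' enters the embedding, clustering, ordering, or tuning computations; it
#' also fixes the reflection gauge and provides per-frame reconstruction
#' errors for validation.
#'
#' @param m an [activity_matrix()].
#' @param behavior optional `behavior_track` for state sorting, gauge fixing
#'   and validation.
#' @param p1,p2 embedding neighbor fractions.
#' @param min_points minimum points per topological cluster (250).
#' @param sub_k number of K-means sub-clusters per locomotion group (10).
#' @param running_states explicit locomotion state ids (overrides the
#'   behavioral sorting).
#' @param max_gap,min_length segmentation thresholds (data-driven defaults).
#' @param seed integer seed for K-means restarts.
#' @return list with `embedding`, `states`, `segments`, `running_states`,
#'   `running_segments` (with `subtype` and `group` columns), and `sub` --
#'   one entry per locomotion group, each with `embedding`, `labels`,
#'   `ordering`, `trajectory`, `frames`.
#' @export
analyze_linear_session <- function(m, behavior = NULL, p1 = 0.00375,
                                   p2 = 0.1125, min_points = 250, sub_k = 10,
                                   running_states = NULL, max_gap = NULL,
                                   min_length = NULL, seed = 1) {
  emb <- embed_two_stage(m, p1, p2)
  states <- cluster_states(emb, "topological", min_points = min_points)
  if (states$n_states == 0) stop("no network state reached min_points")
  segments <- temporal_segments(states$labels, emb$frame_index,
                                max_gap = max_gap, min_length = min_length)
  if (is.null(running_states)) {
    running_states <- if (!is.null(behavior)) {
      run <- behavior$running_direction != "none"
      which(vapply(seq_len(states$n_states), function(s)
        mean(run[emb$frame_index[states$labels == s]]) >= 0.5, logical(1)))
    } else int_mode(states$labels)
  }
  run_segs <- segments[segments$state %in% running_states, , drop = FALSE]
  rownames(run_segs) <- NULL
  # subtype split per locomotion state
  run_segs$subtype <- 1L
  n_subtypes <- setNames(rep(1L, length(running_states)),
                         running_states)
  for (st in running_states) {
    rows <- which(run_segs$state == st)
    if (length(rows) < 4) next
    sp <- segment_subtypes(m, run_segs[rows, ], states$labels,
                           emb$frame_index)
    run_segs$subtype[rows] <- sp$subtype
    n_subtypes[as.character(st)] <- sp$n_subtypes
  }
  # group subtypes across states: by running direction when behavior is
  # available (validation-style sorting), else by subtype of the largest
  # locomotion state only
  seg_frames <- function(i) {
    sel <- which(states$labels == run_segs$state[i] &
                   seq_along(states$labels) >= run_segs$start_idx[i] &
                   seq_along(states$labels) <= run_segs$end_idx[i])
    emb$frame_index[sel]
  }
  if (!is.null(behavior)) {
    dirs <- vapply(seq_len(nrow(run_segs)), function(i) {
      d <- behavior$running_direction[seg_frames(i)]
      d <- d[d != "none"]
      if (!length(d)) "none" else names(which.max(table(d)))
    }, character(1))
    run_segs$group <- dirs
    groups <- setdiff(unique(dirs), "none")
  } else {
    main <- run_segs$state == running_states[
      which.max(tabulate(factor(run_segs$state, running_states)))]
    run_segs$group <- ifelse(main, paste0("subtype", run_segs$subtype), NA)
    groups <- unique(run_segs$group[!is.na(run_segs$group)])
  }
  sub <- list()
  for (grp in groups) {
    rows <- which(run_segs$group == grp)
    frames <- sort(unique(unlist(lapply(rows, seg_frames))))
    if (length(frames) < 50) next
    m_sub <- m
    m_sub$retained_frames <- frames
    e_sub <- embed_two_stage(m_sub, p1, p2)
    lab_sub <- cluster_states(e_sub, "kmeans", k = sub_k, seed = seed)
    # end constraints from temporal blocks of the pooled frames (one block
    # per traversal: pauses between traversals leave gaps of seconds,
    # within-traversal gaps are a few frames)
    fr <- e_sub$frame_index
    blk <- cumsum(c(1L, as.integer(diff(fr) > round(2 / m$bin_width))))
    starts <- ends <- integer(0)
    for (bk in unique(blk)) {
      ii <- which(blk == bk)
      if (length(ii) < 5) next
      starts <- c(starts, lab_sub$labels[ii[1]])
      ends <- c(ends, lab_sub$labels[ii[length(ii)]])
    }
    P <- transition_matrix(lab_sub$labels, "frame", n_states = sub_k)
    ord <- order_states(P, "linear", start_labels = starts,
                        end_labels = ends)
    ext <- if (!is.null(behavior)) behavior$position[e_sub$frame_index]
    traj <- reconstruct_internal_variable(lab_sub$labels, ord, "linear",
                                          frame_index = e_sub$frame_index,
                                          external = ext)
    sub[[grp]] <- list(embedding = e_sub, labels = lab_sub$labels,
                       ordering = ord, trajectory = traj, frames = frames,
                       segments = run_segs[rows, ])
  }
  list(embedding = emb, states = states, segments = segments,
       running_states = running_states, running_segments = run_segs,
       n_subtypes = n_subtypes, sub = sub)
}

#' Full unsupervised analysis of a head-direction session
#'
#' Embeds the binned spike raster with the two-stage spectral embedding,
#' segments the ring into `k_states` K-means states, orders them cyclically
#' from the frame-level transition matrix, and reconstructs the smoothed
#' internal angle of every frame. When behavior is supplied, the rotation
#' and reflection gauge is fixed against the reference heading.
#'
#' @param m an [activity_matrix()].
#' @param behavior optional `behavior_track`; the gauge reference is
#'   `drive_direction` when present (the heading actually driving the cells,
#'   including REM virtual trajectories), else `head_direction`.
#' @param k_states number of ring states (8).
#' @param p1,p2 embedding neighbor fractions.
#' @param seed K-means seed.
#' @return list with `embedding`, `states`, `ordering`, `trajectory`.
#' @export
analyze_ring_session <- function(m, behavior = NULL, k_states = 8,
                                 p1 = 0.00375, p2 = 0.1125, seed = 1) {
  emb <- embed_two_stage(m, p1, p2)
  states <- cluster_states(emb, "kmeans", k = k_states, seed = seed)
  P <- transition_matrix(states$labels, "frame", n_states = k_states)
  ord <- order_states(P, "cyclic")
  ext <- if (!is.null(behavior)) {
    ref <- behavior$drive_direction %||% behavior$head_direction
    ref[emb$frame_index]
  }
  traj <- reconstruct_internal_variable(states$labels, ord, "circular",
                                        frame_index = emb$frame_index,
                                        external = ext)
  list(embedding = emb, states = states, ordering = ord, trajectory = traj)
}

#' Net traversal rate of the cyclic state sequence
#'
#' Measures how many times the segment-level state sequence winds around the
#' ordered cyclic state graph per behavioral running cycle. Each step between
#' consecutive segments contributes its signed distance along the cycle
#' (shortest way); the total winding, divided by the number of states and by
#' the number of behavioral cycles, is the traversal rate -- 1 when one full
#' left-right running cycle corresponds to one cycle of transitions between
#' network states, 2 when it corresponds to two.
#'
#' @param segment_states state ids of consecutive segments in time order.
#' @param ordering cyclic ordering from [order_states()].
#' @param n_cycles number of behavioral (left-right) running cycles spanned.
#' @return traversal rate (cycles of the state graph per behavioral cycle).
#' @export
cycle_traversal_rate <- function(segment_states, ordering, n_cycles) {
  ordering <- if (is.list(ordering)) ordering$ordering else ordering
  M <- length(ordering)
  pos <- match(segment_states, ordering)
  pos <- pos[!is.na(pos)]
  if (length(pos) < 2) return(NA_real_)
  step <- diff(pos)
  step <- ((step + M %/% 2) %% M) - M %/% 2
  abs(sum(step)) / M / n_cycles
}
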