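#' Cluster embedded frames into network states
#'
#' Topological mode treats dense clusters as connected components of the
#' point cloud: single-linkage components (computed exactly from the
#' Euclidean minimum spanning tree) are tracked across the radius threshold,
#' and the radius capturing the maximal number of large components (at least
#' `min_points` members) is selected -- the midpoint of the widest radius
#' interval achieving that maximum. Points outside the large components are
#' associated with the cluster containing their nearest assigned neighbor
#' (the limit of growing the radius while keeping previous assignments).
#' K-means mode segments a continuously distributed cloud into `k` compact
#' states (default 8, as used for binned spike-train data).
#'
#' @param e an `embedding` or coordinate matrix.
#' @param mode `"topological"` or `"kmeans"`.
#' @param min_points minimum component size for a topological cluster
#'   (250 for clustering, 50 for sub-clustering).
#' @param k number of K-means states.
#' @param radius optional fixed radius for topological mode.
#' @param stable_ratio a large-component count qualifies as stable when it
#'   persists while the radius grows by at least this factor (topological
#'   mode); merge radii live on a log scale, so persistence is measured
#'   multiplicatively.
#' @param seed seed for K-means restarts.
#' @return a `state_model`: list with `labels` (per embedding row; cluster
#'   ids ordered by decreasing size), `core_labels` (NA for points joined
#'   post hoc), `n_states`, `method`, `radius`, `centers`, `frame_index`.
#' @export
cluster_states <- function(e, mode = c("topological", "kmeans"),
                           min_points = 250, k = 8, radius = NULL,
                           stable_ratio = 1.4, seed = 1) {
  mode <- match.arg(mode)
  X <- if (inherits(e, "embedding")) e$coords else as.matrix(e)
  frame_index <- if (inherits(e, "embedding")) e$frame_index else
    seq_len(nrow(X))
  n <- nrow(X)
  if (n < 1) stop("empty embedding")
  if (mode == "kmeans") {
    set.seed(as.integer(seed))
    km <- kmeans(X, centers = k, nstart = 10, iter.max = 200,
                 algorithm = "MacQueen")
    ord <- order(km$size, decreasing = TRUE)
    relab <- integer(k); relab[ord] <- seq_len(k)
    labels <- relab[km$cluster]
    centers <- km$centers[ord, , drop = FALSE]
    return(structure(list(labels = labels, core_labels = labels,
                          n_states = k, method = "kmeans", radius = NA_real_,
                          centers = centers, frame_index = frame_index),
                     class = "state_model"))
  }
  mst <- cpp_mst(X)
  w <- mst$lengths
  ord <- order(w)
  if (is.null(radius)) {
    # incremental single-linkage: track the number of components >= min_points
    parent <- seq_len(n); size <- rep(1L, n); n_large <- 0L
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    counts <- integer(length(ord))
    for (t in seq_along(ord)) {
      a <- find(mst$edges[ord[t], 1]); b <- find(mst$edges[ord[t], 2])
      if (a != b) {
        was <- (size[a] >= min_points) + (size[b] >= min_points)
        parent[b] <- a
        size[a] <- size[a] + size[b]
        now <- as.integer(size[a] >= min_points)
        n_large <- n_large + now - was
      }
      counts[t] <- n_large
    }
    # a component count is "stable" when it persists while the radius grows
    # by at least stable_ratio: on intact data genuine state regimes span a
    # >=1.5x radius growth, while the marginal component counts produced by
    # shuffled (structure-free) data flip within <1.25x; among stable counts
    # take the maximum, within it the widest interval, and use its midpoint
    r_ref <- unname(quantile(w, 0.995))
    runs <- rle(counts)
    r_ends <- cumsum(runs$lengths); r_starts <- r_ends - runs$lengths + 1
    ws <- w[ord]
    iv_lo <- ws[r_starts]
    iv_hi <- c(ws[r_starts[-1]], max(ws) * 1.1)
    iv_width <- iv_hi - iv_lo
    stable <- runs$values > 0 & iv_hi >= stable_ratio * iv_lo
    best <- if (any(stable)) max(runs$values[stable]) else max(counts)
    if (best == 0) {
      return(structure(list(labels = rep(NA_integer_, n),
                            core_labels = rep(NA_integer_, n), n_states = 0L,
                            method = "topological", radius = NA_real_,
                            centers = NULL, frame_index = frame_index,
                            flagged = "no component reached min_points"),
                       class = "state_model"))
    }
    cand <- which(runs$values == best)
    bi <- cand[which.max(iv_width[cand])]
    radius <- (iv_lo[bi] + min(iv_hi[bi], r_ref * 1.1)) / 2
  }
  keep_edges <- mst$edges[w <= radius, , drop = FALSE]
  comp <- cpp_components(n, keep_edges)
  tab <- tabulate(comp)
  large <- which(tab >= min_points)
  if (!length(large)) large <- which.max(tab)
  large <- large[order(tab[large], decreasing = TRUE)]
  core <- rep(NA_integer_, n)
  for (s in seq_along(large)) core[comp == large[s]] <- s
  labels <- core
  un <- which(is.na(labels))
  if (length(un)) {
    assigned <- which(!is.na(labels))
    nn <- cpp_nn_index(X[un, , drop = FALSE], X[assigned, , drop = FALSE])
    labels[un] <- labels[assigned[nn]]
  }
  centers <- do.call(rbind, lapply(seq_along(large), function(s)
    colMeans(X[labels == s, , drop = FALSE])))
  structure(list(labels = labels, core_labels = core,
                 n_states = length(large), method = "topological",
                 radius = radius, centers = centers,
                 frame_index = frame_index),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %d states (%s) over %d frames\n", x$n_states,
              x$method, length(x$labels)))
  invisible(x)
}

# total candidate-segment count for a given gap threshold (before the
# minimum-length filter); used by the robustness scan
segment_count <- function(labels, frame_index, gap) {
  total <- 0L
  for (s in sort(unique(labels[!is.na(labels)]))) {
    fr <- frame_index[which(labels == s)]
    total <- total + sum(diff(fr) > gap) + 1L
  }
  total
}

#' Choose the maximal-gap threshold by robustness scan
#'
#' Picks the smallest gap (in frames) at which the total number of candidate
#' segments changes by less than 5% when the threshold is perturbed by one
#' frame in either direction -- the plateau of a robust segment-length
#' distribution.
#'
#' @param labels per-frame state ids (NA allowed).
#' @param frame_index original frame index of each label.
#' @param gap_grid candidate gaps in frames.
#' @return chosen gap (integer frames).
#' @export
choose_max_gap <- function(labels, frame_index = seq_along(labels),
                           gap_grid = 1:30) {
  counts <- vapply(c(gap_grid, max(gap_grid) + 1L),
                   function(g) segment_count(labels, frame_index, g),
                   integer(1))
  for (i in seq_along(gap_grid)[-1]) {
    lo <- abs(counts[i] - counts[i - 1]) / max(counts[i], 1L)
    hi <- abs(counts[i + 1] - counts[i]) / max(counts[i], 1L)
    if (lo < 0.05 && hi < 0.05) return(gap_grid[i])
  }
  gap_grid[length(gap_grid)]
}

#' Choose the minimal segment length from the candidate-length distribution
#'
#' The distribution of candidate-segment point counts is typically bimodal
#' (noise-induced micro-segments versus genuine dwell episodes); the
#' threshold is placed at the antimode (kernel-density valley) between the
#' two dominant modes.
#'
#' @param lengths candidate segment lengths (points per segment).
#' @param fallback value returned when no valley is found.
#' @return minimal segment length (points).
#' @export
choose_min_length <- function(lengths, fallback = 5) {
  if (length(lengths) < 10 || length(unique(lengths)) < 3) return(fallback)
  d <- density(lengths, from = min(lengths), to = max(lengths))
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(locmax) < 2) return(fallback)
  top2 <- sort(locmax[order(y[locmax], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  max(fallback, ceiling(d$x[valley]))
}

#' Temporal segmentation of state labels
#'
#' Per state independently, consecutive frames of the state whose gaps do not
#' exceed `max_gap` are merged into candidate segments; segments with fewer
#' than `min_length` points are dropped. A frame can belong to one, several
#' (when gaps of different states interleave), or no segments.
#'
#' @param labels per-frame state ids (NA for unassigned frames).
#' @param frame_index original frame index of each label (gaps are measured
#'   in these units).
#' @param max_gap maximal interval (frames) between consecutive points of a
#'   segment; `NULL` selects it by [choose_max_gap()].
#' @param min_length minimal number of points in a segment; `NULL` selects it
#'   by [choose_min_length()].
#' @return data.frame with columns `state`, `start_idx`, `end_idx` (positions
#'   in `labels`), `start_frame`, `end_frame`, `n_points`, ordered by start;
#'   attributes `max_gap` and `min_length` record the thresholds.
#' @export
temporal_segments <- function(labels, frame_index = seq_along(labels),
                              max_gap = NULL, min_length = NULL) {
  stopifnot(length(labels) == length(frame_index))
  if (is.null(max_gap)) max_gap <- choose_max_gap(labels, frame_index)
  stopifnot(max_gap >= 0)
  states <- sort(unique(labels[!is.na(labels)]))
  cand <- list()
  for (s in states) {
    pos <- which(labels == s)
    if (!length(pos)) next
    fr <- frame_index[pos]
    brk <- c(0L, which(diff(fr) > max_gap), length(fr))
    for (b in seq_len(length(brk) - 1)) {
      ii <- pos[(brk[b] + 1):brk[b + 1]]
      cand[[length(cand) + 1]] <- data.frame(
        state = s, start_idx = ii[1], end_idx = ii[length(ii)],
        start_frame = frame_index[ii[1]], end_frame = frame_index[ii[length(ii)]],
        n_points = length(ii))
    }
  }
  segs <- if (length(cand)) do.call(rbind, cand) else
    data.frame(state = integer(0), start_idx = integer(0),
               end_idx = integer(0), start_frame = integer(0),
               end_frame = integer(0), n_points = integer(0))
  if (is.null(min_length)) min_length <- choose_min_length(segs$n_points)
  stopifnot(min_length >= 1)
  segs <- segs[segs$n_points >= min_length, , drop = FALSE]
  segs <- segs[order(segs$start_idx), , drop = FALSE]
  rownames(segs) <- NULL
  attr(segs, "max_gap") <- max_gap
  attr(segs, "min_length") <- min_length
  segs
}

#' Split a state's segments into subtypes by segment-level PCA
#'
#' The average activity vector of each segment is projected on the first
#' principal component of the segment-by-neuron matrix. Two subtypes are
#' declared only when the 1-d projection splits into two completely
#' separate clusters: some internal spacing of the sorted projections must
#' exceed one Freedman-Diaconis histogram bin width (the alignment-free
#' form of "two modes separated by an empty histogram bin"); otherwise all
#' segments form a single subtype.
#'
#' @param m an [activity_matrix()].
#' @param segments rows of a [temporal_segments()] result (one state).
#' @param labels,frame_index optional per-frame labels aligned with the
#'   embedding; when given, segment averages use only the state's own frames.
#' @return list with `subtype` (1/2 per segment), `n_subtypes`, `projection`
#'   (PC1 scores), `flagged`.
#' @export
segment_subtypes <- function(m, segments, labels = NULL, frame_index = NULL) {
  n_seg <- nrow(segments)
  if (n_seg < 4) {
    return(list(subtype = rep(1L, n_seg), n_subtypes = 1L,
                projection = rep(NA_real_, n_seg),
                flagged = "too few segments"))
  }
  avg <- matrix(0, n_seg, m$n_neurons)
  for (i in seq_len(n_seg)) {
    if (!is.null(labels) && !is.null(frame_index)) {
      sel <- which(labels == segments$state[i] &
                     seq_along(labels) >= segments$start_idx[i] &
                     seq_along(labels) <= segments$end_idx[i])
      fr <- frame_index[sel]
    } else {
      fr <- segments$start_frame[i]:segments$end_frame[i]
    }
    avg[i, ] <- rowMeans(m$values[, fr, drop = FALSE])
  }
  pc <- prcomp(avg, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1]
  if (var(proj) == 0) {
    return(list(subtype = rep(1L, n_seg), n_subtypes = 1L, projection = proj,
                flagged = NULL))
  }
  # two modes separated by an empty gap of at least one Freedman-Diaconis
  # bin width; tested on the sorted projections (alignment-free: an empty
  # histogram bin of that width exists iff some internal spacing exceeds it)
  bw <- 2 * stats::IQR(proj) / length(proj)^(1 / 3)
  if (bw <= 0) bw <- diff(range(proj)) / 10
  sp <- sort(proj)
  n_p <- length(sp)
  spacing <- diff(sp)
  inner <- 2:(n_p - 2) # at least 2 segments on each side of the split
  gap_ok <- FALSE
  split_at <- NA_real_
  if (length(inner) >= 1) {
    gi <- inner[which.max(spacing[inner])]
    if (spacing[gi] >= bw) {
      gap_ok <- TRUE
      split_at <- (sp[gi] + sp[gi + 1]) / 2
    }
  }
  if (!gap_ok) {
    return(list(subtype = rep(1L, n_seg), n_subtypes = 1L, projection = proj,
                flagged = NULL))
  }
  subtype <- ifelse(proj < split_at, 1L, 2L)
  # subtype 1 = larger group, for determinism
  if (sum(subtype == 2) > sum(subtype == 1)) subtype <- 3L - subtype
  list(subtype = subtype, n_subtypes = 2L, projection = proj, flagged = NULL)
}

#' Empirical transition matrix between states
#'
#' Frame level: probability that the next data point belongs to state `i`
#' given the current point is in state `j` (rows = current state). Segment
#' level: the same for consecutive segments in time order. Rows with any
#' outgoing transition sum to 1; a state with no outgoing transitions keeps a
#' zero row.
#'
#' @param x per-frame labels (frame level) or a [temporal_segments()]
#'   data.frame (segment level).
#' @param level `"frame"` or `"segment"`.
#' @param n_states matrix dimension (default: max observed label).
#' @return row-stochastic `n_states` x `n_states` matrix; entry `[j, i]` is
#'   P(next = i | current = j).
#' @export
transition_matrix <- function(x, level = c("frame", "segment"),
                              n_states = NULL) {
  level <- match.arg(level)
  seqv <- if (level == "frame") as.integer(x) else
    as.integer(x$state[order(x$start_idx)])
  if (length(seqv) < 2) stop("need at least 2 labeled items")
  n_states <- n_states %||% max(seqv, na.rm = TRUE)
  P <- matrix(0, n_states, n_states)
  a <- seqv[-length(seqv)]; b <- seqv[-1]
  ok <- !is.na(a) & !is.na(b)
  for (t in which(ok)) P[a[t], b[t]] <- P[a[t], b[t]] + 1
  rs <- rowSums(P)
  nz <- rs > 0
  P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  attr(P, "level") <- level
  P
}

#' Temporal ordering of states from a transition matrix
#'
#' Finds the permutation of the M states that maximizes the summed transition
#' probability along the order. Linear mode constrains the first and last
#' states (most frequent at segment starts and ends) and searches the
#' (M-2)! interior permutations; cyclic mode maximizes the sum over both
#' neighbors around the cycle over the (M-1)!/2 distinct orders (rotation and
#' reflection symmetry). Ties are broken by the lexicographically smallest
#' permutation.
#'
#' @param P transition matrix (rows = current state).
#' @param mode `"linear"` or `"cyclic"`.
#' @param first,last fixed end states for linear mode; inferred from
#'   `start_labels`/`end_labels` when omitted.
#' @param start_labels,end_labels state of the first/last point of each
#'   segment, used to infer the end constraints.
#' @return list with `ordering` (state ids in order), `objective`, `mode`.
#' @export
order_states <- function(P, mode = c("linear", "cyclic"), first = NULL,
                         last = NULL, start_labels = NULL,
                         end_labels = NULL) {
  mode <- match.arg(mode)
  M <- nrow(P)
  if (M < 3) stop("need at least 3 states to order")
  if (M > 10) stop("more than 10 states: coarsen the clustering before ",
                   "ordering (factorial search)")
  if (mode == "linear") {
    if (is.null(first)) {
      if (is.null(start_labels)) stop("linear mode needs `first` or ",
                                      "`start_labels`")
      first <- int_mode(start_labels)
    }
    if (is.null(last)) {
      if (is.null(end_labels)) stop("linear mode needs `last` or ",
                                    "`end_labels`")
      last <- int_mode(end_labels)
      if (identical(last, first)) {
        tab <- sort(table(end_labels), decreasing = TRUE)
        alt <- as.integer(names(tab))
        last <- alt[alt != first][1]
      }
    }
    interior <- setdiff(seq_len(M), c(first, last))
    pm <- all_perms(length(interior))
    orders <- cbind(first, matrix(interior[pm], nrow(pm)), last)
  } else {
    pm <- all_perms(M - 1)
    rest <- (2:M)[pm]
    dim(rest) <- dim(pm)
    # canonical representative of each reflection pair
    keep <- rest[, 1] < rest[, ncol(rest)]
    orders <- cbind(1L, rest[keep, , drop = FALSE])
  }
  obj <- numeric(nrow(orders))
  for (i in seq_len(ncol(orders) - 1)) {
    obj <- obj + P[cbind(orders[, i], orders[, i + 1])]
    if (mode == "cyclic") obj <- obj + P[cbind(orders[, i + 1], orders[, i])]
  }
  if (mode == "cyclic") {
    obj <- obj + P[cbind(orders[, ncol(orders)], orders[, 1])] +
      P[cbind(orders[, 1], orders[, ncol(orders)])]
  }
  best <- which(obj == max(obj))
  if (length(best) > 1) {
    # lexicographically smallest among ties
    ix <- do.call(order, as.data.frame(orders[best, , drop = FALSE]))
    best <- best[ix[1]]
  }
  list(ordering = as.integer(orders[best, ]), objective = max(obj),
       mode = mode)
}
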