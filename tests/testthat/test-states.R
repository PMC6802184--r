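test_that("topological clustering recovers well-separated blobs", {
  set.seed(2)
  X <- rbind(cbind(rnorm(300, 0, 0.2), rnorm(300, 0, 0.2)),
             cbind(rnorm(300, 6, 0.2), rnorm(300, 6, 0.2)),
             cbind(rnorm(300, 0, 0.2), rnorm(300, 6, 0.2)))
  s <- cluster_states(X, "topological", min_points = 100)
  expect_equal(s$n_states, 3)
  truth <- rep(1:3, each = 300)
  expect_equal(length(unique(paste(s$labels, truth))), 3)
  # single dense blob: one cluster containing all points
  s1 <- cluster_states(X[1:300, ], "topological", min_points = 100)
  expect_equal(s1$n_states, 1)
  expect_true(all(s1$labels == 1))
  # nothing reaches min_points: zero states, flagged
  s0 <- cluster_states(X[1:40, ], "topological", min_points = 100)
  expect_equal(s0$n_states, 0)
  expect_true(all(is.na(s0$labels)))
})

test_that("kmeans mode returns exactly k clusters", {
  set.seed(5)
  X <- matrix(rnorm(2000), ncol = 2)
  s <- cluster_states(X, "kmeans", k = 8)
  expect_equal(s$n_states, 8)
  expect_equal(sort(unique(s$labels)), 1:8)
})

test_that("post-hoc assignment equals brute-force nearest-assigned search", {
  set.seed(9)
  core1 <- matrix(rnorm(400, 0, 0.3), ncol = 2)
  core2 <- matrix(rnorm(400, 8, 0.3), ncol = 2)
  stray <- matrix(runif(100, -2, 10), ncol = 2)
  X <- rbind(core1, core2, stray)
  s <- cluster_states(X, "topological", min_points = 150)
  expect_equal(s$n_states, 2)
  un <- which(is.na(s$core_labels))
  if (length(un)) {
    assigned <- which(!is.na(s$core_labels))
    for (i in un) {
      d <- sqrt(rowSums((X[assigned, , drop = FALSE] -
                           matrix(X[i, ], length(assigned), 2,
                                  byrow = TRUE))^2))
      expect_equal(s$labels[i], s$core_labels[assigned[which.min(d)]])
    }
  }
})

test_that("temporal segmentation merges gaps and drops short runs", {
  # unbroken run of one label: a single segment spanning it
  lab <- c(rep(1L, 20))
  seg <- temporal_segments(lab, max_gap = 2, min_length = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_idx, 1)
  expect_equal(seg$end_idx, 20)

  # 3-frame run with min_length 5: no segment
  lab2 <- c(rep(NA_integer_, 5), rep(1L, 3), rep(NA_integer_, 5))
  seg2 <- temporal_segments(lab2, max_gap = 1, min_length = 5)
  expect_equal(nrow(seg2), 0)

  # planted intervals with internal gaps <= max_gap are recovered exactly
  lab3 <- rep(NA_integer_, 100)
  lab3[c(10:14, 17:20)] <- 1L   # gap of 2 frames inside
  lab3[40:60] <- 2L
  lab3[80:82] <- 1L             # too short
  seg3 <- temporal_segments(lab3, max_gap = 3, min_length = 5)
  expect_equal(nrow(seg3), 2)
  s1 <- seg3[seg3$state == 1, ]
  expect_equal(c(s1$start_idx, s1$end_idx), c(10, 20))
  s2 <- seg3[seg3$state == 2, ]
  expect_equal(c(s2$start_idx, s2$end_idx), c(40, 60))

  # a frame may belong to segments of several states (interleaved gaps)
  lab4 <- rep(1L, 30)
  lab4[15] <- 2L
  seg4 <- temporal_segments(lab4, max_gap = 2, min_length = 3)
  expect_equal(nrow(seg4[seg4$state == 1, ]), 1) # gap bridged
})

test_that("segment subtypes split two planted populations", {
  set.seed(13)
  n_neurons <- 60
  # two segment populations with mean activity 4 SD apart on one axis
  n_seg <- 30
  seg_len <- 20
  truth <- rep(1:2, length.out = n_seg)
  v <- matrix(0L, n_neurons, n_seg * seg_len)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    p <- rep(0.1, n_neurons)
    if (truth[s] == 1) p[1:20] <- 0.6 else p[21:40] <- 0.6
    v[, idx] <- matrix(rbinom(n_neurons * seg_len, 1, p), n_neurons)
  }
  m <- activity_matrix(v, 0.05, "imaging")
  segs <- data.frame(state = 1L,
                     start_idx = seq(1, n_seg * seg_len, seg_len),
                     end_idx = seq(seg_len, n_seg * seg_len, seg_len))
  segs$start_frame <- segs$start_idx
  segs$end_frame <- segs$end_idx
  segs$n_points <- seg_len
  st <- segment_subtypes(m, segs)
  expect_equal(st$n_subtypes, 2L)
  expect_equal(length(unique(paste(st$subtype, truth))), 2)

  # identical segments: one subtype
  v2 <- matrix(rep(c(1L, 0L), length.out = 40 * 100), 40, 100)
  m2 <- activity_matrix(v2, 0.05, "imaging")
  segs2 <- data.frame(state = 1L, start_idx = seq(1, 100, 10),
                      end_idx = seq(10, 100, 10))
  segs2$start_frame <- segs2$start_idx; segs2$end_frame <- segs2$end_idx
  segs2$n_points <- 10
  expect_equal(segment_subtypes(m2, segs2)$n_subtypes, 1L)

  # fewer than 4 segments: single subtype, flagged
  st3 <- segment_subtypes(m, segs[1:3, ])
  expect_equal(st3$n_subtypes, 1L)
  expect_match(st3$flagged, "few")
})

test_that("transition matrices match brute-force pair counting", {
  set.seed(17)
  lab <- sample(1:4, 1000, TRUE)
  P <- transition_matrix(lab, "frame")
  counts <- matrix(0, 4, 4)
  for (t in 1:999) counts[lab[t], lab[t + 1]] <- counts[lab[t], lab[t + 1]] + 1
  expect_equal(unname(P), counts / rowSums(counts), ignore_attr = TRUE)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))

  # segment level counts segment-to-segment successions, not frames
  segs <- data.frame(state = c(1, 2, 1, 3, 2),
                     start_idx = c(1, 10, 20, 30, 40),
                     end_idx = c(5, 15, 25, 35, 45))
  Ps <- transition_matrix(segs, "segment", n_states = 3)
  expect_equal(Ps[1, 2], 0.5)
  expect_equal(Ps[1, 3], 0.5)
  expect_equal(Ps[2, 1], 1)
  expect_equal(Ps[3, 2], 1)
  # a state with no outgoing transition keeps a zero row
  lab0 <- c(1L, 1L, 2L)
  P0 <- transition_matrix(lab0, "frame", n_states = 2)
  expect_equal(unname(P0[2, ]), c(0, 0))
})

test_that("order_states maximizes the objective (exhaustive oracle)", {
  set.seed(23)
  for (M in c(4, 6)) {
    P <- matrix(runif(M * M), M, M)
    diag(P) <- 0
    P <- P / rowSums(P)
    first <- 1L; last <- M
    res <- order_states(P, "linear", first = first, last = last)
    orc <- oracle_order_linear(P, first, last)
    expect_equal(res$objective, orc$objective, tolerance = 1e-12)
    expect_equal(res$ordering[1], first)
    expect_equal(res$ordering[M], last)
    resc <- order_states(P, "cyclic")
    expect_equal(resc$objective, oracle_order_cyclic_objective(P),
                 tolerance = 1e-12)
  }
  # linear M = 3 with fixed ends: the unique ordering
  P3 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  r3 <- order_states(P3, "linear", first = 1, last = 3)
  expect_equal(r3$ordering, c(1L, 2L, 3L))
  expect_error(order_states(matrix(0.1, 12, 12), "cyclic"), "coarsen")
})

test_that("a planted ring Markov chain is cyclically ordered correctly", {
  set.seed(29)
  M <- 7
  # stay 0.8, step to either ring neighbor 0.1 each
  P <- matrix(0, M, M)
  for (i in seq_len(M)) {
    P[i, i] <- 0.8
    P[i, (i %% M) + 1] <- 0.1
    P[i, ((i - 2) %% M) + 1] <- 0.1
  }
  # shuffle state identities and check recovery up to rotation/reflection
  perm <- sample(M)
  Pp <- P[perm, perm]
  res <- order_states(Pp, "cyclic")
  recovered <- perm[res$ordering] # back to original ids
  # consecutive original ids must be ring neighbors in the recovered order
  steps <- (diff(c(match(1:M, recovered), match(1, recovered))) + M) %% M
  expect_true(all(steps == steps[1]))
  expect_true(steps[1] %in% c(1, M - 1))
})

test_that("ordering objective is invariant under reflection and rotation", {
  set.seed(31)
  M <- 6
  P <- matrix(runif(M * M), M, M); diag(P) <- 0; P <- P / rowSums(P)
  res <- order_states(P, "cyclic")
  ordv <- res$ordering
  obj_of <- function(o) {
    on <- c(o[-1], o[1])
    sum(P[cbind(o, on)]) + sum(P[cbind(on, o)])
  }
  expect_equal(obj_of(rev(ordv)), res$objective)
  expect_equal(obj_of(c(ordv[-1], ordv[1])), res$objective)
})
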