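test_that("build_activity_matrix bins, binarizes, and filters by modality", {
  # spike trains at 100 ms bins; a bin with 14 active neurons is excluded
  set.seed(42)
  n <- 20
  trains <- lapply(seq_len(n), function(i) sort(runif(30, 0, 10)))
  m <- build_activity_matrix(trains, bin_width = 0.1, modality = "ephys")
  expect_true(all(m$values %in% c(0L, 1L)))
  expect_equal(m$bin_width, 0.1)
  active <- colSums(m$values)
  expect_true(all(active[m$retained_frames] >= 15))
  expect_true(all(active[setdiff(seq_len(m$n_bins), m$retained_frames)] < 15))

  # engineered bin with exactly 14 active neurons must be excluded
  v <- matrix(0L, 20, 3)
  v[1:14, 1] <- 1L
  v[1:15, 2] <- 1L
  me <- activity_matrix(v, 0.1, "ephys")
  expect_false(1L %in% me$retained_frames)
  expect_true(2L %in% me$retained_frames)

  # imaging filter keeps bins with > 1 active neuron
  mi <- activity_matrix(v, 0.05, "imaging")
  expect_setequal(mi$retained_frames, c(1L, 2L))

  # column sums equal a brute-force recount of distinct active neurons
  ev <- data.frame(neuron = sample(1:10, 200, TRUE),
                   frame = sample(1:50, 200, TRUE))
  mm <- build_activity_matrix(ev, 0.1, "imaging", n_neurons = 10, n_bins = 50)
  brute <- vapply(1:50, function(j)
    length(unique(ev$neuron[ev$frame == j])), integer(1))
  expect_equal(unname(colSums(mm$values)), brute)

  # empty input: zero matrix, no retained frames
  m0 <- build_activity_matrix(data.frame(neuron = integer(0),
                                         frame = integer(0)),
                              0.1, "imaging", n_neurons = 5, n_bins = 10)
  expect_equal(sum(m0$values), 0)
  expect_length(m0$retained_frames, 0)
})

test_that("binarization is idempotent", {
  set.seed(1)
  v <- matrix(rbinom(200, 3, 0.3), 10, 20)
  m1 <- activity_matrix(v, 0.1, "ephys")
  m2 <- activity_matrix(m1$values, 0.1, "ephys")
  expect_identical(m1$values, m2$values)
  expect_identical(m1$retained_frames, m2$retained_frames)
})

test_that("shuffle controls preserve the correct margins", {
  set.seed(7)
  v <- matrix(rbinom(3000, 1, 0.15), 30, 100)
  m <- activity_matrix(v, 0.1, "imaging")
  st <- shuffle_control(m, "time", seed = 3)
  expect_equal(rowSums(st$values), rowSums(m$values))
  sc <- shuffle_control(m, "cell", seed = 3)
  expect_equal(colSums(sc$values), colSums(m$values))
  # all-zero matrix unchanged
  z <- activity_matrix(matrix(0L, 5, 8), 0.1, "imaging")
  expect_equal(sum(shuffle_control(z, "time")$values), 0)
  expect_error(shuffle_control(m, "frame"))
  # seeded determinism
  expect_identical(shuffle_control(m, "time", seed = 9)$values,
                   shuffle_control(m, "time", seed = 9)$values)
})

test_that("detect_ca_events finds planted transients and rejects artifacts", {
  fs <- 20
  K <- 1800 # 90 s, so one event passes the 0.01 Hz rate filter
  # one clean transient with a 400 ms decay under the GCaMP6f config:
  # exactly one event, two consecutive active frames at the peak
  tr <- matrix(0, 1, K)
  pk <- 500
  tt <- seq(0, 5, by = 1 / fs)
  tr[1, pk:(pk + length(tt) - 1)] <- 0.2 * exp(-tt / 0.4)
  set.seed(11)
  tr <- tr + matrix(rnorm(K, 0, 0.008), 1, K)
  out <- detect_ca_events(
    structure(list(traces = tr, frame_rate = fs, indicator = "GCaMP6f"),
              class = "fluorescence_traces"))
  expect_equal(nrow(out$events), 1)
  expect_lt(abs(out$events$frame[1] - pk), 5)
  act <- which(out$values[1, ] == 1)
  expect_length(act, 2)
  expect_equal(diff(act), 1)

  # constant trace: no events
  flat <- structure(list(traces = matrix(1, 1, K), frame_rate = fs,
                         indicator = "GCaMP6f"),
                    class = "fluorescence_traces")
  expect_equal(nrow(detect_ca_events(flat)$events), 0)

  # detection is invariant to a constant offset (median subtraction)
  out2 <- detect_ca_events(
    structure(list(traces = tr + 5, frame_rate = fs, indicator = "GCaMP6f"),
              class = "fluorescence_traces"))
  expect_equal(out2$events$frame, out$events$frame)
})

test_that("planted transients are recovered at high SNR", {
  # 100 planted events in seeded noise at ~10x MAD amplitude
  set.seed(5)
  n_neurons <- 10
  fs <- 20
  K <- 6000
  ev <- matrix(0L, n_neurons, K)
  for (i in seq_len(n_neurons)) {
    at <- sort(sample(50:(K - 100), 10))
    at <- at[c(TRUE, diff(at) > 60)] # keep transients separated
    ev[i, at] <- 1L
  }
  planted <- which(ev == 1, arr.ind = TRUE)
  tr <- gen_fluorescence_traces(
    structure(ev, frame_rate = fs), "GCaMP6s",
    noise_sd = 0.007, seed = 99, amplitude = 0.1)
  out <- detect_ca_events(tr)
  # recall: a planted event is recovered if a detected event of the same
  # neuron lies within 5 frames
  hits <- 0
  for (r in seq_len(nrow(planted))) {
    dd <- out$events$frame[out$events$neuron == planted[r, 1]]
    if (length(dd) && min(abs(dd - planted[r, 2])) <= 5) hits <- hits + 1
  }
  recall <- hits / nrow(planted)
  expect_gte(recall, 0.95)
  # false events: detections not near any planted event
  false_ev <- 0
  for (r in seq_len(nrow(out$events))) {
    pp <- planted[planted[, 1] == out$events$neuron[r], 2]
    if (!length(pp) || min(abs(pp - out$events$frame[r])) > 5)
      false_ev <- false_ev + 1
  }
  expect_lte(false_ev, 5)
})

test_that("gen_fluorescence_traces kernel and baseline behave as specified", {
  ev <- matrix(0L, 2, 200)
  tr0 <- gen_fluorescence_traces(structure(ev, frame_rate = 20), "GCaMP6s",
                                 noise_sd = 0.005, seed = 1)
  # zero events: traces are drift + noise only, small amplitude
  expect_lt(max(abs(tr0$traces)), 0.05)
  expect_error(gen_fluorescence_traces(structure(ev, frame_rate = 20),
                                       "GCaMP7"))
  # decay constants default to 600 / 200 ms by indicator: the 6s transient
  # must decay visibly slower than the 6f transient
  ev[1, 50] <- 1L
  t6s <- gen_fluorescence_traces(structure(ev, frame_rate = 20), "GCaMP6s",
                                 noise_sd = 0, seed = 1, drift_sd = 0)
  t6f <- gen_fluorescence_traces(structure(ev, frame_rate = 20), "GCaMP6f",
                                 noise_sd = 0, seed = 1, drift_sd = 0)
  half_time <- function(x) {
    pk <- which.max(x)
    (which(x[pk:length(x)] < x[pk] / 2)[1] - 1) / 20
  }
  expect_gt(half_time(t6s$traces[1, ]), 0.35) # ~ln2 * 0.6
  expect_lt(half_time(t6f$traces[1, ]), 0.25) # ~ln2 * 0.2
})
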