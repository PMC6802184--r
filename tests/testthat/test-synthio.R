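test_that("linear-track sessions respect the track geometry and are
           reproducible", {
  ses <- gen_linear_track_session("ca1", n_neurons = 60, duration = 120,
                                  seed = 7)
  expect_true(all(ses$behavior$position >= 0 &
                    ses$behavior$position <= 96))
  expect_equal(nrow(ses$behavior), 120 * 20)
  expect_true(all(ses$activity$values %in% c(0L, 1L)))
  # same seed twice: bit-identical outputs
  ses2 <- gen_linear_track_session("ca1", n_neurons = 60, duration = 120,
                                   seed = 7)
  expect_identical(ses$activity$values, ses2$activity$values)
  expect_identical(ses$behavior$position, ses2$behavior$position)
  expect_identical(ses$truth, ses2$truth)
  # different seed differs
  ses3 <- gen_linear_track_session("ca1", n_neurons = 60, duration = 120,
                                   seed = 8)
  expect_false(identical(ses$activity$values, ses3$activity$values))
  expect_error(gen_linear_track_session("ca1", duration = -5))
  expect_error(gen_linear_track_session("ca1", duration = 10,
                                        frame_rate = 0))
})

test_that("acc phase cells are recovered by direct binning of generator
           output", {
  ses <- gen_linear_track_session("acc", n_neurons = 150, duration = 480,
                                  seed = 11)
  ti <- traversal_info(ses$behavior)
  truth <- ses$truth
  phase_cells <- which(truth$class == "phase")
  run <- which(!is.na(ti$phase))
  br <- seq(0, 96, length.out = 25)
  centers <- (br[-1] + br[-25]) / 2
  hit <- 0; tot <- 0
  for (i in phase_cells) {
    ev <- ses$events[i, run]
    occ <- tabulate(findInterval(ti$phase[run], br, rightmost.closed = TRUE),
                    24)
    cnt <- vapply(1:24, function(k)
      sum(ev[findInterval(ti$phase[run], br, rightmost.closed = TRUE) == k]),
      numeric(1))
    if (sum(cnt) < 10) next
    rate <- cnt / pmax(occ, 1)
    tot <- tot + 1
    if (abs(which.max(rate) - which.min(abs(centers - truth$pref[i]))) <= 1)
      hit <- hit + 1
  }
  expect_gt(tot, 30)
  expect_gte(hit / tot, 0.9)
})

test_that("acc rate maps are direction symmetric, ca1 maps are not", {
  sa <- gen_linear_track_session("acc", n_neurons = 150, duration = 480,
                                 seed = 13)
  sc <- gen_linear_track_session("ca1", n_neurons = 150, duration = 480,
                                 seed = 13)
  bidir_of <- function(ses, cls, variant) {
    vals <- c()
    for (i in which(ses$truth$class %in% cls)) {
      cv <- external_tuning_curve(ses$activity, ses$behavior, i, "position")
      v <- bidirectionality(cv$right, cv$left, variant)
      vals <- c(vals, v)
    }
    mean(vals, na.rm = TRUE)
  }
  # phase cells look bidirectional once one direction's bins are flipped;
  # direction-selective place cells do not
  acc_phase <- bidir_of(sa, "phase", "phase-flipped")
  ca1_place <- bidir_of(sc, "place", "phase-flipped")
  expect_gt(acc_phase, ca1_place)
  expect_gt(acc_phase, 0.5)
})

test_that("hd sessions plant recoverable preferred directions", {
  ses <- gen_hd_session(n_neurons = 50, duration = 600, seed = 21)
  expect_equal(ses$activity$bin_width, 0.1)
  expect_true(all(ses$behavior$head_direction >= 0 &
                    ses$behavior$head_direction < 2 * pi))
  # duration 0: empty session
  s0 <- gen_hd_session(n_neurons = 10, duration = 0, seed = 1)
  expect_equal(s0$activity$n_bins, 0)
  expect_error(gen_hd_session(rem_fraction = 1.2))
  # empirical preferred directions from wake spikes match planted ones
  wake <- which(ses$behavior$episode == "wake")
  th <- ses$behavior$drive_direction[wake]
  br <- seq(0, 2 * pi, length.out = 41)
  bin <- findInterval(th, br, rightmost.closed = TRUE)
  occ <- tabulate(bin, 40)
  centers <- (br[-1] + br[-41]) / 2
  emp <- vapply(seq_len(50), function(i) {
    cnt <- vapply(1:40, function(k) sum(ses$spikes[i, wake][bin == k]),
                  numeric(1))
    r <- cnt / pmax(occ, 1)
    atan2(sum(r * sin(centers)), sum(r * cos(centers))) %% (2 * pi)
  }, numeric(1))
  expect_gt(circ_cor(emp, ses$truth$pref), 0.95)
  # rem episodes drive the same tuning through the virtual trajectory
  expect_gt(sum(ses$behavior$episode == "rem"), 0)
  frozen <- ses$behavior$head_direction[ses$behavior$episode == "rem"]
  drive <- ses$behavior$drive_direction[ses$behavior$episode == "rem"]
  expect_gt(sd(drive), sd(diff(frozen)))
})

test_that("multiday sessions preserve tuning and hit the requested
           overlap", {
  days <- gen_multiday_sessions(
    base = list(mode = "ca1", n_neurons = 300, duration = 60),
    n_days = 3, overlap = 0.5, seed = 31)
  expect_length(days, 3)
  # planted tuning identical across days
  expect_identical(days[[1]]$truth, days[[3]]$truth)
  # overlap 1: identical rosters
  full <- gen_multiday_sessions(
    base = list(mode = "ca1", n_neurons = 100, duration = 30),
    n_days = 2, overlap = 1, seed = 5)
  expect_identical(full[[1]]$roster, full[[2]]$roster)
  expect_error(gen_multiday_sessions(n_days = 1))
  expect_error(gen_multiday_sessions(n_days = 3, overlap = 0))
  # measured pairwise overlap within 3 SD of the binomial expectation
  r1 <- days[[1]]$roster; r2 <- days[[2]]$roster
  n_obs <- length(intersect(r1, r2))
  expected <- length(r1) * 0.5
  sd3 <- 3 * sqrt(length(r1) * 0.5 * 0.5)
  expect_lt(abs(n_obs - expected), sd3)
  # off-roster neurons are silent
  off <- setdiff(seq_len(300), days[[1]]$roster)
  expect_equal(sum(days[[1]]$activity$values[off, ]), 0)
})

test_that("session CSV round trip preserves the raster and behavior", {
  ses <- gen_linear_track_session("ca1", n_neurons = 20, duration = 30,
                                  seed = 2)
  dir <- tempfile("sess")
  write_session_csv(ses, dir)
  back <- read_session_csv(dir)
  expect_identical(back$activity$values, ses$activity$values)
  expect_equal(back$behavior$position, ses$behavior$position)
  expect_equal(back$truth$pref, ses$truth$pref)
  unlink(dir, recursive = TRUE)
})

test_that("seed splitting is deterministic and leaves the RNG untouched", {
  s1 <- split_seed(99, 5)
  s2 <- split_seed(99, 5)
  expect_identical(s1, s2)
  expect_true(all(s1 < 2^31))
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(split_seed(5, 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})
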