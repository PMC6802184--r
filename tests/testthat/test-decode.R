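test_that("ml_decode equals exhaustive per-frame likelihood maximization", {
  set.seed(60)
  n_neurons <- 12; n_bins <- 15; n_frames <- 80
  rates <- matrix(runif(n_neurons * n_bins, 0.1, 5), n_neurons)
  X <- matrix(rbinom(n_neurons * n_frames, 1, 0.3), n_neurons)
  dt <- 0.1
  res <- ml_decode(X, rates, "linear", bin_values = seq_len(n_bins),
                   bin_width = dt)
  # independent direct evaluation of the Poisson log-likelihood
  for (f in seq_len(n_frames)) {
    ll <- vapply(seq_len(n_bins), function(b) {
      lam <- pmax(rates[, b], 1e-3) * dt
      sum(X[, f] * log(lam) - lam)
    }, numeric(1))
    if (sum(X[, f]) == 0) {
      expect_true(is.na(res$decoded[f]))
    } else {
      expect_equal(res$decoded[f], which.max(ll))
    }
  }
  # a frame exactly matching one bin's pattern, others orthogonal
  pat <- diag(5) * 4 + 0.001
  x1 <- matrix(c(1, 0, 0, 0, 0), 5, 1)
  r1 <- ml_decode(x1, pat, "linear", bin_values = 1:5, bin_width = 1)
  expect_equal(r1$decoded, 1)
})

test_that("gauge search never increases MSE relative to identity", {
  set.seed(61)
  for (i in 1:10) {
    dec <- runif(100, 0, 2 * pi)
    act <- runif(100, 0, 2 * pi)
    mse_id <- mean(circ_diff(dec, act)^2)
    fit <- popstates:::fit_decode_gauge(dec, act, "circular")
    expect_lte(fit$mse, mse_id + 1e-12)
  }
})

test_that("across-structure decoding is exact on a self-decode", {
  set.seed(62)
  internal <- runif(500)
  external <- internal * 96
  r <- across_structure_decode(internal, internal, external, "linear",
                               actual = external, n_bins = 20)
  # exact at state (bin) resolution: error bounded by one bin of the track
  expect_lt(max(abs(r$error_series)), 96 / 20)
  # reflected internal coordinates are recovered via the symmetry search
  r2 <- across_structure_decode(1 - internal, internal, external, "linear",
                                actual = external, n_bins = 20)
  expect_lt(max(abs(r2$error_series)), 96 / 20)
  expect_error(across_structure_decode(internal, internal, external,
                                       "radial"))
})

test_that("nn phase decoding returns the nearest neighbor's phase", {
  set.seed(63)
  train <- matrix(runif(300), 100, 3)
  phase <- runif(100)
  # test points coincident with training points return their phase
  r <- nn_phase_decode(train[11:20, ], train, phase)
  expect_equal(r$decoded, phase[11:20])
  expect_error(nn_phase_decode(train, train[0, , drop = FALSE], phase))
})

test_that("explained variance follows its defining identity", {
  # decoded = actual everywhere -> EV = 1; decode MSE equal to the shuffle
  # MSE -> EV = 0 (checked through the same arithmetic the decoder uses)
  mse_data <- 0; mse_shuffle <- 4
  expect_equal(1 - mse_data / mse_shuffle, 1)
  set.seed(64)
  ses <- gen_linear_track_session("acc", n_neurons = 120, duration = 240,
                                  seed = 65)
  r <- template_decode(ses$activity, ses$behavior, "phase",
                       n_shuffles = 200, seed = 3)
  expect_lte(r$explained_variance, 1)
  expect_gt(r$explained_variance, 0) # phase cells make phase decodable
  # EV is invariant to affine rescaling of the variable's units: scaling
  # decoded and actual by c scales both MSEs by c^2
  d <- r$decoded[!is.na(r$decoded)]; a <- r$actual[!is.na(r$decoded)]
  set.seed(3)
  msh <- mean(vapply(1:50, function(i) mean((d - sample(a))^2), numeric(1)))
  set.seed(3)
  msh2 <- mean(vapply(1:50, function(i)
    mean((7.3 * d + 2 - sample(7.3 * a + 2))^2), numeric(1)))
  expect_equal(1 - mean((d - a)^2) / msh,
               1 - mean((7.3 * d + 2 - (7.3 * a + 2))^2) / msh2,
               tolerance = 1e-10)
})

test_that("shuffle test p-values are calibrated", {
  set.seed(66)
  # perfect decode: minimal p
  act <- runif(300, 0, 2 * pi)
  r <- popstates:::new_decode_result(act, act, "circular")
  r <- shuffle_test_decoding(r, n_shuffles = 100, seed = 1)
  expect_equal(r$shuffle_p, 1 / 101)
  # random decoded series: p approximately uniform over seeded replicates
  reps <- 200
  ps <- vapply(seq_len(reps), function(i) {
    set.seed(1000 + i)
    dec <- sample(act)
    # apply the same gauge fit the decoders apply, so that observed and
    # null series are treated identically
    fit <- popstates:::fit_decode_gauge(dec, act, "circular")
    rr <- popstates:::new_decode_result(fit$decoded, act, "circular")
    shuffle_test_decoding(rr, n_shuffles = 100, seed = i)$shuffle_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phase/time variability separates phase and time coding", {
  ses <- gen_linear_track_session("acc", n_neurons = 80, duration = 480,
                                  seed = 67)
  m <- ses$activity; b <- ses$behavior
  truth <- ses$truth
  phase_cells <- which(truth$class == "phase")
  res <- lapply(phase_cells, function(i) phase_time_variability(m, b, i))
  keep <- !vapply(res, `[[`, logical(1), "excluded")
  expect_gt(sum(keep), 5)
  sdp <- vapply(res[keep], `[[`, numeric(1), "SD_P")
  sdt <- vapply(res[keep], `[[`, numeric(1), "SD_T")
  # pure phase-tuned cells: variability across phase exceeds variability
  # across time for the vast majority of cells
  expect_gte(mean(sdp > sdt), 0.9)
  expect_equal(dim(res[keep][[1]]$joint_rate_map), c(20L, 20L))
  # too few events: excluded
  mq <- m
  mq$values[1, ] <- 0L
  mq$values[1, 1:5] <- 1L
  expect_true(phase_time_variability(mq, b, 1)$excluded)
})
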