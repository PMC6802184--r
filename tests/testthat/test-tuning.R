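test_that("internal positions are evenly spaced and gauges behave", {
  lab <- rep(1:5, each = 10)
  ordv <- list(ordering = c(2L, 1L, 3L, 5L, 4L), mode = "linear")
  tr <- reconstruct_internal_variable(lab, ordv, "linear")
  vals <- sort(unique(tr$value))
  expect_equal(vals, c(0, 0.25, 0.5, 0.75, 1))
  # reflection gauge: feeding a decreasing external flips the map
  ext <- seq(1, 0, length.out = length(lab))
  tr2 <- reconstruct_internal_variable(lab, ordv, "linear", external = ext)
  expect_true(tr2$gauge$reflected ||
                cor(tr2$value, ext) >= cor(1 - tr2$value, ext))

  # circular: theta_hat = theta everywhere -> all errors 0
  labc <- rep(1:8, times = 40)
  ordc <- list(ordering = 1:8)
  trc <- reconstruct_internal_variable(labc, ordc, "circular",
                                       external = 2 * pi * rep(1:8, 40) / 8,
                                       smooth_sigma = 1e-6, smooth_size = 1)
  expect_lt(max(abs(trc$error_series)), 1e-6)
})

test_that("the circular mismatch formula wraps correctly", {
  # mod(theta_hat - theta + pi, 2pi) - pi on an analytic case
  expect_equal(circ_diff(0.05, 2 * pi - 0.05), 0.1, tolerance = 1e-12)
  expect_equal(circ_diff(2 * pi - 0.05, 0.05), -0.1, tolerance = 1e-12)
  expect_equal(circ_diff(pi, 0), pi)
  # gauge fixing never changes the magnitude distribution, only its frame
  set.seed(20)
  th <- runif(200, 0, 2 * pi)
  noise <- rnorm(200, 0, 0.1)
  obs <- (th + noise + 1.3) %% (2 * pi) # rotated truth
  fit <- popstates:::best_circular_gauge(obs, th)
  aligned <- popstates:::apply_circular_gauge(obs, fit$gauge)
  expect_lt(mean(circ_diff(aligned, th)^2), mean(noise^2) * 1.5)
})

test_that("internal tuning curves exclude sparse neurons and keep flat cells
           flat", {
  set.seed(22)
  n_frames <- 2000
  lab <- sample(1:10, n_frames, TRUE)
  ordv <- list(ordering = 1:10)
  tr <- reconstruct_internal_variable(lab, ordv, "linear")
  v <- matrix(0L, 3, n_frames)
  v[1, sample(n_frames, 4)] <- 1L    # 4 events -> excluded
  v[2, sample(n_frames, 600)] <- 1L  # constant-rate neuron
  m <- activity_matrix(v, 0.05, "imaging")
  m$retained_frames <- seq_len(n_frames)
  c1 <- internal_tuning_curve(m, tr, 1)
  expect_true(c1$excluded)
  c2 <- internal_tuning_curve(m, tr, 2, n_bins = 20)
  expect_false(c2$excluded)
  expect_length(c2$rate, 20)
  # flat cell: coefficient of variation of the curve is small
  expect_lt(sd(c2$rate) / mean(c2$rate), 0.2)
})

test_that("external tuning curves follow the binning conventions", {
  ses <- gen_linear_track_session("ca1", n_neurons = 30, duration = 120,
                                  seed = 41)
  m <- ses$activity
  b <- ses$behavior
  cv <- external_tuning_curve(m, b, 1, "position", "right")
  expect_length(cv$rate, 20) # 24 bins minus 2 per end
  expect_equal(cv$bin_centers[1], 10, tolerance = 1e-9) # 3rd 4-cm bin
  ph <- external_tuning_curve(m, b, 1, "phase")
  expect_length(ph$rate, 20)
  # angle variable: 40 bins
  hd <- gen_hd_session(n_neurons = 20, duration = 60, seed = 8)
  ca <- external_tuning_curve(hd$activity, hd$behavior, 1, "angle")
  expect_length(ca$rate, 40)
  expect_equal(diff(ca$bin_centers)[1], 2 * pi / 40, tolerance = 1e-12)
  # no running at speed threshold 1e9: flagged empty curve
  cv0 <- external_tuning_curve(m, b, 1, "position", "right",
                               speed_threshold = 1e9)
  expect_true(cv0$excluded)
})

test_that("smoothed external rate equals a brute-force kernel computation", {
  set.seed(43)
  ses <- gen_linear_track_session("ca1", n_neurons = 5, duration = 120,
                                  seed = 44)
  m <- ses$activity; b <- ses$behavior
  cv <- external_tuning_curve(m, b, 2, "position", "right")
  # brute force: bin occupancy/counts, truncated-gaussian smooth, divide
  sel <- which(b$running_direction == "right" & b$speed > 1)
  br <- seq(0, 96, by = 4)
  bin <- findInterval(b$position[sel], br, rightmost.closed = TRUE)
  occ <- cnt <- numeric(24)
  for (k in 1:24) {
    occ[k] <- sum(bin == k) * m$bin_width
    cnt[k] <- sum(m$values[2, sel[bin == k]])
  }
  occ <- occ[3:22]; cnt <- cnt[3:22]
  kern <- exp(-(-2:2)^2 / (2 * 1.5^2)); kern <- kern / sum(kern)
  smooth1 <- function(x) {
    out <- numeric(20)
    for (i in 1:20) {
      idx <- (i - 2):(i + 2)
      keep <- idx >= 1 & idx <= 20
      out[i] <- sum(kern[keep] * x[idx[keep]]) / sum(kern[keep])
    }
    out
  }
  expect_equal(cv$rate, smooth1(cnt) / smooth1(occ), tolerance = 1e-12)
})

test_that("information per event matches the direct-sum oracle", {
  set.seed(45)
  occ <- runif(20, 1, 10)
  cnt <- rpois(20, 3)
  cv <- popstates:::new_tuning_curve(seq_len(20), occ, cnt, cnt / occ,
                                     cnt / occ, "linear", "external")
  res <- information_per_event(cv, n_shuffles = 50, seed = 2)
  expect_equal(res$information, oracle_information(occ, cnt),
               tolerance = 1e-12)
  # uniform rate over equal-occupancy bins: 0 bits/event
  cvu <- popstates:::new_tuning_curve(1:8, rep(2, 8), rep(5, 8),
                                      rep(2.5, 8), rep(2.5, 8), "linear",
                                      "external")
  expect_equal(information_per_event(cvu, 10)$information, 0,
               tolerance = 1e-12)
  # all events in 1 of 8 equal-occupancy bins: log2(8) = 3 bits/event
  cvd <- popstates:::new_tuning_curve(1:8, rep(2, 8), c(40, rep(0, 7)),
                                      NULL, NULL, "linear", "external")
  expect_equal(information_per_event(cvd, 10)$information, 3,
               tolerance = 1e-12)
  # fewer than 5 events: undefined
  cv4 <- popstates:::new_tuning_curve(1:8, rep(2, 8), c(4, rep(0, 7)),
                                      NULL, NULL, "linear", "external")
  expect_true(is.na(information_per_event(cv4, 10)$information))
  # information is invariant to bin relabeling
  perm <- sample(20)
  cvp <- popstates:::new_tuning_curve(seq_len(20), occ[perm], cnt[perm],
                                      NULL, NULL, "linear", "external")
  expect_equal(information_per_event(cvp, 10)$information, res$information,
               tolerance = 1e-12)
})

test_that("field stats: width, Rayleigh length against the Bessel oracle", {
  # single-bin delta curve: width 1, Rayleigh length 1
  nb <- 40
  th <- 2 * pi * (seq_len(nb) - 0.5) / nb
  delta <- popstates:::new_tuning_curve(th, rep(1, nb),
                                        c(10, rep(0, nb - 1)),
                                        c(10, rep(0, nb - 1)),
                                        NULL, "circular", "external")
  fs <- field_stats(delta)
  expect_equal(fs$width, 1L)
  expect_equal(fs$rayleigh_length, 1, tolerance = 1e-12)
  # uniform circular curve: Rayleigh length 0
  unif <- popstates:::new_tuning_curve(th, rep(1, nb), rep(3, nb),
                                       rep(3, nb), NULL, "circular",
                                       "external")
  expect_equal(field_stats(unif)$rayleigh_length, 0, tolerance = 1e-12)
  # von Mises curve: Rayleigh length equals I1(k)/I0(k) at fine binning
  nb2 <- 3600
  th2 <- 2 * pi * (seq_len(nb2) - 0.5) / nb2
  for (kappa in c(0.5, 2, 5)) {
    r <- exp(kappa * cos(th2 - 1.1))
    vm <- popstates:::new_tuning_curve(th2, rep(1, nb2), r, r, NULL,
                                       "circular", "external")
    expect_equal(field_stats(vm)$rayleigh_length,
                 besselI(kappa, 1) / besselI(kappa, 0), tolerance = 1e-3)
  }
  # all-zero curve: undefined stats
  z <- popstates:::new_tuning_curve(th, rep(1, nb), rep(0, nb), rep(0, nb),
                                    NULL, "circular", "external")
  expect_true(is.na(field_stats(z)$width))
})

test_that("bidirectionality matches Eq-style direct evaluation", {
  set.seed(47)
  mk <- function(r) popstates:::new_tuning_curve(seq_along(r), rep(1,
    length(r)), r * 5 + 5, r, NULL, "linear", "external")
  for (i in 1:5) {
    r1 <- runif(20); r2 <- runif(20)
    expect_equal(bidirectionality(mk(r1), mk(r2)),
                 oracle_bidirectionality(r1, r2), tolerance = 1e-12)
  }
  # identical maps -> 1; disjoint supports -> 0
  r <- runif(20) + 0.1
  expect_equal(bidirectionality(mk(r), mk(r)), 1, tolerance = 1e-12)
  a <- c(rep(1, 10), rep(0, 10)); b <- c(rep(0, 10), rep(1, 10))
  expect_equal(bidirectionality(mk(a), mk(b)), 0, tolerance = 1e-12)
  # phase-flipped variant reverses one map first
  expect_equal(bidirectionality(mk(a), mk(rev(a)), "phase-flipped"), 1,
               tolerance = 1e-12)
})

test_that("leave-one-out internal information is calibrated for untuned
           cells and tracks planted tuning", {
  ses <- gen_hd_session(n_neurons = 35, duration = 240, seed = 55)
  m <- ses$activity
  # untuned cell: corrected information stays within its own shuffle spread
  m2 <- m
  set.seed(77)
  m2$values <- rbind(m$values, rbinom(m$n_bins, 1, 0.3))
  m2$n_neurons <- m$n_neurons + 1L
  res <- internal_information_loo(m2, m2$n_neurons, n_shuffles = 100,
                                  p1 = 0.02, p2 = 0.15, seed = 5)
  spread <- quantile(res$shuffles - mean(res$shuffles), 0.995) -
    quantile(res$shuffles - mean(res$shuffles), 0.005)
  expect_lt(abs(res$corrected), max(spread, 0.05))
  # tuned cells carry more corrected internal information than untuned ones
  tuned <- internal_information_loo(m, 1, n_shuffles = 50, p1 = 0.02,
                                    p2 = 0.15, seed = 5)
  expect_gt(tuned$corrected, res$corrected - 0.02)
})
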