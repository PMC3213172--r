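# build a minimal trajectory object around a hand-made path
fake_traj <- function(time, x) {
  structure(list(time = time, state = matrix(x, ncol = 1,
                                             dimnames = list(NULL, "X")),
                 events = data.frame(), species = "X", seed = 0L,
                 t_end = max(time)),
            class = "delayq_trajectory")
}

test_that("peak detector handles monotone, sawtooth and crowded inputs", {
  # monotone path: no peaks
  mono <- fake_traj(0:10, 0:10)
  expect_equal(nrow(detect_peaks(mono, min_height = 3)$peaks), 0)

  # sawtooth with 10 maxima above threshold: all found at the right times
  tt <- seq(0, 40, by = 0.5)
  x <- round(10 * (2 - abs((tt %% 4) - 2)))  # peaks of 20 at t = 2, 6, ...
  saw <- fake_traj(tt, x)
  pk <- detect_peaks(saw, min_height = 5, refractory = 1)
  expect_equal(nrow(pk$peaks), 10)
  expect_equal(pk$peaks$time, seq(2, 38, by = 4))
  expect_true(all(pk$peaks$height == 20))
  expect_equal(pk$peaks$period[1:9], rep(4, 9))

  # two distinct maxima closer than the refractory: the higher one is kept
  tw <- fake_traj(c(0, 1, 2, 3, 4, 5, 6),
                  c(0, 8, 0, 12, 0, 3, 0))
  pk2 <- detect_peaks(tw, min_height = 5, refractory = 5)
  expect_equal(nrow(pk2$peaks), 1)
  expect_equal(pk2$peaks$height, 12)
})

test_that("oscillator simulation is reproducible and needs delay to fire", {
  spec <- oscillator_spec(delay = gamma_delay(2, 0.2))
  t1 <- simulate_oscillator(spec, n_osc_target = 10, seed = 4)
  t2 <- simulate_oscillator(spec, n_osc_target = 10, seed = 4)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$state, t2$state)

  # with (nearly) no delay the circuit hovers at the threshold: no spikes
  spec0 <- oscillator_spec(delay = gamma_delay(1e-6, 0))
  tr0 <- simulate_oscillator(spec0, n_osc_target = 3, seed = 5,
                             require_peaks = FALSE)
  pk0 <- detect_peaks(tr0, min_height = spec0$C0, refractory = 0.5)
  expect_lt(nrow(pk0$peaks), 3)

  # fixed delay, step Hill: regular relaxation cycles (height CV << 1)
  specf <- oscillator_spec(delay = gamma_delay(2, 1e-9))
  trf <- simulate_oscillator(specf, n_osc_target = 60, seed = 6)
  pkf <- detect_peaks(trf, min_height = specf$C0, refractory = 1)
  expect_gt(nrow(pkf$peaks), 30)
  expect_lt(pkf$summary$sd_height / pkf$summary$mean_height, 0.3)
})

test_that("signaling-time reduction Delta is zero at zero and grows with cv", {
  spec <- oscillator_spec()
  expect_equal(delta_signaling(spec, 0), 0)
  mu <- spec$delay$mean
  dd <- vapply(seq(0, 1, length.out = 6) * mu, function(s)
    delta_signaling(spec, s), numeric(1))
  expect_true(all(dd >= 0))
  expect_true(all(diff(dd) >= -1e-9))
  # large sd with a two-point delay approaches the asymptote gap
  spec_tp <- oscillator_spec(delay = two_point_delay(2, 0.2))
  K <- round(spec_tp$C0)
  gap <- deterministic_limit(spec_tp$lambda0, 2, K) -
    large_sigma_asymptote(spec_tp$lambda0, 2, 2, K)
  expect_equal(delta_signaling(spec_tp, 2), gap, tolerance = 0.01)
})

test_that("peak-height predictions are ordered and decrease with variability", {
  spec <- oscillator_spec()
  H0 <- 75
  expect_equal(peak_height_prediction(spec, 0, H0, "first"), H0)
  expect_equal(peak_height_prediction(spec, 0, H0, "refined"), H0)
  for (s in c(0.5, 1, 1.6)) {
    pf <- peak_height_prediction(spec, s, H0, "first")
    pr <- peak_height_prediction(spec, s, H0, "refined")
    expect_lte(pf, pr)
    expect_lte(pr, H0)
  }
  sg <- seq(0, 1.6, length.out = 5)
  pf <- vapply(sg, function(s) peak_height_prediction(spec, s, H0, "first"), 0)
  pr <- vapply(sg, function(s) peak_height_prediction(spec, s, H0, "refined"), 0)
  expect_true(all(diff(pf) < 0))
  expect_true(all(diff(pr) < 0))
  # no degradation at all: refined degenerates to first order with a warning
  nodeg <- oscillator_spec(beta_dil = 0, gamma_enz = 0)
  expect_error(
    expect_warning(peak_height_prediction(nodeg, 1, H0, "refined"),
                   "degenerates"),
    NA)
})

test_that("ON-window shortening matches the queue theory prediction", {
  # step-Hill oscillator: mean time the production propensity is maximal per
  # cycle tracks E[T_K](sigma)
  for (cv in c(0.2, 0.5)) {
    spec <- oscillator_spec(delay = gamma_delay(2, cv))
    traj <- simulate_oscillator(spec, n_osc_target = 60, seed = 8)
    pk <- detect_peaks(traj, min_height = spec$C0, refractory = 1)
    x <- traj$state[, "X"]; tt <- traj$time
    on <- x < spec$C0
    dt <- diff(tt)
    pt <- pk$peaks$time
    on_dur <- vapply(seq_len(length(pt) - 1L), function(i) {
      sel <- which(tt >= pt[i] & tt < pt[i + 1L])
      sum(dt[sel] * on[sel])
    }, numeric(1))
    theory <- signaling_time_moments(
      queue_spec(spec$lambda0, gamma_delay(2, cv), round(spec$C0)))$mean
    se <- sd(on_dur) / sqrt(length(on_dur))
    expect_lt(abs(mean(on_dur) - theory), max(3 * se, 0.08 * theory))
  }
})
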