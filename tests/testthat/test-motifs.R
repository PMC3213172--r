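test_that("step switch flips exactly at the K-th completed protein", {
  expect_equal(step_hill_rate(9, 10, 2, "activation"), 0)
  expect_equal(step_hill_rate(10, 10, 2, "activation"), 2)
  expect_equal(step_hill_rate(9, 10, 2, "repression"), 2)
  expect_equal(step_hill_rate(10, 10, 2, "repression"), 0)
  expect_equal(step_hill_rate(12, 10, 7, "activation"),
               3.5 * step_hill_rate(12, 10, 2, "activation"))
})

test_that("cascade signaling times add in mean and variance", {
  # two zero-delay stages with equal rate: gamma(K1+K2, lambda)
  z1 <- queue_spec(2, gamma_delay(1e-9, 1), 3)
  z2 <- queue_spec(2, gamma_delay(1e-9, 1), 2)
  cz <- cascade_time(list(z1, z2))
  expect_equal(cz$mean, 5 / 2, tolerance = 1e-5)
  expect_equal(cz$variance, 5 / 4, tolerance = 1e-4)
  # convolved density integrates to one and matches the gamma law
  tt <- cz$grid
  expect_equal(sum(cz$pdf(tt)) * diff(tt[1:2]), 1, tolerance = 1e-3)
  expect_lt(max(abs(cz$pdf(tt) - dgamma(tt, 5, rate = 2))), 0.02)

  # deterministic delays: sum of per-stage deterministic limits
  f1 <- queue_spec(5, fixed_delay(1), 3)
  f2 <- queue_spec(4, fixed_delay(1.5), 2)
  cf <- cascade_time(list(f1, f2))
  expect_equal(cf$mean, (1 + 3 / 5) + (1.5 + 2 / 4), tolerance = 1e-7)

  # full two-gene simulation agrees with the analytic sums
  s1 <- queue_spec(5, two_point_delay(1, 0.5), 3)
  s2 <- queue_spec(4, two_point_delay(1.5, 0.6), 2)
  an <- cascade_time(list(s1, s2))
  net <- two_gene_cascade_network(s1, s2)
  sim <- vapply(1:1500, function(i)
    first_crossing(simulate_network(net, t_end = 15, seed = 7000 + i),
                   "X2", 2), numeric(1))
  expect_lt(abs(mean(sim) - an$mean), 3 * sd(sim) / sqrt(length(sim)))
  expect_lt(abs(var(sim) - an$variance),
            3 * sd((sim - mean(sim))^2) / sqrt(length(sim)))
})

test_that("repressor-windowed production has the documented mean", {
  d <- two_point_delay(1, 0.5)
  # no switch
  expect_equal(repressor_exit_mean(2, d, Inf, 3), 2 * delay_icdf(d, 3))
  # zero delay: lambda * min(t, T)
  tiny <- gamma_delay(1e-9, 1)
  expect_equal(repressor_exit_mean(2, tiny, 1.5, c(1, 4)), c(2, 3),
               tolerance = 1e-6)
  # every initiated protein eventually completes
  expect_equal(repressor_exit_mean(2, d, 3, 50), 2 * 3, tolerance = 1e-9)
  # random shutoff: conditioning matches a manual mixture
  t_off <- list(density = function(x) dunif(x, 1, 2), lower = 1, upper = 2)
  got <- repressor_exit_mean(2, d, t_off, 4)
  manual <- integrate(function(T) vapply(T, function(Ti)
    2 * (delay_icdf(d, 4) - delay_icdf(d, 4 - Ti)), 0) * dunif(T, 1, 2),
    1, 2)$value
  expect_equal(got, manual, tolerance = 1e-7)
})

test_that("windowed variability response follows the midpoint rule", {
  # midpoint below the mean delay: more completions with larger sd
  up <- windowed_sigma_response(1, "two_point", mean = 5, T = 2, t = 5.5,
                                sigma_grid = seq(0.3, 1.5, length.out = 6))
  expect_identical(up$classification, "increasing")
  # midpoint above the mean: fewer
  dn <- windowed_sigma_response(1, "two_point", mean = 5, T = 2, t = 7,
                                sigma_grid = seq(0.3, 1.5, length.out = 6))
  expect_identical(dn$classification, "decreasing")
  # midpoint at the mean: symmetry cancels the derivative
  fl <- windowed_sigma_response(1, "two_point", mean = 5, T = 2, t = 6,
                                sigma_grid = seq(0.3, 1.5, length.out = 6))
  expect_identical(fl$classification, "flat")
  expect_lt(max(abs(diff(fl$values))), 1e-8)
})

test_that("conditional signaling given N initiations shows the trichotomy", {
  # sigma = 0: T_K = K-th arrival + mu
  est0 <- conditional_signaling_given_N(10, fixed_delay(1), K = 4, N = 8,
                                        n_rep = 2e4, seed = 1)
  expect_lt(abs(est0$mean - (4 / 10 + 1)), 3 * est0$se)
  expect_error(conditional_signaling_given_N(1, fixed_delay(1), 4, 3, 10, 1),
               "N >= K")

  sc <- trichotomy_scan(10, "two_point", mean = 1, K = 2,
                        N_grid = c(2, 3, 8), sigma_grid = c(0.2, 0.5, 0.8),
                        n_rep = 3e4, seed = 5)
  expect_identical(sc$classification, c("increasing", "flat", "decreasing"))
  expect_identical(attr(sc, "predicted_flat_N"), 3L)
})

test_that("coherent FFL turn-on is the max of the two path times", {
  mk <- function(d1, d2) ffl_spec("coherent_AND", K12 = 3, K13 = 4, K23 = 2,
                                  lambda1 = 5, lambda2 = 5, beta3 = 1,
                                  delay1 = d1, delay2 = d2)
  # fixed delays, well-separated branches: the turn-on concentrates on the
  # longer deterministic path sum (initiation noise stays, so compare at MC
  # precision)
  sp <- mk(fixed_delay(1), fixed_delay(1.5))
  an <- coherent_ffl_on_time(sp, n_rep = 5000, seed = 1, mode = "analytic")
  det <- max(1 + 4 / 5, (1 + 3 / 5) + (1.5 + 2 / 5))
  expect_lt(abs(an$mean - det), 3 * an$se)

  # K13 = 1 with a huge lambda1: the indirect branch dominates
  sp2 <- ffl_spec("coherent_AND", K12 = 1, K13 = 1, K23 = 3,
                  lambda1 = 500, lambda2 = 2, beta3 = 1,
                  delay1 = gamma_delay(0.1, 0.5), delay2 = gamma_delay(1, 0.5))
  an2 <- coherent_ffl_on_time(sp2, n_rep = 3000, seed = 2, mode = "analytic")
  qs <- delayq:::ffl_queues(sp2)
  branch <- signaling_time_moments(qs$T12)$mean +
    signaling_time_moments(qs$T23)$mean
  expect_equal(an2$mean, branch, tolerance = 3 * an2$se / branch)

  # analytic-mode mean decreases with a shared delay sd
  means <- vapply(c(0.05, 0.4, 0.8), function(s) {
    sp <- mk(two_point_delay(1, s), two_point_delay(1.5, s))
    coherent_ffl_on_time(sp, n_rep = 4000, seed = 3, mode = "analytic")$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  # simulation mode agrees with the analytic approximation within a few SE
  sp3 <- mk(gamma_delay(1, 0.4), gamma_delay(1.5, 0.4))
  sim <- coherent_ffl_on_time(sp3, n_rep = 300, seed = 4, mode = "simulation")
  ana <- coherent_ffl_on_time(sp3, n_rep = 20000, seed = 5, mode = "analytic")
  expect_lt(abs(sim$mean - ana$mean), 4 * sim$se)
})

test_that("incoherent FFL pulse follows the three-term linear combination", {
  d <- gamma_delay(1, 0.3)
  sp <- ffl_spec("incoherent", K12 = 8, K13 = 2, K23 = 5,
                 lambda1 = 5, lambda2 = 5, beta3 = 5,
                 delay1 = d, delay2 = d)
  # deterministic check at sigma = 0
  res0 <- incoherent_ffl_pulse(sp, sigma_grid = 0, mode = "analytic")
  det <- (1 + 8 / 5) + (1 + 5 / 5) - (1 + 2 / 5)
  expect_equal(res0$pulse, det, tolerance = 1e-6)

  # K12 = K13: the gene-1 terms cancel and the pulse is E[T23]
  spc <- ffl_spec("incoherent", K12 = 4, K13 = 4, K23 = 5,
                  lambda1 = 5, lambda2 = 5, beta3 = 5,
                  delay1 = d, delay2 = d)
  resc <- incoherent_ffl_pulse(spc, sigma_grid = 0.3, mode = "analytic")
  t23 <- signaling_time_moments(queue_spec(5, gamma_delay(1, 0.3), 5))$mean
  expect_equal(resc$pulse, t23, tolerance = 1e-6)

  # analytic vs simulation on one grid point
  both <- incoherent_ffl_pulse(sp, sigma_grid = 0.4, mode = "both",
                               n_rep = 500, seed = 11)
  ana <- both$pulse[both$mode == "analytic"]
  sim <- both[both$mode == "simulation", ]
  expect_lt(abs(sim$pulse - ana), 3 * sim$se)
  expect_equal(sim$empty_fraction, 0)
})
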