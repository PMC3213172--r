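test_that("transient departure and queue means obey the Poisson-law identities", {
  # zero-delay limit: departures are the arrivals
  z <- queue_spec(2, gamma_delay(1e-9, 1), 1)
  expect_equal(departure_mean(z, 5), 10, tolerance = 1e-6)
  expect_equal(queue_mean(z, 5), 0, tolerance = 1e-5)

  qs <- queue_spec(2, two_point_delay(1, 0.5), 1)
  expect_equal(departure_mean(qs, 2), 2 * 1)   # 2 * Lambda(2)
  expect_equal(departure_mean(qs, 0), 0)
  # stationary queue mean -> lambda * mu
  expect_equal(queue_mean(qs, 50), 2 * 1, tolerance = 1e-8)
  # conservation lambda*t = E[Q] + E[D] on a grid
  tt <- seq(0, 5, length.out = 50)
  expect_equal(queue_mean(qs, tt) + departure_mean(qs, tt), 2 * tt,
               tolerance = 1e-8)
})

test_that("signaling-time density matches the rescaled gamma law", {
  # zero delay: exactly gamma(K, lambda)
  z <- queue_spec(2, gamma_delay(1e-9, 1), 4)
  tt <- c(0.5, 1, 3)
  expect_equal(signaling_time_pdf(z, tt), dgamma(tt, 4, rate = 2),
               tolerance = 1e-5)

  # the delay CDF's jump at tau2 propagates into the density
  qs <- queue_spec(1, two_point_delay(1, 0.5), 2)
  left <- signaling_time_pdf(qs, 1.5 - 1e-9)
  right <- signaling_time_pdf(qs, 1.5)
  expect_equal(right / left, 2, tolerance = 1e-6)  # F jumps 1/2 -> 1

  # density integrates to one (gamma delay, with breakpoints)
  qg <- queue_spec(1, gamma_delay(1, 0.5), 3)
  total <- integrate(function(t) signaling_time_pdf(qg, t), 0, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)

  # CDF is the regularized gamma of the rescaled clock
  expect_equal(signaling_time_cdf(qg, 2),
               pgamma(1 * delay_icdf(gamma_delay(1, 0.5), 2), 3, rate = 1))
})

test_that("moments agree across the rescaled, t-axis and Monte Carlo routes", {
  qs <- queue_spec(1, two_point_delay(1, 0.5), 2)
  m_res <- signaling_time_moments(qs)
  m_tax <- signaling_time_moments(qs, method = "t_axis")
  expect_equal(m_res$mean, m_tax$mean, tolerance = 1e-6)
  expect_equal(m_res$variance, m_tax$variance, tolerance = 1e-6)
  expect_equal(m_res$cv, m_res$sd / m_res$mean)

  x <- simulate_signaling_times(qs, 2e4, seed = 3)
  expect_lt(abs(mean(x) - m_res$mean), 3 * sd(x) / sqrt(2e4))

  # deterministic delay: mean = mu + K/lambda, gamma-part variance only
  qf <- queue_spec(2, fixed_delay(3), 4)
  mf <- signaling_time_moments(qf)
  expect_equal(mf$mean, 3 + 4 / 2, tolerance = 1e-8)
  expect_equal(mf$variance, 4 / 4, tolerance = 1e-6)

  # zero delay K=4, lambda=2: plain gamma moments
  mz <- signaling_time_moments(queue_spec(2, gamma_delay(1e-9, 1), 4))
  expect_equal(mz$mean, 2, tolerance = 1e-5)
  expect_equal(mz$variance, 1, tolerance = 1e-4)
})

test_that("two-point closed form reduces correctly in its limits", {
  # sigma = 0: deterministic limit
  expect_equal(two_point_mean_closed_form(2, 1, 0, 3), 1 + 3 / 2)
  # K = 1 closed-form reduction
  expect_equal(two_point_mean_closed_form(2, 1, 0.5, 1),
               1 - 0.5 + 2 / 2 - exp(-2 * 0.5) / 2, tolerance = 1e-12)
  # continuity towards sigma -> 0+
  expect_equal(two_point_mean_closed_form(1, 1, 1e-9, 2),
               deterministic_limit(1, 1, 2), tolerance = 1e-7)
  expect_error(two_point_mean_closed_form(1, 1, 1.5, 2), "sd <= mean")
})

test_that("asymptotes bracket the closed form and cross at K/lambda", {
  expect_equal(deterministic_limit(1, 1, 2), 3)
  expect_equal(deterministic_limit(10, 5, 20), 7)
  expect_equal(large_sigma_asymptote(1, 10, 8, 2), 6)
  # slope in sigma is exactly -1
  s1 <- large_sigma_asymptote(2, 5, 1, 3)
  s2 <- large_sigma_asymptote(2, 5, 2, 3)
  expect_equal(s2 - s1, -1)
  expect_equal(transition_sigma(1, 2), 2)
  expect_equal(transition_sigma(4, 2), 0.5)
  # the two lines meet at sigma* = K/lambda
  lam <- 3; K <- 4; mu <- 3
  sg <- transition_sigma(lam, K)
  expect_equal(deterministic_limit(lam, mu, K),
               large_sigma_asymptote(lam, mu, sg, K))
  # at sigma* the two lines meet; the exact mean lies strictly below their
  # common value (the lines form the envelope of the curve from above, and
  # the curve approaches each line at its end of the sigma axis; exact for
  # K = 1: mean = asymptote - exp(-lambda*sigma)/lambda)
  m <- two_point_mean_closed_form(2, 4, transition_sigma(2, 5), 5)
  expect_lt(m, deterministic_limit(2, 4, 5))
  expect_lt(m, large_sigma_asymptote(2, 4, transition_sigma(2, 5), 5))
  expect_equal(two_point_mean_closed_form(2, 4, 3, 1),
               large_sigma_asymptote(2, 4, 3, 1) - exp(-2 * 3) / 2,
               tolerance = 1e-12)

  # envelope over a parameter grid
  for (K in c(1, 3, 8)) for (r in c(0.1, 0.4, 0.9)) {
    m <- two_point_mean_closed_form(2, 2, 2 * r, K)
    expect_lte(m, deterministic_limit(2, 2, K) + 1e-12)
    expect_lte(m, large_sigma_asymptote(2, 2, 2 * r, K) + 1e-12)
  }
  # deep acceleration regime: within 1% of the linear asymptote
  expect_equal(two_point_mean_closed_form(10, 6, 5, 2),
               large_sigma_asymptote(10, 6, 5, 2), tolerance = 0.01)
})

test_that("normal-delay approximation matches quadrature and its limits", {
  expect_equal(normal_mean_approx(2, 1, 0, 3)$mean, 1 + 3 / 2)
  full <- signaling_time_moments(queue_spec(1, normal_delay(10, 1), 3))$mean
  appr <- normal_mean_approx(1, 10, 1, 3)
  expect_lt(abs(appr$mean - full), 1e-4 * 10)
  expect_identical(appr$regime, "deterministic")
  expect_identical(normal_mean_approx(10, 1, 0.8, 2)$regime, "accelerated")
  # monotone non-increasing in sigma
  grid <- seq(0, 0.3, length.out = 7) * 10
  vals <- vapply(grid, function(s) normal_mean_approx(1, 10, s, 3)$mean, 0)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("mean signaling time decreases with delay sd for symmetric families", {
  lam <- 4; mu <- 1; K <- 3
  tp <- vapply(seq(0.04, 0.8, length.out = 20) * mu, function(s)
    signaling_time_moments(queue_spec(lam, two_point_delay(mu, s), K))$mean, 0)
  expect_true(all(diff(tp) < 0))
  no <- vapply(seq(0.015, 0.3, length.out = 20) * mu, function(s)
    signaling_time_moments(queue_spec(lam, normal_delay(mu, s), K))$mean, 0)
  expect_true(all(diff(no) < 0))
})

test_that("order-statistic Monte Carlo is exact and reproducible", {
  z <- queue_spec(2, gamma_delay(1e-9, 1), 3)
  x <- simulate_signaling_times(z, 2e4, seed = 5)
  expect_identical(x, simulate_signaling_times(z, 2e4, seed = 5))
  expect_lt(abs(mean(x) - 3 / 2), 3 * sd(x) / sqrt(2e4))
  p <- suppressWarnings(ks.test(x, pgamma, shape = 3, rate = 2)$p.value)
  expect_gt(p, 0.01)

  qs <- queue_spec(1, two_point_delay(1, 0.5), 2)
  y <- simulate_signaling_times(qs, 2e4, seed = 6)
  expect_lt(abs(mean(y) - two_point_mean_closed_form(1, 1, 0.5, 2)),
            3 * sd(y) / sqrt(2e4))
})

test_that("signaling time becomes normal and distribution-free at large K", {
  # true skewness here is essentially that of a gamma(K) clock, 2/sqrt(K)
  # = 0.141, so the 0.15 bound needs a skewness standard error well under
  # 0.004: chunked 4e5-replicate samples
  lam <- 10; mu <- 1; sig <- 0.5; K <- 200
  for (d in list(two_point_delay(mu, sig), gamma_delay(mu, sig / mu))) {
    qs <- queue_spec(lam, d, K)
    x <- unlist(lapply(1:20, function(i)
      simulate_signaling_times(qs, 20000, seed = 900 + i)))
    expect_lt(abs(skewness(x)), 0.15)
    expect_equal(mean(x), signaling_time_moments(qs)$mean,
                 tolerance = 5 * sd(x) / sqrt(length(x)) /
                   signaling_time_moments(qs)$mean)
  }
})
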