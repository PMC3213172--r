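#' Queue specification for a single gene
#'
#' Couples a constant transcription-initiation rate, a delay distribution and
#' a signaling threshold.  Initiations form a Poisson process with rate
#' `rate`; each initiated protein matures after an independent delay; the
#' signaling time `T_K` is the first time `threshold` mature proteins exist.
#'
#' @param rate Initiation rate lambda (initiations per unit time, > 0).
#' @param delay A [delay_dist] object.
#' @param threshold Integer threshold K >= 1 (number of completed proteins
#'   that flips the downstream switch).
#' @return An object of class `queue_spec`.
#' @examples
#' qs <- queue_spec(2, two_point_delay(1, 0.5), threshold = 3)
#' departure_mean(qs, 2)
#' signaling_time_moments(qs)$mean
#' @export
queue_spec <- function(rate, delay, threshold) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0,
            inherits(delay, "delay_dist"))
  if (threshold < 1 || threshold != round(threshold))
    stop("`threshold` must be an integer >= 1", call. = FALSE)
  structure(list(rate = rate, delay = delay, threshold = as.integer(threshold)),
            class = "queue_spec")
}

#' @export
print.queue_spec <- function(x, ...) {
  cat("<queue_spec> rate:", x$rate, " threshold:", x$threshold, "\n")
  print(x$delay)
  invisible(x)
}

#' Transient means of the departure and queue-size processes
#'
#' At any fixed time the number of completed proteins `D(t)` is Poisson with
#' mean `lambda * Lambda(t)` (`Lambda` the integrated delay CDF), and the
#' number of still-maturing proteins `Q(t)` is Poisson with mean
#' `lambda * (t - Lambda(t))`.  Their means add up to the arrival mean
#' `lambda * t`.
#'
#' @param spec A [queue_spec].
#' @param t Numeric vector of times, `>= 0`.
#' @return Expected counts, same length as `t`.
#' @export
departure_mean <- function(spec, t) {
  stopifnot(inherits(spec, "queue_spec"))
  spec$rate * delay_icdf(spec$delay, t)
}

#' @rdname departure_mean
#' @export
queue_mean <- function(spec, t) {
  stopifnot(inherits(spec, "queue_spec"))
  spec$rate * (t - delay_icdf(spec$delay, t))
}

#' Signaling-time density, CDF and random sampler
#'
#' The first-passage time `T_K` to K completed proteins has density
#' `f(t) = lambda F(t) (lambda Lambda(t))^(K-1) exp(-lambda Lambda(t)) / (K-1)!`:
#' the gamma(K, lambda) law of the K-th event of a homogeneous Poisson
#' process, pushed through the inverse of the time rescaling
#' `t -> Lambda(t)`.  Jumps of F (two-point and fixed delays) appear as jump
#' discontinuities of the density and are preserved: the density is evaluated
#' with the right-continuous F, and [delay_atoms()] lists the breakpoints a
#' plotting or quadrature grid should include.  The CDF
#' `P(T_K <= t) = P(D(t) >= K)` is continuous regardless.
#'
#' `rsignaling()` draws exact samples by mapping gamma(K, rate = lambda)
#' variates through the generalized inverse of `Lambda`; it samples the
#' analytic law directly and is distinct from the arrival-based Monte Carlo
#' oracle [simulate_signaling_times()].
#'
#' @param spec A [queue_spec].
#' @param t Numeric vector of times, `>= 0`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Density values, probabilities, or samples.
#' @export
signaling_time_pdf <- function(spec, t) {
  stopifnot(inherits(spec, "queue_spec"))
  lam <- spec$rate
  K <- spec$threshold
  lam * delay_cdf(spec$delay, t) *
    dgamma(lam * delay_icdf(spec$delay, pmax(t, 0)), shape = K, rate = 1)
}

#' @rdname signaling_time_pdf
#' @export
signaling_time_cdf <- function(spec, t) {
  stopifnot(inherits(spec, "queue_spec"))
  pgamma(spec$rate * delay_icdf(spec$delay, pmax(t, 0)),
         shape = spec$threshold, rate = 1)
}

#' @rdname signaling_time_pdf
#' @export
rsignaling <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "queue_spec"))
  if (!is.null(seed)) set.seed(seed)
  s <- rgamma(n, shape = spec$threshold, rate = spec$rate)
  delay_icdf_inv(spec$delay, s)
}

# knots of the inverse integrated CDF on the rescaled axis, used to split
# quadrature intervals
rescaled_knots <- function(delay) {
  switch(delay$family,
         two_point = delay$sd,
         numeric(0))
}

#' Mean, variance and CV of the signaling time
#'
#' Moments are computed on the rescaled axis:
#' `E[T_K^m] = integral_0^Inf (Lambda^{-1}(s))^m g(s) ds` with `g` the
#' gamma(K, rate = lambda) density, by adaptive quadrature split at the knots
#' of the piecewise-defined inverse.  The equivalent t-axis integral against
#' the signaling-time density is available as a cross-check via
#' `method = "t_axis"`.
#'
#' @param spec A [queue_spec].
#' @param method `"rescaled"` (default) or `"t_axis"` (cross-check route).
#' @param rel_tol Relative quadrature tolerance.
#' @param grid_n Number of grid points for the returned density grid.
#' @return An object of class `signaling_summary`: a list with `mean`,
#'   `variance`, `sd`, `cv`, `pdf` (vectorized density function), `cdf`,
#'   `grid` (evaluation grid including all atoms of the delay law) and
#'   `spec`.
#' @export
signaling_time_moments <- function(spec, method = c("rescaled", "t_axis"),
                                   rel_tol = 1e-10, grid_n = 512L) {
  stopifnot(inherits(spec, "queue_spec"))
  method <- match.arg(method)
  lam <- spec$rate
  K <- spec$threshold
  d <- spec$delay

  if (method == "rescaled") {
    knots <- rescaled_knots(d)
    moment <- function(pow) {
      f <- function(s) delay_icdf_inv(d, s)^pow * dgamma(s, K, rate = lam)
      piecewise_integrate(f, c(0, knots, Inf), rel_tol = rel_tol)
    }
    m1 <- moment(1)
    m2 <- moment(2)
  } else {
    atoms <- delay_atoms(d)
    upper <- delay_icdf_inv(d, qgamma(1 - 1e-13, K, rate = lam)) + 1
    moment <- function(pow) {
      f <- function(t) t^pow * signaling_time_pdf(spec, t)
      piecewise_integrate(f, sort(unique(c(0, atoms, upper, Inf))),
                          rel_tol = rel_tol)
    }
    m1 <- moment(1)
    m2 <- moment(2)
  }

  v <- max(m2 - m1^2, 0)
  qlo <- qgamma(1e-7, K, rate = lam)
  qhi <- qgamma(1 - 1e-7, K, rate = lam)
  rng <- delay_icdf_inv(d, c(qlo, qhi))
  grid <- sort(unique(c(seq(rng[1], rng[2], length.out = grid_n),
                        delay_atoms(d))))
  grid <- grid[grid >= 0]
  structure(
    list(mean = m1, variance = v, sd = sqrt(v), cv = sqrt(v) / m1,
         pdf = function(t) signaling_time_pdf(spec, t),
         cdf = function(t) signaling_time_cdf(spec, t),
         grid = grid, spec = spec),
    class = "signaling_summary"
  )
}

#' @export
print.signaling_summary <- function(x, ...) {
  cat("<signaling_summary> mean:", format(x$mean),
      " sd:", format(x$sd), " cv:", format(x$cv), "\n")
  invisible(x)
}

# adaptive quadrature over consecutive breakpoint intervals
piecewise_integrate <- function(f, breaks, rel_tol = 1e-10) {
  breaks <- sort(unique(breaks))
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    if (lo == hi) next
    total <- total + integrate(f, lo, hi, rel.tol = rel_tol,
                               subdivisions = 400L,
                               stop.on.error = TRUE)$value
  }
  total
}

#' Closed-form mean signaling time for the two-point delay
#'
#' For the symmetric two-point delay (values `mu - sigma`, `mu + sigma` with
#' probability 1/2) the mean first-passage time to K completed proteins is
#'
#' `E[T_K] = mu + K/lambda - sigma * P(K, lambda sigma) + (K/lambda) * P(K+1, lambda sigma)`
#'
#' where `P` is the regularized lower incomplete gamma function
#' (`pgamma(lambda * sigma, shape, rate = 1)`).  This follows from
#' integrating the piecewise-linear inverse integrated CDF against the
#' gamma(K, lambda) density.  It interpolates between the deterministic limit
#' `mu + K/lambda` at `sigma = 0` and the large-variability asymptote
#' `mu - sigma + 2K/lambda`.
#'
#' @param rate Initiation rate lambda.
#' @param mean Mean delay mu.
#' @param sd Delay standard deviation sigma (0 <= sd <= mean).
#' @param threshold Threshold K.
#' @return Mean signaling time.
#' @export
two_point_mean_closed_form <- function(rate, mean, sd, threshold) {
  stopifnot(rate > 0, mean > 0, threshold >= 1)
  if (sd < 0 || sd > mean)
    stop("two-point delay requires 0 <= sd <= mean", call. = FALSE)
  K <- threshold
  x <- rate * sd
  mean + K / rate - sd * pgamma(x, K, rate = 1) +
    (K / rate) * pgamma(x, K + 1, rate = 1)
}

#' Small- and large-variability asymptotes of the mean signaling time
#'
#' `deterministic_limit()` returns `mu + K/lambda`: the mean delay plus the
#' average time to initiate K proteins, exact at `sigma = 0` and approached
#' rapidly as the threshold grows.  `large_sigma_asymptote()` returns
#' `mu - sigma + 2K/lambda` (slope exactly -1 in sigma), valid when
#' `lambda * sigma >> K`.  The two lines intersect at
#' `sigma = K/lambda = transition_sigma()`, the boundary between the
#' deterministic regime and the regime where increasing delay variability
#' accelerates signaling.
#'
#' @param rate Initiation rate lambda.
#' @param mean Mean delay mu.
#' @param sd Delay standard deviation sigma.
#' @param threshold Threshold K.
#' @return A time (asymptotic mean signaling time, or the transition sigma).
#' @export
deterministic_limit <- function(rate, mean, threshold) {
  mean + threshold / rate
}

#' @rdname deterministic_limit
#' @export
large_sigma_asymptote <- function(rate, mean, sd, threshold) {
  if (sd > mean) stop("requires sd <= mean", call. = FALSE)
  mean - sd + 2 * threshold / rate
}

#' @rdname deterministic_limit
#' @export
transition_sigma <- function(rate, threshold) {
  threshold / rate
}

#' Two-regime approximation of the mean signaling time for normal delay
#'
#' Uses the closed-form integrated CDF of the untruncated normal,
#' `Lambda(t) = (t - mu) Phi(z) + sigma phi(z)` with `z = (t - mu)/sigma`,
#' which agrees with the truncated-normal Lambda up to terms exponentially
#' small in `(mu/sigma)^2`; the approximation is integrated on the rescaled
#' axis against the gamma(K, lambda) density.  A regime label reports which
#' side of the transition `sigma* = K/lambda` the parameters fall on.
#'
#' @param rate Initiation rate lambda.
#' @param mean Mean delay mu.
#' @param sd Delay standard deviation sigma.
#' @param threshold Threshold K.
#' @return A list with `mean` (approximate mean signaling time) and `regime`
#'   (`"deterministic"` if `lambda * sigma < K`, else `"accelerated"`).
#' @export
normal_mean_approx <- function(rate, mean, sd, threshold) {
  stopifnot(rate > 0, mean > 0, sd >= 0, threshold >= 1)
  K <- threshold
  if (sd == 0) {
    m <- mean + K / rate
  } else {
    icdf_u <- function(t) {
      z <- (t - mean) / sd
      (t - mean) * pnorm(z) + sd * dnorm(z)
    }
    lo_t <- mean - 8 * sd
    inv_u <- function(s) {
      vapply(s, function(si) {
        if (si <= icdf_u(lo_t)) return(lo_t)
        uniroot(function(t) icdf_u(t) - si,
                lower = lo_t, upper = si + mean + 1,
                tol = 1e-11 * mean)$root
      }, numeric(1))
    }
    m <- piecewise_integrate(
      function(s) inv_u(s) * dgamma(s, K, rate = rate),
      c(0, Inf), rel_tol = 1e-9)
  }
  list(mean = m,
       regime = if (rate * sd < K) "deterministic" else "accelerated")
}

#' Monte Carlo signaling times from explicit queue order statistics
#'
#' The independent simulation oracle for the analytics: per replicate,
#' arrival times are drawn as a Poisson process of rate lambda, each arrival
#' receives an independent delay, and the K-th smallest completion time is
#' returned.  Arrivals are generated until the running K-th order statistic
#' is provably final, i.e. the next arrival time exceeds the current K-th
#' smallest completion (later arrivals cannot complete earlier than they
#' arrive), so there is no horizon-truncation bias.
#'
#' @param spec A [queue_spec].
#' @param n_rep Number of replicates.
#' @param seed Integer seed (same seed, same sample vector).
#' @return Numeric vector of `n_rep` signaling times.
#' @export
simulate_signaling_times <- function(spec, n_rep, seed) {
  stopifnot(inherits(spec, "queue_spec"), n_rep >= 1)
  set.seed(seed)
  lam <- spec$rate
  K <- spec$threshold
  d <- spec$delay
  mu <- delay_mean(d); sig <- delay_sd(d)

  # batch size: enough arrivals that the last one a.s. exceeds T_K
  horizon <- mu + 6 * sig + K / lam
  M <- max(K + 5L,
           ceiling(lam * horizon + 4 * sqrt(lam * horizon + 1)) + 10L)

  draw_batch <- function(n) {
    A <- matrix(rexp(n * M, lam), n, M)
    for (j in 2:M) A[, j] <- A[, j - 1L] + A[, j]
    comp <- A + matrix(sample_delay(d, n * M), n, M)
    tk <- apply(comp, 1L, function(x) sort.int(x, partial = K)[K])
    list(tk = tk, last_arrival = A[, M])
  }

  b <- draw_batch(n_rep)
  out <- b$tk
  # rare replicates where the batch was too short: redo one-by-one, exactly
  redo <- which(b$last_arrival <= out)
  for (i in redo) {
    arr <- cumsum(rexp(M, lam))
    comp <- arr + sample_delay(d, M)
    repeat {
      ck <- sort.int(comp, partial = K)[K]
      if (arr[length(arr)] > ck) break
      ext <- arr[length(arr)] + cumsum(rexp(M, lam))
      comp <- c(comp, ext + sample_delay(d, M))
      arr <- c(arr, ext)
    }
    out[i] <- sort.int(comp, partial = K)[K]
  }
  out
}
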