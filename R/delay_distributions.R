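#' Delay distributions for protein maturation times
#'
#' A `delay_dist` represents the random time tau between the initiation of
#' transcription and the appearance of a fully mature protein.  All queueing
#' analytics in the package are driven by three derived functions of the
#' delay law: the CDF `F(t)`, the integrated CDF
#' `Lambda(t) = integral_0^t F(s) ds`, and the generalized inverse of the
#' latter.  Four families are supported:
#'
#' * `two_point_delay(mean, sd)`: delay equal to `mean - sd` or `mean + sd`
#'   with probability 1/2 each.  The analytically tractable symmetric case;
#'   requires `sd <= mean` so the support is non-negative.
#' * `gamma_delay(mean, cv)`: gamma with the stated mean and coefficient of
#'   variation (shape `cv^-2`, scale `mean * cv^2`).
#' * `normal_delay(mean, sd)`: normal truncated to `[0, Inf)` and
#'   renormalized.  Both nominal and post-truncation moments are stored; a
#'   warning is recorded when `sd/mean > 0.3`, where the truncation bias is
#'   no longer negligible.
#' * `fixed_delay(mean)`: the degenerate (deterministic) delay.  All
#'   factories return this family when the dispersion parameter is zero, so
#'   deterministic limits need no special casing.
#'
#' @param mean Mean delay (time units, > 0).  For `normal_delay` this is the
#'   nominal (pre-truncation) location.
#' @param sd Standard deviation of the delay (time units, >= 0).
#' @param cv Coefficient of variation (sd/mean, >= 0).
#' @return An object of class `delay_dist` with fields `family`, `mean`,
#'   `sd` (nominal parameters), `mean_eff`, `sd_eff` (post-truncation moments,
#'   equal to the nominal ones except for the truncated normal) and, for the
#'   truncated normal, `truncation_warning` (TRUE when `sd/mean > 0.3`).
#' @examples
#' d <- two_point_delay(1, 0.5)
#' delay_cdf(d, c(0.4, 0.9, 2))
#' delay_icdf(d, 1.5)          # integrated CDF at t = 1.5
#' delay_icdf_inv(d, 0.25)     # its generalized inverse
#' sample_delay(gamma_delay(1, 0.5), 5, seed = 1)
#' @name delay_dist
NULL

new_delay_dist <- function(family, mean, sd, ...) {
  structure(
    c(list(family = family, mean = mean, sd = sd), list(...)),
    class = "delay_dist"
  )
}

check_positive_mean <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("`mean` must be a single positive number", call. = FALSE)
}

#' @rdname delay_dist
#' @export
two_point_delay <- function(mean, sd) {
  check_positive_mean(mean)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single non-negative number", call. = FALSE)
  if (sd > mean)
    stop("two-point delay requires sd <= mean (support must be non-negative)",
         call. = FALSE)
  if (sd == 0) return(fixed_delay(mean))
  new_delay_dist("two_point", mean, sd,
                 tau1 = mean - sd, tau2 = mean + sd,
                 mean_eff = mean, sd_eff = sd)
}

#' @rdname delay_dist
#' @export
gamma_delay <- function(mean, cv) {
  check_positive_mean(mean)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("`cv` must be a single non-negative number", call. = FALSE)
  if (cv == 0) return(fixed_delay(mean))
  shape <- cv^-2
  scale <- mean * cv^2
  new_delay_dist("gamma", mean, mean * cv,
                 shape = shape, scale = scale,
                 mean_eff = mean, sd_eff = mean * cv)
}

#' @rdname delay_dist
#' @export
normal_delay <- function(mean, sd) {
  check_positive_mean(mean)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single non-negative number", call. = FALSE)
  if (sd == 0) return(fixed_delay(mean))
  # moments of the normal truncated to [0, Inf)
  alpha <- -mean / sd
  lam <- dnorm(alpha) / (1 - pnorm(alpha))   # hazard at the truncation point
  mean_eff <- mean + sd * lam
  var_eff <- sd^2 * (1 + alpha * lam - lam^2)
  warn <- sd / mean > 0.3
  if (warn)
    warning("normal delay with sd/mean > 0.3: truncation at 0 shifts the ",
            "mean by ", signif(mean_eff - mean, 3),
            "; post-truncation moments are reported in the object",
            call. = FALSE)
  new_delay_dist("normal_truncated", mean, sd,
                 mean_eff = mean_eff, sd_eff = sqrt(var_eff),
                 truncation_warning = warn)
}

#' @rdname delay_dist
#' @export
fixed_delay <- function(mean) {
  check_positive_mean(mean)
  new_delay_dist("fixed", mean, 0, mean_eff = mean, sd_eff = 0)
}

#' @export
print.delay_dist <- function(x, ...) {
  cat("<delay_dist> family:", x$family,
      " mean:", format(x$mean), " sd:", format(x$sd), "\n")
  if (identical(x$family, "normal_truncated")) {
    cat("  post-truncation mean:", format(x$mean_eff),
        " sd:", format(x$sd_eff),
        if (isTRUE(x$truncation_warning)) " [truncation bias non-negligible]",
        "\n", sep = "")
  }
  invisible(x)
}

#' Effective (post-truncation) moments of a delay distribution
#'
#' For the truncated normal these differ from the nominal parameters; for
#' every other family they coincide with them.
#'
#' @param dist A [delay_dist] object.
#' @return A single number.
#' @export
delay_mean <- function(dist) {
  stopifnot(inherits(dist, "delay_dist"))
  dist$mean_eff
}

#' @rdname delay_mean
#' @export
delay_sd <- function(dist) {
  stopifnot(inherits(dist, "delay_dist"))
  dist$sd_eff
}

#' Atoms (jump points) of the delay CDF
#'
#' Locations where F jumps; analytic signaling-time PDFs inherit these jumps,
#' so evaluation grids should include them as breakpoints.
#'
#' @param dist A [delay_dist] object.
#' @return Numeric vector (possibly empty) of jump locations.
#' @export
delay_atoms <- function(dist) {
  stopifnot(inherits(dist, "delay_dist"))
  switch(dist$family,
         two_point = c(dist$tau1, dist$tau2),
         fixed = dist$mean,
         numeric(0))
}

#' CDF of the delay
#'
#' `F(t) = P(tau <= t)`, right-continuous, zero for `t < 0`.
#'
#' @param dist A [delay_dist] object.
#' @param t Numeric vector of times.
#' @return `F(t)`, same length as `t`.
#' @export
delay_cdf <- function(dist, t) {
  stopifnot(inherits(dist, "delay_dist"))
  switch(dist$family,
    two_point = 0.5 * (t >= dist$tau1) + 0.5 * (t >= dist$tau2),
    gamma = pgamma(pmax(t, 0), shape = dist$shape, scale = dist$scale),
    fixed = as.numeric(t >= dist$mean),
    normal_truncated = {
      m <- dist$mean; s <- dist$sd
      p0 <- pnorm(0, m, s)
      out <- (pnorm(pmax(t, 0), m, s) - p0) / (1 - p0)
      ifelse(t < 0, 0, out)
    },
    stop("unknown delay family: ", dist$family)
  )
}

#' Probability density of the delay (continuous families only)
#'
#' @param dist A [delay_dist] object with a continuous law (`gamma` or
#'   `normal_truncated`).
#' @param t Numeric vector of times.
#' @return Density values.
#' @export
delay_pdf <- function(dist, t) {
  stopifnot(inherits(dist, "delay_dist"))
  switch(dist$family,
    gamma = dgamma(pmax(t, 0), shape = dist$shape, scale = dist$scale) *
      (t >= 0),
    normal_truncated = {
      p0 <- pnorm(0, dist$mean, dist$sd)
      dnorm(t, dist$mean, dist$sd) / (1 - p0) * (t >= 0)
    },
    stop("delay_pdf is defined only for continuous delay families, not ",
         dist$family)
  )
}

#' Integrated CDF of the delay
#'
#' `Lambda(t) = integral_0^t F(s) ds`: non-decreasing, convex, and
#' asymptotically `t - mean` (post-truncation mean).  `rate * Lambda(t)` is
#' the mean of the departure (completed-protein) process of the M/G/infinity
#' queue, and the time rescaling `t -> Lambda(t)` turns that process into a
#' homogeneous Poisson process.  Closed forms are used for every family:
#' piecewise linear for the two-point and fixed delays, gamma-CDF identities
#' for the gamma, and normal-CDF/PDF identities for the truncated normal.
#'
#' @param dist A [delay_dist] object.
#' @param t Numeric vector of times, all `>= 0`.
#' @return `Lambda(t)`, same length as `t`.
#' @export
delay_icdf <- function(dist, t) {
  stopifnot(inherits(dist, "delay_dist"))
  if (any(t < 0)) stop("integrated CDF is defined for t >= 0", call. = FALSE)
  switch(dist$family,
    two_point = {
      tau1 <- dist$tau1; tau2 <- dist$tau2
      ifelse(t < tau1, 0,
             ifelse(t < tau2, (t - tau1) / 2, t - dist$mean))
    },
    fixed = pmax(0, t - dist$mean),
    gamma = {
      # int_0^t F = t F_a(t) - mu F_{a+1}(t), a = shape
      t * pgamma(t, shape = dist$shape, scale = dist$scale) -
        dist$mean * pgamma(t, shape = dist$shape + 1, scale = dist$scale)
    },
    normal_truncated = {
      m <- dist$mean; s <- dist$sd
      p0 <- pnorm(0, m, s)
      G <- function(u) {
        z <- (u - m) / s
        (u - m) * pnorm(z) + s * dnorm(z)
      }
      (G(t) - G(0) - t * p0) / (1 - p0)
    },
    stop("unknown delay family: ", dist$family)
  )
}

#' Generalized inverse of the integrated CDF
#'
#' `delay_icdf_inv(dist, s) = inf(t : Lambda(t) >= s)` for `s > 0` (the
#' infimum convention matches first-passage semantics of the K-th departure);
#' at `s = 0` the continuity limit from above is returned.  Closed form for
#' the two-point and fixed families, bracketed root finding (absolute
#' tolerance `1e-10 * mean`) otherwise.
#'
#' @param dist A [delay_dist] object.
#' @param s Numeric vector of rescaled times, all `>= 0`.
#' @return Times `t` with `Lambda(t) = s`, same length as `s`.
#' @export
delay_icdf_inv <- function(dist, s) {
  stopifnot(inherits(dist, "delay_dist"))
  if (any(s < 0)) stop("inverse integrated CDF is defined for s >= 0",
                       call. = FALSE)
  switch(dist$family,
    two_point = {
      sig <- dist$sd
      ifelse(s < sig, dist$tau1 + 2 * s, s + dist$mean)
    },
    fixed = s + dist$mean,
    {
      mu_eff <- dist$mean_eff
      tol <- 1e-10 * dist$mean
      vapply(s, function(si) {
        if (si == 0) return(0)
        hi <- si + mu_eff + 1
        uniroot(function(t) delay_icdf(dist, t) - si,
                lower = 0, upper = hi, tol = tol)$root
      }, numeric(1))
    }
  )
}

#' Draw random delays
#'
#' @param dist A [delay_dist] object.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; when supplied the draws are
#'   reproducible, when `NULL` the current RNG stream is used (as inside the
#'   stochastic simulator).
#' @return Numeric vector of `n` non-negative delays.
#' @export
sample_delay <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "delay_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(dist$family,
    two_point = dist$mean + dist$sd * (2 * rbinom(n, 1L, 0.5) - 1),
    gamma = rgamma(n, shape = dist$shape, scale = dist$scale),
    fixed = rep(dist$mean, n),
    normal_truncated = {
      # inverse-CDF sampling restricted to the surviving upper tail
      p0 <- pnorm(0, dist$mean, dist$sd)
      qnorm(p0 + runif(n) * (1 - p0), dist$mean, dist$sd)
    },
    stop("unknown delay family: ", dist$family)
  )
}

#' Build a delay distribution from a config-style specification
#'
#' Accepts the distribution block used in experiment configs: a list with
#' `family` plus `mean` and either `sd` or `cv`.
#'
#' @param block A named list, e.g. `list(family = "gamma", mean = 1, cv = 0.5)`.
#' @return A [delay_dist] object.
#' @export
delay_from_config <- function(block) {
  if (is.null(block$family)) stop("delay block needs a `family` field",
                                  call. = FALSE)
  mean <- block$mean
  sd <- block$sd
  if (is.null(sd) && !is.null(block$cv)) sd <- block$cv * mean
  switch(block$family,
    two_point = two_point_delay(mean, sd),
    gamma = gamma_delay(mean, sd / mean),
    normal = ,
    normal_truncated = normal_delay(mean, sd),
    fixed = fixed_delay(mean),
    stop("unknown delay family in config: ", block$family, call. = FALSE)
  )
}
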