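#' Step-switch (sharp Hill) transcription rate
#'
#' The steep-Hill approximation of a regulated promoter: an activated gene
#' transcribes at the maximal rate `beta` once `threshold` copies of the
#' regulator have been fully formed (`x >= K`), a repressed gene transcribes
#' only while `x < K`.  The K-th completed protein flips the switch.
#'
#' @param x Regulator count (completed proteins).
#' @param threshold Switch threshold K >= 1.
#' @param beta Maximal initiation rate (> 0).
#' @param mode `"activation"` or `"repression"`.
#' @return Initiation rate, vectorized over `x`.
#' @export
step_hill_rate <- function(x, threshold, beta,
                           mode = c("activation", "repression")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 1, beta > 0)
  if (mode == "activation") beta * (x >= threshold) else beta * (x < threshold)
}

#' Signaling time of an activator cascade
#'
#' In a linear chain of activating genes each stage is an independent queue:
#' stage i starts when stage i-1 crosses its threshold, so the total
#' signaling time is the independent sum of the per-stage first-passage
#' times.  Means and variances add; the density of the total is obtained by
#' numerical convolution of the stage densities on a common grid.
#'
#' @param stages A list of [queue_spec] objects (>= 1), in pathway order.
#' @param grid_n Grid resolution used for the convolved density.
#' @return A list of class `signaling_summary` with `mean`, `variance`,
#'   `sd`, `cv`, `pdf` (interpolated convolution), `grid` and `stages`.
#' @export
cascade_time <- function(stages, grid_n = 2048L) {
  stopifnot(is.list(stages), length(stages) >= 1,
            all(vapply(stages, inherits, TRUE, "queue_spec")))
  summaries <- lapply(stages, signaling_time_moments)
  m <- sum(vapply(summaries, `[[`, 0, "mean"))
  v <- sum(vapply(summaries, `[[`, 0, "variance"))

  # common grid wide enough for the sum, fine enough for every stage's jumps
  upper <- m + 8 * sqrt(v) + sum(vapply(stages, function(s)
    2 * delay_sd(s$delay), 0))
  dt <- upper / grid_n
  tt <- seq(0, upper, by = dt)
  dens <- NULL
  for (s in stages) {
    f <- signaling_time_pdf(s, tt)
    f <- f / (sum(f) * dt)
    dens <- if (is.null(dens)) f else {
      g <- convolve(dens, rev(f), type = "open")[seq_along(tt)] * dt
      g / (sum(g) * dt)
    }
  }
  pdf_fun <- approxfun(tt, dens, yleft = 0, yright = 0)
  structure(list(mean = m, variance = v, sd = sqrt(v), cv = sqrt(v) / m,
                 pdf = pdf_fun, grid = tt, stages = stages),
            class = "signaling_summary")
}

#' Expected completed proteins under a repressor switch
#'
#' The upstream gene initiates at rate lambda only during `[0, t_off]`; after
#' shutoff, proteins already in the maturation queue still emerge.  For a
#' fixed shutoff time `T`, `E[D(t)] = lambda (Lambda(t) - Lambda(max(0, t - T)))`;
#' for a random shutoff the expectation is integrated against its density.
#'
#' @param rate Initiation rate lambda.
#' @param delay A [delay_dist].
#' @param t_off Shutoff time: a single number (possibly `Inf`), or a list
#'   `list(density = f, lower = , upper = )` describing its distribution.
#' @param t Observation time(s), `>= 0`.
#' @return Expected completed-protein count at `t`.
#' @export
repressor_exit_mean <- function(rate, delay, t_off, t) {
  stopifnot(inherits(delay, "delay_dist"), all(t >= 0))
  fixed_T <- function(T, t) {
    if (is.infinite(T)) return(rate * delay_icdf(delay, t))
    rate * (delay_icdf(delay, t) - delay_icdf(delay, pmax(0, t - T)))
  }
  if (is.numeric(t_off) && length(t_off) == 1L) return(fixed_T(t_off, t))
  if (is.list(t_off) && is.function(t_off$density)) {
    vapply(t, function(ti) {
      integrate(function(T) {
        vapply(T, function(Ti) fixed_T(Ti, ti), 0) * t_off$density(T)
      }, t_off$lower, t_off$upper, rel.tol = 1e-8)$value
    }, numeric(1))
  } else stop("`t_off` must be a number or list(density, lower, upper)",
              call. = FALSE)
}

#' Sign of the variability response of a windowed queue
#'
#' With initiation active only on a window of length `T` ending before the
#' observation time `t`, `E[D(t)] = lambda * integral_{t-T}^{t} F(s) ds`.
#' For a delay law symmetric about its mean, this window integral increases
#' with the delay sd when the window midpoint `t - T/2` lies below the mean
#' delay, decreases when above, and is flat when the midpoint equals the
#' mean.  The function evaluates `E[D(t)]` on a sigma grid and classifies the
#' observed monotonicity.
#'
#' @param rate Initiation rate lambda.
#' @param family `"two_point"` or `"normal"` (symmetric families).
#' @param mean,T,t Mean delay, window length, observation time (`t > T`).
#' @param sigma_grid Grid of delay standard deviations.
#' @param tol Derivative magnitudes below `tol` count as flat.
#' @return A list with `classification` (`"increasing"`, `"decreasing"` or
#'   `"flat"`), `midpoint`, `values` (E[D(t)] per sigma) and `sigma_grid`.
#' @export
windowed_sigma_response <- function(rate, family = c("two_point", "normal"),
                                    mean, T, t,
                                    sigma_grid = seq(0.05, 0.3, length.out = 6) * mean,
                                    tol = 1e-8) {
  family <- match.arg(family)
  stopifnot(t > T, T > 0)
  make <- switch(family, two_point = two_point_delay, normal = normal_delay)
  vals <- vapply(sigma_grid, function(sig) {
    d <- suppressWarnings(make(mean, sig))
    rate * (delay_icdf(d, t) - delay_icdf(d, t - T))
  }, numeric(1))
  dv <- diff(vals)
  classification <- if (all(abs(dv) <= tol)) "flat"
  else if (all(dv >= -tol)) "increasing"
  else if (all(dv <= tol)) "decreasing"
  else "non-monotone"
  list(classification = classification, midpoint = t - T / 2,
       values = vals, sigma_grid = sigma_grid)
}

#' Signaling time conditioned on the number of initiation events
#'
#' If the upstream gene shuts off after exactly `N` transcription initiation
#' events, the signaling time to the K-th completed protein behaves
#' qualitatively differently from the unconditioned queue: with few
#' initiations (`N` close to `K`) increasing delay variability *slows*
#' signaling, with many it accelerates it, with a balance point in between.
#' Monte Carlo: the first `N` arrival times of a rate-lambda Poisson process
#' receive i.i.d. delays; the K-th smallest completion is recorded.
#'
#' @param rate Initiation rate lambda.
#' @param delay A [delay_dist].
#' @param K Threshold (K <= N).
#' @param N Number of initiation events before shutoff.
#' @param n_rep Monte Carlo replicates.
#' @param seed Integer seed.
#' @return A list with `mean`, `se` (standard error of the mean), `cv`,
#'   `cv_se`, `n_rep`.
#' @export
conditional_signaling_given_N <- function(rate, delay, K, N, n_rep, seed) {
  stopifnot(inherits(delay, "delay_dist"), K >= 1)
  if (N < K)
    stop("infeasible threshold: need N >= K initiations", call. = FALSE)
  set.seed(seed)
  A <- matrix(rexp(n_rep * N, rate), n_rep, N)
  if (N > 1) for (j in 2:N) A[, j] <- A[, j - 1L] + A[, j]
  comp <- A + matrix(sample_delay(delay, n_rep * N), n_rep, N)
  tk <- if (K == N && N == 1L) comp[, 1L]
  else apply(comp, 1L, function(x) sort.int(x, partial = K)[K])
  m <- mean(tk); s <- sd(tk)
  cv <- s / m
  # delta-method standard error for the CV
  cv_se <- cv * sqrt(1 / (2 * (n_rep - 1)) + s^2 / (n_rep * m^2))
  list(mean = m, se = s / sqrt(n_rep), cv = cv, cv_se = cv_se, n_rep = n_rep)
}

#' Scan the conditional signaling time across N and sigma
#'
#' For each `N` the conditional mean `E[T_K | N]` is estimated independently
#' at every sigma in the grid and a weighted least-squares slope in sigma is
#' formed; `N` is classified as increasing / flat / decreasing according to
#' whether the slope differs from zero by more than `z_flat` standard errors.
#' The entry/exit balance argument predicts the flat point at `N = 2K - 1`.
#'
#' @param rate Initiation rate lambda.
#' @param family `"two_point"` or `"normal"`.
#' @param mean Mean delay.
#' @param K Threshold.
#' @param N_grid Integer vector of initiation counts (all >= K).
#' @param sigma_grid Delay standard deviations.
#' @param n_rep Replicates per (N, sigma) cell.
#' @param seed Base seed; each cell uses `seed + counter`.
#' @param z_flat Flatness band in slope standard errors.
#' @return A data frame with one row per `N`: slope, its standard error and
#'   the classification, plus attribute `predicted_flat_N = 2K - 1`.
#' @export
trichotomy_scan <- function(rate, family = c("two_point", "normal"), mean, K,
                            N_grid, sigma_grid, n_rep, seed, z_flat = 2) {
  family <- match.arg(family)
  stopifnot(all(N_grid >= K))
  make <- switch(family, two_point = two_point_delay, normal = normal_delay)
  counter <- 0L
  rows <- lapply(N_grid, function(N) {
    means <- ses <- numeric(length(sigma_grid))
    for (i in seq_along(sigma_grid)) {
      counter <<- counter + 1L
      d <- suppressWarnings(make(mean, sigma_grid[i]))
      est <- conditional_signaling_given_N(rate, d, K, N, n_rep,
                                           seed = seed + counter)
      means[i] <- est$mean; ses[i] <- est$se
    }
    xc <- sigma_grid - base::mean(sigma_grid)
    w <- xc / sum(xc^2)                 # least-squares slope contrast
    slope <- sum(w * means)
    slope_se <- sqrt(sum(w^2 * ses^2))
    cls <- if (slope > z_flat * slope_se) "increasing"
    else if (slope < -z_flat * slope_se) "decreasing"
    else "flat"
    data.frame(N = N, slope = slope, slope_se = slope_se,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "predicted_flat_N") <- as.integer(2 * K - 1)
  out
}

#' Feedforward loop specification
#'
#' Type-1 FFLs: gene 1 activates genes 2 and 3; gene 2 activates gene 3
#' (coherent, AND-gate promoter) or represses it (incoherent, active while
#' `X1 >= K13` and `X2 < K23`).  Edge ij carries a threshold `Kij`; the
#' producing gene of each protein has its own initiation rate and delay law.
#'
#' @param topology `"coherent_AND"` or `"incoherent"`.
#' @param K12,K13,K23 Edge thresholds (>= 1).
#' @param lambda1,lambda2,beta3 Initiation rates of genes 1, 2, 3.
#' @param delay1,delay2,delay3 [delay_dist] objects for proteins 1, 2, 3.
#' @param degradation Optional named vector of first-order degradation rates
#'   `c(X1 = , X2 = , X3 = )` (defaults to none).
#' @return An object of class `ffl_spec`.
#' @export
ffl_spec <- function(topology = c("coherent_AND", "incoherent"),
                     K12, K13, K23, lambda1, lambda2, beta3,
                     delay1, delay2, delay3 = delay2,
                     degradation = c(X1 = 0, X2 = 0, X3 = 0)) {
  topology <- match.arg(topology)
  stopifnot(K12 >= 1, K13 >= 1, K23 >= 1, lambda1 > 0, lambda2 > 0, beta3 > 0,
            inherits(delay1, "delay_dist"), inherits(delay2, "delay_dist"),
            inherits(delay3, "delay_dist"))
  deg <- c(X1 = 0, X2 = 0, X3 = 0)
  deg[names(degradation)] <- degradation
  structure(list(topology = topology, K12 = K12, K13 = K13, K23 = K23,
                 lambda1 = lambda1, lambda2 = lambda2, beta3 = beta3,
                 delay1 = delay1, delay2 = delay2, delay3 = delay3,
                 degradation = deg),
            class = "ffl_spec")
}

# three-gene FFL as a delayed reaction network
ffl_network <- function(spec) {
  incoherent <- spec$topology == "incoherent"
  g3_prop <- if (incoherent) {
    function(state, t) spec$beta3 *
      (state[["X1"]] >= spec$K13) * (state[["X2"]] < spec$K23)
  } else {
    function(state, t) spec$beta3 *
      (state[["X1"]] >= spec$K13) * (state[["X2"]] >= spec$K23)
  }
  rxns <- list(
    reaction("gene1", function(state, t) spec$lambda1,
             delayed_change = c(X1 = 1), delay = spec$delay1),
    reaction("gene2", function(state, t)
      spec$lambda2 * (state[["X1"]] >= spec$K12),
      delayed_change = c(X2 = 1), delay = spec$delay2),
    reaction("gene3", g3_prop,
             delayed_change = c(X3 = 1), delay = spec$delay3)
  )
  deg <- spec$degradation
  for (spn in names(deg)) {
    if (deg[[spn]] > 0) {
      local({
        nm <- spn; rate <- deg[[spn]]
        rxns[[length(rxns) + 1L]] <<- reaction(
          paste0("deg_", nm),
          function(state, t) rate * state[[nm]],
          change = setNames(-1, nm))
      })
    }
  }
  reaction_network(species = c(X1 = 0L, X2 = 0L, X3 = 0L), reactions = rxns)
}

# per-edge queue specs of an FFL
ffl_queues <- function(spec) {
  list(T12 = queue_spec(spec$lambda1, spec$delay1, spec$K12),
       T13 = queue_spec(spec$lambda1, spec$delay1, spec$K13),
       T23 = queue_spec(spec$lambda2, spec$delay2, spec$K23))
}

#' Turn-on time of the coherent (AND-gate) feedforward loop
#'
#' Gene 3 starts transcribing when both `X1 >= K13` and `X2 >= K23`.  In
#' simulation mode the full three-gene delayed-SSA is run and the two
#' branch-crossing times share the same X1 trajectory (the reference).  In
#' analytic mode the turn-on is approximated by `max(T13, T12 + T23)` with
#' the three first-passage times drawn independently from their analytic
#' laws; the dependence between T13 and T12 through the shared X1 path is
#' thereby ignored, and comparing the two modes quantifies that gap.
#'
#' @param spec An [ffl_spec()] with coherent topology.
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @param mode `"analytic"` or `"simulation"`.
#' @param t_max Simulation horizon per replicate.
#' @return A list with `samples`, `mean`, `se`, `mode`.
#' @export
coherent_ffl_on_time <- function(spec, n_rep, seed,
                                 mode = c("analytic", "simulation"),
                                 t_max = NULL) {
  stopifnot(inherits(spec, "ffl_spec"))
  if (spec$topology != "coherent_AND")
    stop("coherent_ffl_on_time needs topology = 'coherent_AND'", call. = FALSE)
  mode <- match.arg(mode)
  qs <- ffl_queues(spec)
  if (mode == "analytic") {
    set.seed(seed)
    t13 <- rsignaling(qs$T13, n_rep)
    t12 <- rsignaling(qs$T12, n_rep)
    t23 <- rsignaling(qs$T23, n_rep)
    samples <- pmax(t13, t12 + t23)
  } else {
    if (is.null(t_max)) {
      m <- vapply(qs, function(q) signaling_time_moments(q)$mean, 0)
      t_max <- (m[["T12"]] + m[["T23"]] + m[["T13"]]) * 3 + 10
    }
    net <- ffl_network(spec)
    samples <- vapply(seq_len(n_rep), function(i) {
      traj <- simulate_network(net, t_end = t_max, seed = seed + i)
      on1 <- first_crossing(traj, "X1", spec$K13)
      on2 <- first_crossing(traj, "X2", spec$K23)
      max(on1, on2)
    }, numeric(1))
  }
  list(samples = samples, mean = mean(samples),
       se = sd(samples) / sqrt(n_rep), mode = mode)
}

#' Pulse duration of the incoherent feedforward loop
#'
#' Gene 3 transcribes while `X1 >= K13` and `X2 < K23`: a pulse that opens
#' when X1 crosses the low threshold of gene 3 and closes when X2 (whose
#' gene starts once X1 crosses K12) reaches K23.  Analytically the expected
#' duration is the linear combination
#' `E[dT] = E[T12] + E[T23] - E[T13]` of three single-gene signaling-time
#' curves, so its response to delay variability can take either sign
#' depending on the thresholds.  Simulation mode measures the signed gap
#' between the two crossing times in the full delayed SSA (`pulse`), plus
#' the non-negative duration the gene-3 propensity was actually positive
#' (`active`, which differs from `pulse` when the pulse is empty or when
#' degradation causes re-crossings).
#'
#' @param spec An [ffl_spec()] with incoherent topology.
#' @param sigma_grid Delay standard deviations applied to all three delay
#'   laws (family and means preserved).
#' @param mode `"analytic"`, `"simulation"` or `"both"`.
#' @param n_rep Simulation replicates per sigma.
#' @param seed Integer seed.
#' @return A data frame with one row per sigma and mode: columns `sigma`,
#'   `mode`, `pulse` (expected signed duration), `se`, `active`,
#'   `empty_fraction` (simulation only).
#' @export
incoherent_ffl_pulse <- function(spec, sigma_grid,
                                 mode = c("analytic", "simulation", "both"),
                                 n_rep = 2000L, seed = 1L) {
  stopifnot(inherits(spec, "ffl_spec"))
  if (spec$topology != "incoherent")
    stop("incoherent_ffl_pulse needs topology = 'incoherent'", call. = FALSE)
  mode <- match.arg(mode)

  reparam <- function(d, sig) {
    switch(d$family,
           two_point = two_point_delay(d$mean, sig),
           gamma = gamma_delay(d$mean, sig / d$mean),
           normal_truncated = suppressWarnings(normal_delay(d$mean, sig)),
           fixed = if (sig == 0) d else
             stop("cannot vary sd of a fixed delay; pick a family"),
           stop("unknown family"))
  }

  rows <- list()
  counter <- 0L
  for (sig in sigma_grid) {
    sp <- spec
    sp$delay1 <- reparam(spec$delay1, sig)
    sp$delay2 <- reparam(spec$delay2, sig)
    sp$delay3 <- reparam(spec$delay3, sig)
    qs <- ffl_queues(sp)
    if (mode %in% c("analytic", "both")) {
      m <- vapply(qs, function(q) signaling_time_moments(q)$mean, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sig, mode = "analytic",
        pulse = m[["T12"]] + m[["T23"]] - m[["T13"]],
        se = 0, active = NA_real_, empty_fraction = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (mode %in% c("simulation", "both")) {
      net <- ffl_network(sp)
      sm <- lapply(qs, signaling_time_moments)
      # horizon: the off-crossing T12 + T23 plus a wide safety margin
      t_max <- sm$T12$mean + sm$T23$mean + max(sm$T13$mean, 0) +
        10 * sqrt(sm$T12$variance + sm$T23$variance) + 2
      res <- vapply(seq_len(n_rep), function(i) {
        counter <<- counter + 1L
        traj <- simulate_network(net, t_end = t_max, seed = seed + counter)
        on3 <- first_crossing(traj, "X1", sp$K13)
        off3 <- first_crossing(traj, "X2", sp$K23)
        c(off3 - on3, max(0, off3 - on3))
      }, numeric(2))
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sig, mode = "simulation",
        pulse = mean(res[1L, ]), se = sd(res[1L, ]) / sqrt(n_rep),
        active = mean(res[2L, ]), empty_fraction = mean(res[1L, ] <= 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-gene activator cascade as a reaction network
#'
#' Gene 1 initiates at a constant rate from time 0; gene 2 initiates at its
#' maximal rate once `K1` copies of protein 1 are complete.  Used as the
#' simulation ground truth for [cascade_time()].
#'
#' @param stage1,stage2 [queue_spec] objects for the two stages (`stage1$rate`
#'   is gene 1's rate and `stage1$threshold` the threshold on X1 that starts
#'   gene 2; `stage2` likewise governs X2 and the final threshold).
#' @return A [reaction_network()].
#' @export
two_gene_cascade_network <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "queue_spec"), inherits(stage2, "queue_spec"))
  reaction_network(
    species = c(X1 = 0L, X2 = 0L),
    reactions = list(
      reaction("gene1", function(state, t) stage1$rate,
               delayed_change = c(X1 = 1), delay = stage1$delay),
      reaction("gene2", function(state, t)
        stage2$rate * (state[["X1"]] >= stage1$threshold),
        delayed_change = c(X2 = 1), delay = stage2$delay)
    ))
}
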