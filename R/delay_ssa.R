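#' Reactions and reaction networks with delayed products
#'
#' A reaction has a propensity function of the current state (and time), a
#' stoichiometric change applied immediately when the reaction fires, and
#' optionally a *delayed* change applied after a random delay drawn from a
#' [delay_dist].  Delayed protein production is written as an immediate
#' no-op (or reactant consumption) plus a delayed `+1` on the product: the
#' maturing molecules form the queue of an M/G/infinity server and do not
#' influence propensities unless the model references a species that counts
#' them.
#'
#' Propensities must be constant between events (piecewise-constant in
#' state); every rate change in the supported models happens at an event, so
#' event-driven re-evaluation keeps the algorithm exact.
#'
#' @param name Reaction name (used in event logs).
#' @param propensity Function `(state, t) -> rate`, where `state` is the
#'   named count vector.
#' @param change Named numeric vector of immediate stoichiometric changes
#'   (may be empty).
#' @param delayed_change Optional named numeric vector applied at completion.
#' @param delay A [delay_dist]; required when `delayed_change` is given.  One
#'   delay is drawn per firing, at initiation time.
#' @return An object of class `delayq_reaction`.
#' @examples
#' rxn <- reaction("production", function(state, t) 10,
#'                 change = c(), delayed_change = c(X = 1),
#'                 delay = gamma_delay(1, 0.5))
#' net <- reaction_network(species = c(X = 0), reactions = list(rxn))
#' traj <- simulate_network(net, t_end = 2, seed = 1)
#' state_at(traj, 2, "X")
#' @export
reaction <- function(name, propensity, change = c(), delayed_change = NULL,
                     delay = NULL) {
  stopifnot(is.function(propensity))
  if (!is.null(delayed_change) && !inherits(delay, "delay_dist"))
    stop("a reaction with a delayed change needs a `delay` distribution",
         call. = FALSE)
  if (is.null(delayed_change) && !is.null(delay))
    stop("`delay` given without a `delayed_change`", call. = FALSE)
  structure(list(name = name, propensity = propensity,
                 change = change, delayed_change = delayed_change,
                 delay = delay),
            class = "delayq_reaction")
}

#' @param species Named integer vector of initial copy numbers.
#' @param reactions List of [reaction()] objects.
#' @rdname reaction
#' @export
reaction_network <- function(species, reactions) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("`species` must be a named vector of initial counts", call. = FALSE)
  if (any(species < 0) || any(species != round(species)))
    stop("initial counts must be non-negative integers", call. = FALSE)
  stopifnot(length(reactions) >= 1,
            all(vapply(reactions, inherits, TRUE, "delayq_reaction")))
  sp <- names(species)
  expand <- function(ch) {
    v <- setNames(numeric(length(sp)), sp)
    if (length(ch)) {
      if (is.null(names(ch)) || !all(names(ch) %in% sp))
        stop("stoichiometric changes must be named after declared species",
             call. = FALSE)
      v[names(ch)] <- ch
    }
    v
  }
  reactions <- lapply(reactions, function(r) {
    r$change_full <- expand(r$change)
    r$delayed_full <- if (!is.null(r$delayed_change)) expand(r$delayed_change)
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' Static validation of a reaction network
#'
#' Checks species declarations, initial counts, the validity of every delay
#' distribution, and the sign of every propensity on the initial state and a
#' set of randomly perturbed non-negative states.  Runtime negativity is
#' additionally guarded inside [simulate_network()].
#'
#' @param network A [reaction_network()].
#' @param n_probe Number of random probe states for the propensity check.
#' @param seed Seed for the probe states.
#' @return A list with `ok` (logical) and `messages` (character vector of
#'   failures, empty when `ok`).
#' @export
validate_network <- function(network, n_probe = 50L, seed = 1L) {
  stopifnot(inherits(network, "reaction_network"))
  msgs <- character(0)
  sp <- network$species
  set.seed(seed)
  probes <- c(list(sp), lapply(seq_len(n_probe), function(i) {
    setNames(rpois(length(sp), lambda = pmax(sp, 5)), names(sp))
  }))
  for (ri in seq_along(network$reactions)) {
    r <- network$reactions[[ri]]
    for (st in probes) {
      a <- r$propensity(st, 0)
      if (!is.finite(a) || a < 0) {
        msgs <- c(msgs, sprintf(
          "reaction '%s': propensity %s at state (%s)", r$name,
          format(a), paste(st, collapse = ",")))
        break
      }
    }
    # a reaction that consumes a species must be switched off when absent
    consumed <- names(which(r$change_full < 0))
    if (length(consumed)) {
      zero <- sp * 0L
      if (r$propensity(zero, 0) > 0)
        msgs <- c(msgs, sprintf(
          "reaction '%s' consumes (%s) but has positive propensity at the zero state",
          r$name, paste(consumed, collapse = ",")))
    }
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

#' Exact stochastic simulation with delayed reactions
#'
#' Implements the delayed extension of the direct stochastic simulation
#' algorithm.  At each step a putative next Markovian firing time is drawn
#' from the total propensity; if the earliest pending delayed completion
#' precedes it, the system advances to that completion, applies the stored
#' change, and re-draws (exact by memorylessness of the exponential).  When a
#' delayed reaction fires, its immediate change is applied at once and its
#' delayed change is stored together with the completion time `now + tau`,
#' with `tau` drawn from the reaction's delay distribution at initiation
#' time.  Pending events are kept ordered by completion time, ties broken by
#' insertion order; completions scheduled at exactly a putative firing time
#' are applied first.
#'
#' @param network A validated [reaction_network()].
#' @param t_end End of the simulated interval (> 0).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param max_events Event budget; exceeding it raises a resource error.
#' @return An object of class `delayq_trajectory`: a list with `time` and
#'   `state` (event-ordered, one row per applied event, including the
#'   initial state at time 0 and the final state at `t_end`), `events`
#'   (data frame with per-event `time`, `reaction`, `type` = "init" or
#'   "completion", and for initiations of delayed reactions the scheduled
#'   `completion` time), `species`, `seed` and `t_end`.
#' @export
simulate_network <- function(network, t_end, seed, max_events = 5e6) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  set.seed(seed)
  rxns <- network$reactions
  nr <- length(rxns)
  state <- as.numeric(network$species)
  names(state) <- names(network$species)

  cap <- 4096L
  times <- numeric(cap); states <- matrix(0, cap, length(state))
  ev_time <- numeric(cap); ev_rxn <- integer(cap); ev_type <- integer(cap)
  ev_completion <- numeric(cap)
  n_rec <- 0L; n_ev <- 0L
  grow <- function() {
    cap2 <- cap * 2L
    times[cap2] <<- 0; states <- rbind(states, matrix(0, cap, ncol(states)))
    states <<- states
    ev_time[cap2] <<- 0; ev_rxn[cap2] <<- 0L; ev_type[cap2] <<- 0L
    ev_completion[cap2] <<- 0
    cap <<- cap2
  }
  record <- function(t) {
    n_rec <<- n_rec + 1L
    if (n_rec > cap) grow()
    times[n_rec] <<- t
    states[n_rec, ] <<- state
  }
  log_event <- function(t, rxn, type, completion) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) grow()
    ev_time[n_ev] <<- t; ev_rxn[n_ev] <<- rxn; ev_type[n_ev] <<- type
    ev_completion[n_ev] <<- completion
  }

  # pending completions, sorted by time (ties keep insertion order)
  pend_t <- numeric(0); pend_r <- integer(0)
  t <- 0
  record(0)
  steps <- 0L

  apply_change <- function(ch, t, rxn) {
    state <<- state + ch
    if (any(state < -1e-9)) {
      stop("reaction '", rxns[[rxn]]$name, "' drove a count negative at t = ",
           format(t), "; state: ", paste(names(state), state, collapse = ", "),
           call. = FALSE)
    }
  }

  repeat {
    steps <- steps + 1L
    if (steps > max_events)
      stop("event budget (", max_events, ") exhausted at t = ", format(t),
           call. = FALSE)
    a <- vapply(rxns, function(r) r$propensity(state, t), numeric(1))
    if (any(a < 0))
      stop("negative propensity at t = ", format(t), "; state: ",
           paste(names(state), state, collapse = ", "), call. = FALSE)
    a0 <- sum(a)
    t_next <- if (a0 > 0) t + rexp(1L, a0) else Inf

    if (length(pend_t) && pend_t[1L] <= t_next) {
      # earliest pending completion wins (ties: completion first)
      t <- pend_t[1L]
      if (t > t_end) break
      rxn <- pend_r[1L]
      pend_t <- pend_t[-1L]; pend_r <- pend_r[-1L]
      apply_change(rxns[[rxn]]$delayed_full, t, rxn)
      record(t); log_event(t, rxn, 2L, NA_real_)
    } else {
      if (t_next > t_end) break
      t <- t_next
      j <- findInterval(runif(1L) * a0, cumsum(a)) + 1L
      r <- rxns[[j]]
      completion <- NA_real_
      if (!is.null(r$delayed_full)) {
        completion <- t + sample_delay(r$delay, 1L)
        pos <- findInterval(completion, pend_t)
        pend_t <- append(pend_t, completion, after = pos)
        pend_r <- append(pend_r, j, after = pos)
      }
      apply_change(r$change_full, t, j)
      record(t); log_event(t, j, 1L, completion)
    }
  }
  record(t_end)

  events <- data.frame(
    time = ev_time[seq_len(n_ev)],
    reaction = vapply(rxns, `[[`, "", "name")[ev_rxn[seq_len(n_ev)]],
    type = c("init", "completion")[ev_type[seq_len(n_ev)]],
    completion = ev_completion[seq_len(n_ev)],
    stringsAsFactors = FALSE
  )
  st <- states[seq_len(n_rec), , drop = FALSE]
  colnames(st) <- names(state)
  structure(list(time = times[seq_len(n_rec)], state = st, events = events,
                 species = names(state), seed = seed, t_end = t_end),
            class = "delayq_trajectory")
}

#' @export
print.delayq_trajectory <- function(x, ...) {
  cat("<delayq_trajectory> species:", paste(x$species, collapse = ", "),
      "\n  events:", nrow(x$events), " horizon:", x$t_end,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Piecewise-constant state accessor
#'
#' @param traj A `delayq_trajectory`.
#' @param t Times at which to read the state (each in `[0, t_end]`).
#' @param species Species name (default: first species).
#' @return Counts at the requested times (value right before the next event,
#'   i.e. the cadlag path).
#' @export
state_at <- function(traj, t, species = traj$species[1L]) {
  stopifnot(inherits(traj, "delayq_trajectory"))
  idx <- findInterval(t, traj$time)
  idx[idx < 1L] <- 1L
  unname(traj$state[idx, species])
}

#' First time a species reaches a level
#'
#' @param traj A `delayq_trajectory`.
#' @param species Species name.
#' @param level Count to reach.
#' @return The first event time with count `>= level`, or `NA` if never
#'   reached within the horizon.
#' @export
first_crossing <- function(traj, species, level) {
  stopifnot(inherits(traj, "delayq_trajectory"))
  hit <- which(traj$state[, species] >= level)
  if (!length(hit)) return(NA_real_)
  traj$time[hit[1L]]
}

#' Fraction of adjacent initiation pairs completing out of order
#'
#' Pairs each initiation of a delayed reaction with its scheduled completion
#' time (from the event log) and reports the fraction of adjacent initiation
#' pairs whose completions are inverted.  With random delay, proteins can
#' "skip ahead" in the maturation queue; the fraction grows with the delay
#' spread.
#'
#' @param traj A `delayq_trajectory`.
#' @param reaction Name of the delayed reaction (default: the first reaction
#'   appearing in the log with a scheduled completion).
#' @return Fraction in `[0, 1]`, or `NA` if fewer than two initiations.
#' @export
out_of_order_fraction <- function(traj, reaction = NULL) {
  stopifnot(inherits(traj, "delayq_trajectory"))
  ev <- traj$events
  ev <- ev[ev$type == "init" & !is.na(ev$completion), ]
  if (!is.null(reaction)) ev <- ev[ev$reaction == reaction, ]
  if (nrow(ev) < 2L) return(NA_real_)
  comp <- ev$completion[order(ev$time)]
  mean(diff(comp) < 0)
}
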