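#' Read and validate an experiment configuration
#'
#' Configurations are YAML (or already-parsed lists) with a `kind` field
#' (`queue_sweep`, `pdf_compare`, `ffl_pulse`, `trichotomy`,
#' `oscillator_sweep`), a model block owned by the corresponding module, and
#' an execution block (`seed`, `n_rep` or sizes, grids, `out_dir`).  Every
#' random procedure derives its stream from the single `seed` by a counter
#' rule (`seed + counter`), recorded in the manifest.
#'
#' @param config A file path to a YAML config or a named list.
#' @return The validated config list (class `delayq_config`).
#' @export
read_experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  kinds <- c("queue_sweep", "pdf_compare", "ffl_pulse", "trichotomy",
             "oscillator_sweep")
  if (is.null(config$kind) || !config$kind %in% kinds)
    stop("config error: `kind` must be one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  req <- function(fields) {
    missing <- setdiff(fields, names(config))
    if (length(missing))
      stop("config error: missing field(s) ",
           paste(missing, collapse = ", "), " for kind ", config$kind,
           call. = FALSE)
  }
  base_req <- c("seed")
  switch(config$kind,
    queue_sweep = req(c(base_req, "delay", "lambda", "K", "sigma_grid",
                        "methods")),
    pdf_compare = req(c(base_req, "delay", "lambda", "K", "n_samples",
                        "n_bins")),
    ffl_pulse = req(c(base_req, "ffl", "sigma_grid", "mode")),
    trichotomy = req(c(base_req, "delay", "lambda", "K", "N_grid",
                       "sigma_grid", "n_rep")),
    oscillator_sweep = req(c(base_req, "oscillator", "cv_grid", "n_osc"))
  )
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("config error: `seed` must be a single integer", call. = FALSE)
  structure(config, class = c("delayq_config", "list"))
}

#' Run a configured experiment
#'
#' Dispatches on `kind`, writes tidy CSV output plus a JSON manifest
#' (version, timestamp, config echo, md5 checksums of the data files) into
#' `out_dir`, and returns the result table invisibly.  Re-running with an
#' identical config reproduces byte-identical data files.
#'
#' @param config A config list, file path, or `delayq_config`.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return The main result data frame, invisibly; files on disk as a side
#'   effect.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  config <- read_experiment_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop(
    "config error: no `out_dir` given", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  result <- switch(config$kind,
    queue_sweep = exp_queue_sweep(config),
    pdf_compare = exp_pdf_compare(config),
    ffl_pulse = exp_ffl_pulse(config),
    trichotomy = exp_trichotomy(config),
    oscillator_sweep = exp_oscillator_sweep(config)
  )

  data_file <- file.path(out_dir, paste0(config$kind, ".csv"))
  write.csv(result, data_file, row.names = FALSE)
  manifest <- list(
    package = "delayq",
    version = as.character(utils::packageVersion("delayq")),
    timestamp = format(Sys.time(), tz = "UTC"),
    kind = config$kind,
    config = unclass(config),
    seed_rule = "stream i uses seed + i (counter-based spawning)",
    checksums = as.list(tools::md5sum(data_file))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

exp_queue_sweep <- function(config) {
  d0 <- delay_from_config(config$delay)
  lambda <- config$lambda
  methods <- config$methods
  n_rep <- config$n_rep %||% 10000L
  rows <- list()
  counter <- 0L
  for (K in config$K) for (sig in config$sigma_grid) {
    d <- switch(d0$family,
                two_point = two_point_delay(d0$mean, sig),
                gamma = gamma_delay(d0$mean, sig / d0$mean),
                normal_truncated = suppressWarnings(normal_delay(d0$mean, sig)),
                fixed = two_point_delay(d0$mean, sig))
    qs <- queue_spec(lambda, d, K)
    for (m in methods) {
      counter <- counter + 1L
      res <- switch(m,
        closed_form = {
          if (!d$family %in% c("two_point", "fixed"))
            stop("closed_form method applies to the two-point family",
                 call. = FALSE)
          c(mean = two_point_mean_closed_form(lambda, d0$mean, sig, K),
            var = NA_real_)
        },
        quadrature = {
          s <- signaling_time_moments(qs)
          c(mean = s$mean, var = s$variance)
        },
        monte_carlo = {
          x <- simulate_signaling_times(qs, n_rep, seed = config$seed + counter)
          c(mean = mean(x), var = var(x))
        },
        stop("config error: unknown method ", m, call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        family = d$family, mu = d0$mean, sigma = sig, cv = sig / d0$mean,
        lambda = lambda, K = K, mean_T = res[["mean"]], var_T = res[["var"]],
        cv_T = sqrt(res[["var"]]) / res[["mean"]], method = m,
        n_rep = if (m == "monte_carlo") n_rep else NA_integer_,
        seed = if (m == "monte_carlo") config$seed + counter else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

exp_pdf_compare <- function(config) {
  d <- delay_from_config(config$delay)
  qs <- queue_spec(config$lambda, d, config$K)
  samples <- simulate_signaling_times(qs, config$n_samples,
                                      seed = config$seed)
  cmp <- compare_pdf_histogram(function(t) signaling_time_pdf(qs, t),
                               samples, n_bins = config$n_bins,
                               atoms = delay_atoms(d),
                               cdf = function(t) signaling_time_cdf(qs, t))
  tab <- cmp$table
  tab$ks_stat <- cmp$ks_stat
  tab$ks_p <- cmp$ks_p
  tab
}

exp_ffl_pulse <- function(config) {
  f <- config$ffl
  spec <- ffl_spec(topology = f$topology %||% "incoherent",
                   K12 = f$K12, K13 = f$K13, K23 = f$K23,
                   lambda1 = f$lambda1, lambda2 = f$lambda2,
                   beta3 = f$beta3 %||% 1,
                   delay1 = delay_from_config(f$delay),
                   delay2 = delay_from_config(f$delay),
                   delay3 = delay_from_config(f$delay))
  incoherent_ffl_pulse(spec, sigma_grid = unlist(config$sigma_grid),
                       mode = config$mode,
                       n_rep = config$n_rep %||% 1000L,
                       seed = config$seed)
}

exp_trichotomy <- function(config) {
  d <- delay_from_config(config$delay)
  fam <- if (d$family == "normal_truncated") "normal" else d$family
  trichotomy_scan(config$lambda, family = fam, mean = d$mean, K = config$K,
                  N_grid = unlist(config$N_grid),
                  sigma_grid = unlist(config$sigma_grid),
                  n_rep = config$n_rep, seed = config$seed)
}

exp_oscillator_sweep <- function(config) {
  o <- config$oscillator
  hill <- o$hill %||% "step"
  if (is.character(hill) && hill != "step") hill <- as.numeric(hill)
  spec <- oscillator_spec(
    lambda0 = o$lambda0, C0 = o$C0, hill = hill,
    delay = delay_from_config(o$delay),
    beta_dil = o$beta_dil %||% 0, gamma_enz = o$gamma_enz %||% 0,
    enz_cutoff = o$enz_cutoff %||% 10)
  sweep_oscillator_cv(spec, cv_grid = unlist(config$cv_grid),
                      n_osc = config$n_osc, seed = config$seed)
}

#' Compare an analytic density with a sample histogram
#'
#' Bins the samples on a grid whose breakpoints include all atoms of the
#' delay distribution (where the analytic density jumps), integrates the
#' analytic PDF over each bin, and runs a Kolmogorov-Smirnov test of the
#' samples against the analytic CDF.
#'
#' @param pdf Vectorized analytic density function.
#' @param samples Non-empty numeric sample vector.
#' @param n_bins Number of bins (>= 2).
#' @param atoms Optional jump locations to force as breakpoints.
#' @param cdf Optional analytic CDF; when missing it is built by cumulative
#'   quadrature of `pdf`.
#' @return A list with `table` (data frame: `lower`, `upper`, `observed`
#'   fraction, `expected` mass), `ks_stat` and `ks_p`.
#' @export
compare_pdf_histogram <- function(pdf, samples, n_bins, atoms = numeric(0),
                                  cdf = NULL) {
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  rng <- range(samples)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
  atoms <- atoms[atoms > breaks[1] & atoms < breaks[length(breaks)]]
  breaks <- sort(unique(c(breaks, atoms)))
  counts <- tabulate(findInterval(samples, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  if (is.null(cdf)) {
    grid <- sort(unique(c(breaks, seq(breaks[1], breaks[length(breaks)],
                                      length.out = 4096L))))
    dens <- pdf(grid)
    cum <- c(0, cumsum((head(dens, -1L) + tail(dens, -1L)) / 2 * diff(grid)))
    cdf_at <- approx(grid, cum, xout = breaks)$y
    cdf <- approxfun(grid, cum, yleft = 0, yright = max(cum))
  } else {
    cdf_at <- cdf(breaks)
  }
  expected <- diff(cdf_at)
  # fold the analytic tail mass into the edge bins so masses sum to one
  expected[1L] <- expected[1L] + cdf_at[1L]
  expected[length(expected)] <- expected[length(expected)] +
    max(0, 1 - cdf_at[length(cdf_at)])
  ks <- suppressWarnings(ks.test(samples, cdf))
  list(table = data.frame(lower = head(breaks, -1L), upper = tail(breaks, -1L),
                          observed = counts / length(samples),
                          expected = expected),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
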