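# shared oracles for the test suite

# integrated delay CDF by direct quadrature (independent of the closed forms)
icdf_quadrature <- function(dist, t, rel_tol = 1e-10) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    integrate(function(s) delay_cdf(dist, s), 0, ti,
              rel.tol = rel_tol, subdivisions = 400L)$value
  }, numeric(1))
}

# chi-square goodness of fit of integer counts against a Poisson law,
# pooling both tails so every expected bin count is at least 5
poisson_gof_p <- function(counts, lambda) {
  kmax <- max(counts, qpois(1 - 1e-9, lambda))
  probs <- dpois(0:kmax, lambda)
  probs[length(probs)] <- probs[length(probs)] +
    ppois(kmax, lambda, lower.tail = FALSE)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  e <- probs * length(counts)
  keep_lo <- which(cumsum(e) >= 5)[1]
  keep_hi <- length(e) + 1L - which(cumsum(rev(e)) >= 5)[1]
  if (keep_lo >= keep_hi) stop("degenerate pooling in poisson_gof_p")
  o2 <- c(sum(obs[seq_len(keep_lo)]),
          if (keep_hi - keep_lo > 1L) obs[(keep_lo + 1L):(keep_hi - 1L)],
          sum(obs[keep_hi:length(obs)]))
  e2 <- c(sum(e[seq_len(keep_lo)]),
          if (keep_hi - keep_lo > 1L) e[(keep_lo + 1L):(keep_hi - 1L)],
          sum(e[keep_hi:length(e)]))
  suppressWarnings(chisq.test(o2, p = e2 / sum(e2)))$p.value
}

# sample skewness
skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
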