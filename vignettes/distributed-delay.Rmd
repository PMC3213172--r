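---
title: "Distributed transcriptional delay as a transient queue: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed transcriptional delay as a transient queue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayq)
```

## The model

`delayq` treats protein production as a delayed reaction: transcription of a
gene initiates as a Poisson process with rate $\lambda$, and each initiated
protein becomes functional only after an independent random maturation delay
$\tau$ with CDF $F$, mean $\mu$ and standard deviation $\sigma$. Because the
maturing molecules do not interact, this is a transient
$M/G/\infty$ queue. Three facts drive everything in the package. With
$\Lambda(t) = \int_0^t F(s)\,ds$ (the integrated delay CDF):

1. at any fixed $t$ the number of *completed* proteins $D(t)$ is Poisson
   with mean $\lambda\Lambda(t)$, and the number still maturing is Poisson
   with mean $\lambda(t - \Lambda(t))$;
2. the completion process is a homogeneous Poisson process after the time
   change $t \mapsto \Lambda(t)$, so the signaling time
   $T_K = \inf\{t : D(t) \ge K\}$ is a gamma$(K, \lambda)$ variate pushed
   through the generalized inverse $\Lambda^{-1}$;
3. completions need not respect initiation order — late initiations with
   short delays overtake early initiations with long delays. Only finitely
   many proteins enter the queue before the $K$-th one, while infinitely
   many enter after it, so the overtaking balance *accelerates* signaling:
   for delay laws symmetric about their mean, $E[T_K]$ is decreasing in
   $\sigma$ at fixed $\mu$.

The downstream readout is a step switch: a promoter regulated by the
protein flips when $K$ copies are complete. This is the sharp limit of a
steep Hill function; the package uses the convention that the $K$-th
*completed* protein flips the switch (`step_hill_rate()`), applied
uniformly across motifs.

For the symmetric two-point delay ($\tau = \mu \pm \sigma$, probability 1/2
each) everything is closed form. $\Lambda$ is piecewise linear with kinks
at $\mu \pm \sigma$, and

$$E[T_K] = \mu + \frac{K}{\lambda} - \sigma P(K, \lambda\sigma)
  + \frac{K}{\lambda} P(K+1, \lambda\sigma),$$

with $P$ the regularized lower incomplete gamma function
(`two_point_mean_closed_form()`). The curve is bounded above by its two
asymptotes — the deterministic limit $\mu + K/\lambda$ and the
large-variability line $\mu - \sigma + 2K/\lambda$ — and approaches each at
its end of the $\sigma$ axis; for $K = 1$ the approach to the second line
is exactly $-e^{-\lambda\sigma}/\lambda$, i.e. from below. (This is why the
package's tests assert the asymptotes as an *upper* envelope.) The lines
cross at $\sigma^* = K/\lambda$, the average time to initiate $K$ proteins,
which separates the deterministic regime from the accelerated one.

## Delay families and numerics

Four families are provided: two-point, gamma (parameterized by mean and
CV), normal truncated to $[0,\infty)$, and the degenerate fixed delay. All
dispersion-zero factories return the fixed family, so deterministic limits
need no special casing. Design notes:

* **Truncated normal.** A normal delay has negative-support mass that the
  queue analytics cannot accept ($F(t)$ must vanish for $t<0$). We truncate
  at zero and renormalize, report both nominal and post-truncation moments,
  and record a warning when $\sigma/\mu > 0.3$, where the bias stops being
  negligible. Analytics always use the post-truncation mean.
* **Closed-form $\Lambda$ everywhere.** Piecewise linear for two-point and
  fixed; $t F_a(t) - \mu F_{a+1}(t)$ for the gamma (CDF identities); a
  $\Phi/\phi$ expression for the truncated normal. Adaptive quadrature is
  reserved for tests, where it serves as the independent oracle — with
  integration intervals split at the atoms of $F$, since step
  discontinuities defeat adaptive error estimates.
* **Generalized inverse.** $\Lambda^{-1}(s) = \inf\{t: \Lambda(t) \ge s\}$,
  matching the first-passage semantics of the $K$-th departure at flat
  segments; closed form where available, bracketed root finding (absolute
  tolerance $10^{-10}\mu$) otherwise.
* **Moments on the rescaled axis.** $E[T_K^m] = \int_0^\infty
  (\Lambda^{-1}(s))^m g_{K,\lambda}(s)\,ds$ is integrated to relative
  tolerance $10^{-10}$, split at the kinks of $\Lambda^{-1}$, because
  $\Lambda^{-1}$ is Lipschitz where the gamma mass lies. The $t$-axis
  integral against the signaling-time density is kept as a cross-check
  (`method = "t_axis"`).
* **Jumps are preserved.** Atoms of $F$ produce jump discontinuities in the
  signaling-time *density* (not the CDF); densities are evaluated with the
  right-continuous $F$ and `delay_atoms()` exposes the breakpoints so grids
  and histograms include them.
* **Normal-delay approximation.** `normal_mean_approx()` uses the
  untruncated-normal closed form
  $\Lambda(t) \approx (t-\mu)\Phi(z) + \sigma\phi(z)$, $z=(t-\mu)/\sigma$,
  exact up to terms exponentially small in $(\mu/\sigma)^2$, inverted
  numerically; it agrees with full quadrature to $10^{-4}\mu$ in the tested
  regimes and carries a regime label relative to $\sigma^*$.

## The delayed stochastic simulator

`simulate_network()` implements the delayed extension of the exact direct
method. A putative Markovian firing time is drawn from the total
propensity; if a pending delayed completion comes first, the simulation
advances to it, applies the stored change and re-draws. Choices the
algorithm fixes (all measure-zero or exactness-preserving):

* the Markovian waiting time is *re-drawn* after a completion rather than
  shifted — exact by memorylessness and simpler;
* delays are drawn at initiation, one draw per firing, matching the queue
  semantics of delayed production;
* ties: completions before putative firings at equal times; among
  completions, insertion order;
* propensities must be piecewise-constant in state (every rate change in
  the supported models happens at an event), so event-driven re-evaluation
  is exact — no thinning is needed;
* negativity is guarded both statically (`validate_network()`) and at run
  time.

The simulator is pure R; at the problem sizes used throughout (units of
$10^5$–$10^6$ events per experiment) a full sweep runs in tens of seconds,
which keeps the whole suite desk-scale.

## Motifs

**Cascades.** In an activating chain each stage starts when the previous
one crosses its threshold, so stage times are independent and means and
variances add; the density of the total is a numerical convolution.

**Repressor switches.** If initiation runs only on a window $[0, T]$,
$E[D(t)] = \lambda(\Lambda(t) - \Lambda(\max(0, t-T)))$. For a symmetric
delay the response of $E[D(t)]$ to $\sigma$ is governed by the window
midpoint $t - T/2$: below $\mu$ the output *rises* with delay noise, above
$\mu$ it falls, at $\mu$ symmetry cancels the derivative. Note the response
can also be exactly flat when the window contains the whole support of the
delay — the classification reports what the integral actually does.

**Conditioning on N initiations.** If the gene shuts off after exactly $N$
initiations, the overtaking balance around the $K$-th protein is finite on
both sides: $E[T_K \mid N]$ *increases* with $\sigma$ for $N$ near $K$,
*decreases* for large $N$, and is flat at the balance point $N = 2K-1$
(each protein ahead of the $K$-th can trade places with one behind it).
`trichotomy_scan()` verifies this prediction by Monte Carlo with a
weighted least-squares slope in $\sigma$ per $N$; flatness means the slope
is within two standard errors of zero. The scan resolves the trichotomy
when $\lambda\sigma$ is comparable to $K$ (around the transition
$\sigma^*$); deep in the deterministic regime all slopes are numerically
tiny.

**Feedforward loops.** In the incoherent type-1 loop, gene 3 is active
while $X_1 \ge K_{13}$ and $X_2 < K_{23}$, a pulse of expected duration
$E[\Delta T] = E[T_{12}] + E[T_{23}] - E[T_{13}]$ — a linear combination of
three single-gene signaling-time curves, so its sign of response to delay
variability depends on where each threshold sits relative to its
transition. Small $K_{13}$ with large $K_{12}$ lengthens the pulse with
noise; the reverse shortens it. The simulator measures the *signed* gap
between the two crossing times (its expectation is exactly the analytic
combination, by linearity, even though the paths share gene 1), reports
the non-negative active-window duration separately, and flags empty
pulses. In the coherent AND loop the turn-on is $\max(T_{13}, T_{12} +
T_{23})$; analytic mode draws the three terms independently, which ignores
the dependence through the shared $X_1$ path — simulation mode is the
reference and the comparison quantifies that gap.

## The degrade-and-fire oscillator

A single gene represses itself through the delayed channel: production at
rate $\lambda_0/(1 + (X/C_0)^h)$ (or the step limit), first-order dilution
$\beta X$ and saturated enzymatic decay at rate $\gamma$ (linearly tapered
below `enz_cutoff` molecules so counts stay non-negative). With delay, the
proteins already committed when $X$ crosses $C_0$ keep arriving, producing
a spike; without delay the circuit just hovers at the threshold — the
zero-delay run in the test suite finds no peaks at all.

The ON window of a cycle is the gene's own signaling time with $K = C_0$,
so its mean shortens by $\Delta(\sigma) = E[T_K](0) - E[T_K](\sigma)$ when
the delay becomes variable, and both the amplitude and the period of the
oscillation fall monotonically with the delay CV — the sweep
(`sweep_oscillator_cv()`) confirms both at two standard errors. Two
analytic height predictions anchored at the empirical zero-variability
baseline $H(0)$ are tabulated: first-order
$H(\sigma) = H(0) - \lambda_0\Delta$, and a refined variant
$H(0) - s\lambda_0\Delta + \gamma\Delta$ with survival factor
$s = e^{-\beta\mu}$ (a configurable knob) that credits back dilution losses
and the shortened decay phase.

Two empirical findings from instrumented simulations are worth stating
plainly. First, the ON-window theory requires the inter-spike trough to
reset near zero — a leftover standing count of even one or two molecules
visibly shortens the measured ON window below $E[T_K]$. The default
`enz_cutoff = 2` keeps small-count decay fast enough for a full reset.
Second, for a gamma delay the pre-peak degradation window *widens* with
$\sigma$ (the arrival spread grows faster than the ON window shrinks), so
the simulated height drop slightly *exceeds* $\lambda_0\Delta$ in every
regime we examined; the first-order prediction is then uniformly the
closer of the two, and the refined variant — which by construction
predicts a smaller drop — overestimates the heights. The refined form is
retained because its structure is instructive and its survival factor is
exposed for exploration, but users comparing predictions to simulations
should expect the first-order curve to track better for heavy-tailed
delays.

**Default regime.** $\lambda_0 = 40$, $C_0 = 4$, $\mu = 2$,
$\beta = 0.05$, $\gamma = 4$: spikes of roughly 75 molecules, period about
16–20 time units, chosen so that (i) the trough fully resets, (ii) the
decay phase stays long compared to the delay spread across the whole CV
grid (cycles remain coherent up to CV 0.8), and (iii) a thousand cycles
simulate in about a minute.

**Peak detection.** A peak is the maximum of an excursion strictly above
`min_height` (default $C_0$), with two safeguards: peak-relative
hysteresis — a new peak requires the path to drop below half the previous
peak's height in between — and a refractory merge keeping the higher of
two close candidates. Raw local maxima are useless here: straggler
completions put small bumps on the decaying flank, and the threshold hover
before the main burst arrives would register as a separate peak. Excursions
still open at the end of the record are censored.

## The synthetic-data scope

Everything in the package runs on internally generated realizations; there
is no external data. What the generators emulate: memoryless initiation,
i.i.d. maturation delays from the four families, step-like regulation,
first-order dilution and saturated proteolysis. What they deliberately do
not: bursty (non-Poisson) initiation, cell-to-cell variability of the delay
law itself, finite service capacity (polymerase/ribosome exclusion), and
graded Hill regulation in the *analytic* formulas (the simulator accepts
finite Hill coefficients for comparison). Passing tests therefore validate
the queueing theory and the simulator against each other under these
assumptions — they do not certify that any particular biological system
satisfies them; in particular genes of copy number one, where initiation
order cannot be permuted, sit outside the overtaking argument.

## Problem sizes and tolerances

The test suite and the acceptance script use: $10^5$ Monte Carlo
signaling-time samples per KS comparison, $10^4$ delayed-SSA runs for the
transient Poisson and cascade checks, $10^5$ replicates per trichotomy
cell, 800 simulated loops per feedforward grid point, and at least $10^3$
oscillator peaks per CV point. Statistical assertions use two standard
errors for monotonicity claims and three for mean comparisons; exact
analytic identities are asserted at $10^{-8}$ relative or tighter. These
sizes keep the full suite within a coffee break on one CPU while leaving
every statistical margin at several standard errors.
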