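---
title: "Selecting the MVAR segment length from stationarity, and the DTF pipeline behind it"
author: "kurtoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the MVAR segment length from stationarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Directed (effective) connectivity from EEG is usually computed by
fitting a multivariate autoregressive model

$$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + \varepsilon_t$$

on short segments of the multichannel recording and reading directed
influence off the spectral transfer matrix
$H(f) = [I - \sum_k A_k e^{-i 2\pi f k / f_s}]^{-1}$ via the squared
Directed Transfer Function,
$\mathrm{DTF}^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_m |H_{im}(f)|^2$, the
fraction of the spectral inflow into sink $i$ contributed by source
$j$ (rows sum to one by construction). The MVAR fit presumes each
segment is weak-sense stationary. This package treats the segment
length not as a convention but as a parameter to be estimated from the
data's own stationarity profile.

The stationarity score is the excess kurtosis
$K'(x) = E[(x-\mu)^4]/\sigma^4 - 3$ of each segment. After band-pass
filtering the channel mean is zero and the variance carries no shape
information, so the fourth standardized moment is the lowest moment
that still discriminates: it is zero in expectation for a Gaussian
segment and drifts when the segment mixes regimes with different
scales or tail weights. The working assumption — shared by the score's
use as a non-stationarity index — is that a stationary stretch of EEG
is approximately Gaussian, so departures from Gaussianity within a
window flag departures from stationarity at that window length.

For each channel, the recording of duration $t$ is cut into
non-overlapping windows of duration $w_i = i \cdot W_L$,
$i = 1 \dots N_w$ (trailing samples that do not fill a window are
dropped; the segment count is exactly $\lfloor t / w_i \rfloor$). The
variance of the per-segment kurtosis vector collapses each
channel-duration pair to one dispersion score, giving the
channels-by-multiples matrix $K\sigma^2$. For i.i.d. Gaussian data the
sample excess kurtosis has asymptotic variance $24/n$, so entries fall
like $1/(i \cdot W_L f_s)$ with window length; a duration whose
windows straddle regime boundaries breaks that law with inflated,
heterogeneous variances. The selection exploits exactly this contrast.

## The selection rule

A Gamma density is fitted to all $K\sigma^2$ entries by maximum
likelihood (started from method-of-moments estimates; a chi-square
target is the Gamma(k/2, scale 2) special case, so the Gamma family
covers it). Its mode $pk = (\alpha - 1)/\beta$ anchors the search;
when the fitted shape is at most 1 the density peaks at the support
edge and the matrix minimum is used instead. With fewer than 10
entries the method-of-moments fit stands in for the MLE; a matrix of
identical values is treated as a point mass at that value, and an
all-zero matrix is an error.

Two search procedures are provided:

* `varianceSearch` is the iterative interval search: $[L_b, H_b]$
  starts at $pk$ and widens by the searching rate $c$ per side each
  iteration (default $c$ = 1% of the matrix range, `kMax` = 200); at
  each width every channel contributes the SHORTEST duration whose
  variance falls inside, and the search stops once more than
  `threshold1`·M channels qualify and the mean selected variance is at
  most `threshold2` times the mean per-channel maximum (defaults 0.5
  and 0.4). Widening never removes a channel, so the retained count is
  monotone in the interval width. The unit tests hold this procedure
  equal to a brute-force enumeration oracle on matrices up to 8 × 10.

* `selectWindow` is the percentage-threshold selection used for the
  per-recording window. The interval at percentage $p$ spans $p$% of
  the distance from $pk$ down to the matrix minimum and up to the
  matrix maximum, so $p = 100$ covers every entry. For each duration
  the minimal $p$ at which its column places at least
  $\lceil \mathrm{threshold1} \cdot M \rceil$ channels inside is
  available in closed form (each value's entry percentage is its
  distance from $pk$ relative to the span on its side), and the
  duration with the smallest qualifying percentage wins, ties going to
  the shorter duration. Computing the exact percentage rather than
  scanning a 10%-step grid was a deliberate design choice: adjacent
  variance clusters (for example the $24/n$ floors of two neighbouring
  durations) are often separated by far less than 10% of the span, and
  a coarse grid degenerates the choice to "shortest duration inside
  the first step". The 10..100 grid remains the reporting convention
  of `percentageDomain`, which reproduces the count-per-cell table
  layout used for visual inspection.

Per-recording selections aggregate across a cohort by the statistical
mode of the windows (ties to the shorter), with variance and channel
percentages averaged and rounded.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `windowLength` (W_L) | 1 | s | elemental duration; 1 s resolves all conventional EEG rhythms |
| `nWindows` (N_w) | 10 | – | longest candidate 10 s; beyond that too few segments remain per recording |
| `threshold1` | 0.5 | fraction | minimum share of channels that must share the stationarity range; per-recording overrides are accepted |
| `threshold2` | 0.4 | fraction | bound on mean selected variance relative to the mean per-channel maximum |
| `c` | 1% of range | variance units | searching rate of the iterative interval |
| band-pass | 0.5–50 | Hz | removes drift/DC and line-frequency residue, keeps delta through gamma |
| resample target | 250 | Hz | ample for alpha-band connectivity; 4x lighter MVAR fits |
| Kaiser design | 60 dB, 1 Hz transition | – | stopband/transition unstated upstream; exposed in the API. The low-edge transition is capped at the edge frequency so the stopband still reaches 0 Hz |
| `order` / `orderMax` | BIC, 12 | – | order selection unstated upstream; BIC over 1..12 |
| `alpha` | 0.05 | – | raw per-edge threshold; optional Benjamini-Hochberg flag |
| costs | 21, 30, 51, 100 | % | representative sparse-to-full snapshots of the masked network |

## Numerical choices

* **Kurtosis estimator.** Population moments (denominator $n$), as the
  defining expectation ratio is written; the bias-corrected G2
  estimator is available behind a flag. The variance in the
  $K\sigma^2$ matrix is the population variance of the
  *uninterpolated* kurtosis vector; interpolation (linear, endpoints
  preserved) is only used to pool profiles of different lengths into
  per-channel kurtosis densities.
* **Zero-phase filtering.** The FIR is applied once with its integer
  group delay compensated, after even-reflection padding at both ends.
  Zero phase matters because a phase-shifted filter would smear
  segment boundaries and distort segment-wise kurtosis; even
  reflection (rather than anti-symmetric reflection) preserves the
  local mean at the edges so the filter's DC null is not polluted by
  pad discontinuities.
* **MVAR estimation.** Ordinary least squares on the stacked lag
  regression, residual covariance with denominator $n - p$, stability
  checked on the companion matrix; unstable segment fits are excluded
  from the DTF tensor without shifting the indices of the remaining
  segments.
* **Significance test scale.** Band-averaged squared-DTF values are
  strongly right-skewed, which makes a one-sided t-test on the raw
  scale conservative. The test therefore applies the Wilson–Hilferty
  cube-root transform — the classical normalizing transform for
  chi-square-type statistics — to the segment values and to the null
  level before the t-test. Two nulls are available: `uniform` tests
  against $1/M$, the equal-inflow reference (conservative by
  construction, since estimated off-diagonal DTF under no coupling
  sits well below $1/M$); `surrogate` tests against the edge-specific
  mean DTF of phase-randomized copies of the recording, which
  calibrates the test to the estimator's own no-coupling distribution.
  Zero-variance edges are flagged significant iff their mean exceeds
  the null level.
* **Graph conventions.** Path-based and clustering measures run on the
  binarized graph at the given cost; strength uses weights. Directed
  clustering is Fagiolo's total clustering; betweenness is normalized
  by $(N-1)(N-2)$; disconnected pairs contribute 0 to efficiency and
  are excluded from the characteristic path length so neither
  diverges. The cost rule is the magnitude convention — $p$% keeps
  edges within $(100-p)$% of the maximum weight — which differs from
  the "top $p$% of edges" convention.
* **Ties.** Every tie over durations resolves to the shorter duration,
  consistent with the objective of maximizing segments per recording.

## What the synthetic generators emulate

`simulatePiecewiseStationary` produces channels built from consecutive
$\tau$-second blocks drawn from alternating regimes (Gaussian or
Laplace, i.i.d. or AR(1) within block; defaults: Gaussian,
$\sigma \in \{1, 3\}$, $\tau$ = 4 s). Windows aligned with $\tau$ see
one regime per segment and a kurtosis variance on the $24/n$ floor;
misaligned longer windows mix regimes and inflate it — the structure
the selection is designed to detect, with $\tau$ as recoverable ground
truth. `simulateMVAR` generates stable MVAR realizations with a known
directed edge set (spectral-radius rescaling to 0.95 when a requested
coefficient set is unstable) for connectivity-recovery and
significance checks. `cohortFixture` assembles paired R1/R2 recordings
with a metadata table in the retention filter's layout; artifact
rejection itself is not simulated — the clean duration simply scales
the raw one, matching the package's position that cleaning happens
upstream and only its summary output is consumed.

None of these emulate volume conduction, spatially correlated noise,
1/f spectra, or the gradual (rather than block-switching)
non-stationarity of real EEG. Passing tests therefore demonstrate that
the algorithms implement their definitions and recover planted
structure under the stated regimes, not that 4 s is the right window
for any particular laboratory's recordings.

## Problem sizes used by the tests

The suite exercises the same code paths as a full-scale analysis at
reduced sizes chosen for a single CPU: recovery simulations use 8
channels x 200 s at 250 Hz over 20 seeds; calibration and power use 5
channels x 60 s with 30 segments of 2 s, 20 surrogates, 50 seeds, with
the DTF grid restricted to the alpha bins that the test consumes;
oracle enumeration covers all digraphs on 3 nodes plus seeded random
4-8 node graphs; the estimator-variance law uses 200 replicates of 60
s. Full-scale dimensions (62 channels, 1000 Hz native, 3-5 min) are
the generator defaults and run in the same code without modification.

## Known limitations

* The selection assumes the candidate grid $i \cdot W_L$ contains the
  true timescale; non-integer multiples are not searched.
* The Gamma fit pools all channels and durations; a recording whose
  channels split into distinct stationarity families yields a
  compromise peak. Per-recording `threshold1` overrides are the
  intended relief.
* The surrogate null refits the MVAR per phase-randomized copy at the
  tensor's median order rather than re-running order selection — a
  deliberate economy; order selection on surrogates would multiply
  cost for little change in the null level.
* The uniform-inflow null is a reference level, not a calibrated null;
  use surrogates when false-positive control matters.
* EDF support covers continuous 16-bit recordings with one shared
  sampling rate (the scalp-EEG case); annotations and variable-rate
  signals are out of scope.
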