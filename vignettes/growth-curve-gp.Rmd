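---
title: "Modeling microbial growth curves with Gaussian processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial growth curves with Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpgrowth)
```

## The model and its assumptions

A growth assay observes optical density $OD(t)$ in a well over time. After
preprocessing (below), the corrected log curve $y(t) = \ln OD(t)$ is
modeled as a zero-mean Gaussian process with a squared-exponential (RBF)
kernel plus independent Gaussian measurement noise:

$$y \sim N\!\big(0,\; K\big), \qquad
k(t_i, t_j) = \sigma^2_{RBF}\exp\!\Big(-\frac{(t_i-t_j)^2}{2\ell^2}\Big)
  + \sigma^2_{noise}\,\delta_{i=j}.$$

The assumptions are deliberately weak: the latent growth function is
smooth on the scale of the lengthscale $\ell$, the measurement noise is
additive, Gaussian and time-independent, and the curve has been anchored
at zero so a zero-mean prior is sensible. Nothing sigmoidal is assumed,
which is the point — biphasic curves, post-stationary decay and flat
wells are all representable. Replicates are pooled by stacking their
observations at repeated time points; the GP then infers one latent curve
whose uncertainty shrinks with replication.

Hyperparameters are chosen by maximizing the log marginal likelihood
$-\tfrac12 y^\top K^{-1}y - \tfrac12\log|K| - \tfrac{n}{2}\log 2\pi$ with
L-BFGS-B on log-transformed parameters, analytic gradients, and three
restarts (the first from $\ell = \mathrm{span}/10$,
$\sigma^2_{RBF} = \mathrm{var}(y)$,
$\sigma^2_{noise} = 0.1\,\mathrm{var}(y)$; the others log-normally
perturbed, reproducibly under the configured seed). All hyperparameters
are bounded to $[10^{-6}, 10^{6}]$. These optimizer choices are this
package's own: multi-restart quasi-Newton is the standard treatment of
the multimodal GP likelihood, and the bounds keep degenerate flat wells
(where $\sigma^2_{RBF}$ collapses) numerically well behaved.

Because differentiation is linear, the growth rate $y'(t)$ and
acceleration $y''(t)$ have closed-form posteriors obtained by
differentiating the kernel; function and derivative are predicted
jointly, so posterior draws of a curve and of its rate are mutually
consistent. Latent predictions exclude the noise variance; credible bands
add it back when requested.

## Preprocessing

Corrections apply in a fixed order: (1) drop the first $n$ time points
(readers are noisy right after inoculation); (2) subtract the pointwise
mean of blank (medium-only) wells; (3) subtract the pointwise mean of
group-specific control wells within each group; (4) shift the plate so
its minimum is at the positivity floor; (5) take the natural log;
(6) anchor the curve at zero. Steps 4–6 are mandatory, the rest opt-in.
Where several blank or control wells exist their pointwise mean is used —
an unbiased and simple aggregate; the choice of mean over median matters
little for the handful of control wells a plate carries.

The `"auto"` positivity floor is the median absolute change in OD between
consecutive measurements pooled over the plate — a robust scale for the
smallest believable reading. A user-supplied limit of detection overrides
it.

Baseline anchoring subtracts the first log measurement by default, so
every curve starts at exactly zero. The optional polynomial baseline
instead evaluates, at the first time point, a cubic fitted to the first
five $(t, \ln OD)$ points. A degree-five polynomial through five or six
points would interpolate them and return the first measurement unchanged,
so the degree is capped at two below the window size to obtain a genuine
smoothing estimate; the option requires at least six time points so the
window is a proper subset of the curve.

## Growth parameters

All parameters are read off the latent posterior on an evenly spaced grid
spanning the observed times (same count as unique observation times —
dense enough that grid discretization is far below posterior
uncertainty):

- $K = \max_t \mu(t)$ and $r = \max_t \mu'(t)$, with argmax ties broken
  by the earliest time;
- AUC as the left-endpoint Riemann sum with one $\Delta t$ weight per
  grid point, $AUC \sim N(a\mu,\, a\Sigma a^\top)$ — so a constant $c$
  over $m$ points yields exactly $c\,m\,\Delta t$;
- lag $= t_r - \mu(t_r)/r$ (tangent construction; undefined when
  $r \le 0$);
- adaptation time: first grid time at which the credible interval of
  $\mu'(t)$ lies above zero;
- death $= |\mu(T) - K|$ and the maximum death rate
  $\min_{t \ge t_K}\mu'(t)$, reported signed (negative while the culture
  declines; the sign convention follows the "most negative rate" reading,
  and the restriction window makes it a *stationary-phase* death rate);
- doubling time $\ln 2 / r$.

Sampling-based summaries recompute every parameter on each of $n$ joint
posterior draws (default 100) and report means, standard deviations and
percentile intervals. Draws in which a parameter is undefined (a flat
draw has no lag) are dropped from that parameter's summary with the count
recorded — censoring them at zero would bias the intervals.

## Diauxie detection

Inflection points are the zero crossings of the posterior mean
acceleration, located by sign change with linear interpolation; upward
crossings (growth-rate valleys) are *positive*, downward ones *negative*,
and the first and last time points always count as positive so phases
tile the window. Crossings are ignored unless $|\mu''|$ exceeds
$10^{-6}$ on **both** flanking segments: flat curves produce
floating-point chatter whose neighboring segment magnitudes are
essentially zero, while a genuine phase boundary has curvature on both
sides. Exact zeros on the grid attach to the left interval.

Candidate phases between consecutive positive inflections are merged
iteratively: rank phases by total growth (or, optionally, by maximum
rate), compare the smallest against the largest, and stop once the
smallest contributes at least the threshold ratio (default 20%).
Otherwise the smallest merges into the neighbor with the lower
activation energy — the gap between the phase's own maximum rate and the
rate at that boundary — with ties and edge phases resolving leftward.
Diauxie is called when at least two phases survive. The procedure is
deterministic, and monotone in the threshold: raising it can only merge
more.

## Differential growth

Conditions enter the kernel as extra input dimensions with their own
lengthscales, encoded 0/1 (two levels) or one-hot (more). The null model
sees time only; the alternative sees time plus condition; the log Bayes
factor is the difference of their optimized log marginal likelihoods,
each fitted independently with fresh restarts. The null distribution
permutes condition labels across whole curves — never across time points,
which would destroy the autocorrelation the test depends on — and the
significance threshold is the $100(1-\mathrm{FDR})$ empirical percentile
(default the 90th). Designs with fewer distinct label assignments than
requested permutations fall back to enumerating all of them, which is the
exact null.

The functional difference $OD\Delta(t)$ is the difference of the two
condition curves predicted jointly from the alternative model, and
$\lVert OD\Delta\rVert = \sqrt{\sum_t OD\Delta(t)^2}$ is its Euclidean
norm (the norm includes the radical; the "sum of squared differences"
reading without it would not scale like a distance). Its credible
interval comes from percentiles of the norm over joint posterior draws of
the difference, noise-free by default and configurable. As a scale-aware
summary it inherits the magnitude of the curves — doubling both
conditions doubles the norm — which is why the Bayes factor, not the
norm, carries the significance decision.

## The synthetic generator, and what passing tests show

The generator produces log-scale sigmoids parameterized directly by the
quantities the package estimates,
$y(t) = K / (1 + \exp\{4r/K(\lambda - t) + 2\})$, whose maximum slope is
exactly $r$ and whose tangent at the inflection crosses zero exactly at
the lag $\lambda$; sums of two sigmoids give biphasic curves, a linear
post-onset decline gives decay shapes, and iid Gaussian noise on the log
scale gives replicates. Default conditions emulate a typical anaerobe
assay: 24 h at 10-min cadence, inoculation OD 0.05 for plate export,
noise sd 0.02 ln OD, three technical replicates.

This emulates the dominant structure of real plate data but not all of
it: real noise is heteroscedastic over time (larger in stationary
phase), replicates share systematic batch effects, and OD is a proxy that
can saturate or respond to lysis chemistry. Passing recovery and coverage
tests therefore demonstrates the estimator's correctness under its own
assumptions, not robustness to every instrumental artifact. The optional
empirical noise profile — replicate variance per time point smoothed with
a 1 h Gaussian filter, held fixed during optimization and never used for
prediction at new times — is the provided escape hatch for
heteroscedasticity.

## Numerical choices and edge cases

- Cholesky factorizations are attempted unjittered first; on failure a
  jitter of $10^{-8}$ times the mean diagonal is escalated by factors of
  100. This keeps the likelihood exact on well-conditioned problems and
  pooled designs (repeated time points) stable.
- Posterior sampling uses an eigendecomposition with negative eigenvalues
  clamped to zero, tolerating the semi-definite covariances that arise at
  near-interpolated points.
- Credible bands default to the *posterior* latent variance plus noise
  terms; a strict composition using $\sigma^2_{RBF}$ verbatim is exposed
  (`latent = "prior"`). The prior form ignores conditioning on the data
  and is wider everywhere; it is kept because both compositions are
  defensible readings of the band formula and the difference is visible
  exactly where data constrain the fit.
- Flat wells: $\sigma^2_{RBF}$ collapses to its bound, $K \approx 0$,
  $r \approx 0$, lag and doubling are reported missing.
- Time units are hours everywhere; explicit time axes with values above
  100 are treated as seconds and divided by 3600 unless configured
  otherwise.

## Problem sizes

The shipped tests and the acceptance script simulate at the study
conditions (145 time points, 3 replicates) for parameter recovery, and at
30–90 min cadences for the heavier Monte Carlo pieces: 20 recovery
plates, 50 coverage fits, a 100-permutation effect-case test with five
replicates per condition, and 20 null-calibration repeats using all 70
distinct label assignments of a 4-vs-4 design. These sizes give stable
medians and rates while keeping a full run in the minutes range on one
core.

## Known limitations

Only RBF kernels are offered; strongly nonstationary curves (abrupt
lysis) are smoothed at the lengthscale the whole curve selects.
Heteroscedastic noise is handled only through the fixed empirical
profile, not learned jointly. The diauxie heuristic operates on the
posterior mean, so phase boundaries carry no uncertainty statement. One
categorical covariate is tested per run (multi-level via one-hot);
hierarchical replicate structure (mixed-effects GPs) is out of scope.
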