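---
title: "Notched random-dot kinematograms: stimulus construction, task simulation, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Notched random-dot kinematograms: stimulus construction, task simulation, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdknotch)
```

## The measurement problem

Motion transparency — perceiving two superimposed motions in the same
region of the visual field — is classically studied by asking observers
whether a display "looks transparent". That judgement depends on each
observer's private response criterion, so differences between
conditions and between observers are confounded with criterion shifts.

The criterion-free alternative implemented by this package turns
transparency into a discrimination. Each trial presents three
random-dot kinematogram (RDK) intervals. Two contain the *standard*: a
dot field whose per-dot speeds (or directions) are drawn from a uniform
discrete distribution. One contains the *comparison*: dots drawn from
two distributions that together cover the same range and have the same
global mean as the standard, but are separated by an empty central
interval — a speed *notch* or a directional *gap*. The observer simply
reports which interval is the odd one out (3AFC oddity; chance = 1/3).
Because the range and the global mean are matched by construction, no
strategy based on the fastest, slowest, or average motion can succeed:
only the internal structure of the distribution — the notch assumed to
drive the transparent percept — distinguishes the comparison.

The package supplies all the machinery this method needs: distribution
construction under the matching constraints, dot kinematics, trial and
session simulation against model observers, and the psychometric
analysis of the resulting logs.

## Distribution construction

All distributions are finite grids of speeds (deg/s) or directions
(deg) with per-point probabilities (`discrete_distribution`). Four
families cover the experimental designs:

* **Symmetric notch at varying width** (`build_symmetric_notched`):
  the default speed range is 0.4–23.6 deg/s at 1 deg/s spacing, global
  mean 12 deg/s; notch widths 1–19 deg/s.
* **Targeted distance between band means**
  (`build_mean_targeted_notched`): two 8.1-deg/s bands around a fixed
  7-deg/s notch, with per-band sampling densities chosen so the local
  means sit 13–17 deg/s apart while the global mean stays at 12 deg/s.
* **Bandwidth family** (`build_bandwidth_family`): total spans of
  8–20 deg/s with the 7-deg/s notch and the 12-deg/s mean held fixed.
* **Constant mean distance at varying notch**
  (`build_constant_distance_notched`): slow (1.2–8 deg/s, mean 4.6)
  and fast (17.2–24 deg/s, mean 20.6) ranges, notch widths 1.2–5.2
  deg/s, with the distance between band means held constant.
* **Directional gaps** (`build_direction_gapped`): a 58-deg span of
  directions about 30 deg, gaps 2–50 deg, at fixed dot speed.

### Gridding conventions

Two small but consequential numerical choices are made here.

First, the configured speed ranges are not always whole multiples of
the grid spacing (0.4–23.6 deg/s spans 23.2 deg/s at a 1-deg/s grid).
A grid laid out from one end would miss the upper endpoint and shift
the mean (to 11.9 rather than 12). `build_uniform` therefore anchors
the grid at *both* declared endpoints and grids inward; the residual
incommensurability is absorbed at the central seam (a single 1.2-deg/s
gap between 11.4 and 12.6 in the default standard). This preserves the
declared endpoints, the span, and — by symmetry — the mean, exactly.
For commensurate ranges it reduces to the ordinary regular grid.

Second, band anchoring for notched distributions. The default
(`band_anchor = "outer"`) grids each band from its outer range endpoint
toward the notch, dropping points strictly inside the notch; points
landing exactly on a notch edge belong to the band (closed bands, open
notch), which makes the zero-width notch literally identical to the
uniform standard. Where the notch width is itself a controlled constant
of a family — the 7-deg/s notch of the mean-distance and bandwidth
families — each band is instead anchored at *both* its endpoints
(`band_anchor = "both"`), so the band width and notch width keep
exactly their configured values for any grid spacing (the 8.1-deg/s
bands are not a whole multiple of any of the available spacings).

### Mean control by exponential tilting

The mean-distance and constant-distance families require a band on a
fixed grid to take a prescribed mean. The experimental description —
"changing the sampling density" — fixes no functional form, so the
package uses the canonical minimally-informative solution: exponential
tilting, `w_i ∝ exp(λ x_i)` (`solve_band_tilt`). The tilted mean is
strictly increasing in λ, so λ is found by a doubling bracket and
Brent root-finding to 1e-12; λ = 0 (uniform weights) is returned
exactly when the target equals the unweighted band mean, and targets
outside the open band interval are rejected as infeasible. Each band
carries probability mass 1/2, which pins the global mean at the range
midpoint irrespective of the tilt. Constraint satisfaction is verified
to 1e-6 deg/s at construction time.

The constant mean distance of the slow/fast family is nowhere printed
in the experimental description; the package default is 6.0 deg/s, a
value feasible for all four notch widths on both speed ranges
(band means at midpoint ± 3 deg/s), exposed as a parameter.

Direction arithmetic is linear, not circular: all direction supports
span at most 58 deg about their mean, far from wrap-around; any global
rotation of the stimulus is applied modulo 360 at trial level.

## Stimulus kinematics

`stimulus_spec()` carries the display geometry: 226 dots (2 dots/deg²)
of 0.1-deg diameter in a 12-deg circular aperture, 10 images per
interval at an 18.75-Hz update rate (533.3 ms; the update rate is every
4th frame of a 75-Hz display). Dots are initialised uniformly over the
aperture *area* and, on every positional update, each dot independently
redraws its speed (or direction) from the source distribution — dot
speed performs a random walk across the interval, so tracking any
single dot cannot reveal the extremes of the underlying distribution.
Displacement per update is `speed / update_rate`; a dot leaving the
aperture is redrawn on the opposite side (point reflection through the
centre, clamped just inside the rim — the most literal reading of the
wrap rule; re-entry along the motion chord would be an alternative).
Dots may overlap; positions are continuous degrees, with pixel
quantisation applied only in `rasterize()`.

The maximum-displacement (Dmax) task uses the same displays except that
all dots share one fixed displacement per update, all leftward or all
rightward; at 18.75 Hz a 100-arc-min displacement corresponds to a
31.25-deg/s dot, and no speed used by the oddity experiments exceeds
24 deg/s.

## Task simulation and model observers

`make_oddity_trial()` places the comparison at a uniformly random
interval, samples the two standard intervals independently, and draws a
shared trial direction from [0, 360) (speed experiments) or holds a
shared fixed speed (direction experiments). `run_session()` presents
interleaved (or blocked) conditions, passes each trial to the observer
*blinded* — the observer view contains interval dot data but never the
odd position — and logs one row per trial; invalid responses are
recorded as protocol violations rather than scored. A session is fully
reproducible from its configuration and master seed; per-component
sub-seeds are derived from the master seed with `derive_seed()` so
components can be re-run in isolation.

The observers are inventions of this package, not claims of the
experimental work:

* `observer_guessing()` — the chance floor.
* `observer_speed_gap(noise_fraction)` — perceives each sampled speed
  with multiplicative (Weber-like) Gaussian noise and computes the
  largest empty gap among an interval's perceived speeds; the interval
  whose gap statistic is most distant from the other two is chosen
  (`oddity_decision`). The largest-gap statistic was preferred over
  bimodality coefficients or mixture fits because it targets exactly
  the manipulated construct (the notch) and has a trivial brute-force
  oracle. Multiplicative noise is the simplest mechanism that erases a
  fixed-width notch at fast absolute speeds while sparing it at slow
  ones.
* `observer_direction_gap()` — the direction analogue, with optional
  speed-scaled direction noise.
* `observer_dmax(limit, slope)` — a calibrated response model whose
  percent correct declines logistically through 75% at the configured
  displacement limit. A rule with an exactly calibrated accuracy cannot
  be stimulus-blind, so this model (alone) reads the trial's true
  direction; it exists for threshold-recovery tests of the analysis
  chain.

No observer learns across trials: the task provides no feedback.

## Psychometric analysis

`summarize_session()` counts exactly: proportions are integer ratios,
the per-condition error is the closed-form binomial standard error, and
pooled multi-observer tables append an across-observer mean with SEM
error bars (the convention of multi-observer performance plots).
Oddity experiments are reported as raw proportion-correct curves;
fitting them is optional. For the Dmax task, `fit_psychometric()`
performs a maximum-likelihood binomial fit with the guess rate fixed by
the task (1/2 single-interval, 1/3 oddity), a free lapse rate bounded
by default at 0.06 (or fixed at zero for lapse-free simulated data),
and Weibull or logistic families — the 75%-correct threshold criterion
is fixed; no particular family is canonical for this task, so both are
provided and the family used should be reported. The fit-free
alternative, the highest level still meeting the criterion, is provided
as `threshold_highest_passing()` so an analysis can state which
convention produced its number. `bootstrap_ci()` resamples trials
within condition and refits for percentile intervals.

## What the simulations do and do not show

The synthetic pipeline emulates the *stimulus* conditions exactly — the
distribution statistics are hard constraints verified to 1e-6 or better
— and the *procedure* faithfully (trial structure, counterbalancing,
blinding, trial counts). It does not emulate human vision: the model
observers are statistical readouts of the sampled values, not of the
spatiotemporal stimulus, and their quantitative accuracies are
properties of those readouts. Passing tests therefore demonstrate that
the method is internally sound (matched constructions admit no trivial
strategy; a notch-sensitive statistic recovers the manipulation; the
analysis recovers known thresholds), not that any observer model
reproduces human performance curves.

## Problem sizes and numerical settings

The bundled tests run the chance floor at 10^4 trials, the
gap-observer monotonicity sweep at 2000 trials per notch width, and
Dmax threshold recovery at 280 trials per level (the procedure's
per-condition minimum), using draws-only interval generation where the
observer reads only sampled values. Constraint tolerances are 1e-9 for
probability normalisation and grid geometry, 1e-6 deg/s for mean
constraints, and 1e-12 in λ for the tilt root-finder. All randomness
flows from explicit seeds; identical seeds give bit-identical
trajectories, logs, and summaries.

## Known limitations

* No display backend: timing, gamma correction, and photometry are out
  of scope; `rasterize()` is for inspection, not presentation.
* Gridded distributions only; continuous or non-uniform base shapes are
  not supported.
* The mapping between grid spacing and condition used in the original
  mean-distance manipulation is not recoverable from its description;
  the tilting construction is this package's declared stand-in, and the
  0.2-deg/s default spacing is one of the documented spacings chosen
  for feasibility across all conditions.
* Linear direction arithmetic restricts direction spans to well under a
  half-circle (enforced by the configured geometry).
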