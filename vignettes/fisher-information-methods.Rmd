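---
title: "Tracking system stability with the discrete Fisher information index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking system stability with the discrete Fisher information index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisherinfo)
```

## The model

A system observed through $n$ variables $y_1, \dots, y_n$ occupies, at each
time step $t_j$, a point $v_j = (y_1(t_j), \dots, y_n(t_j))$ in phase
space. Small fluctuations and measurement error should not count as changes
of state, so two observations are declared *indistinguishable* when

$$|y_i(t_j) - y_i(t_k)| \le \Delta y_i$$

holds for (enough of) the variables, where $\Delta y_i$ is the
per-variable **size of state**, in that variable's units. A *state* is
therefore an $n$-dimensional hyper-rectangle with sides $2\Delta y_i$.

Within one time window of $w$ consecutive steps the points are partitioned
into states by a greedy, center-based procedure: the earliest unassigned
point founds a state and becomes its center; every later unassigned point
inside the center's hyper-rectangle is captured immediately; captured
points are never reassigned, even if a later center's rectangle also
covers them. Iterating until all $w$ points are assigned yields $m$ states
in discovery (time) order. Two consequences of this definition are worth
stating because they look like bugs and are not:

* membership is tested against the *founding center only*, so two members
  of one state may differ by more than $\Delta y_i$ (in the worked example
  of `?bin_window`, points 3 and 5 share a state although their first
  coordinates differ by 0.65 against a width of 0.5);
* the partition depends on the time order of the points. Discovery order
  is part of the method; a sorted or permutation-invariant variant would
  change results and is deliberately not offered.

The window's state occupancies give probabilities
$p_i = (\text{points in state } i)/w$ and amplitudes $q_i = \sqrt{p_i}$,
and the discrete Fisher information is

$$\mathrm{FI} = 4 \sum_i (q_i - q_{i+1})^2,$$

with the amplitude sequence, taken in discovery order, padded with a zero
before $q_1$ and after $q_m$. The amplitude form exists to avoid dividing
by small probabilities; since $p$ comes from counts, no small-denominator
guard is needed anywhere. The zero boundary makes the index strictly
positive, with sharp analytic anchors used throughout the test suite:
$\mathrm{FI} = 8$ exactly when $m = 1$ (and only then), and a uniform
occupancy over $m$ states gives exactly $8/m$. Expanding the squares shows
$\mathrm{FI} = 8\,(1 - \sum_{i<m} q_i q_{i+1}) \le 8$ for any profile.

The index is computed per sliding window and attributed to the window's
*last* time step, so every reported value uses only past data; incomplete
trailing windows are dropped. For a series of $T$ steps, width $w$ and
increment $h$ give $\lfloor (T-w)/h \rfloor + 1$ values.

Interpretation follows the sustainable-regimes reading: a high, nearly
constant index marks an orderly regime; a steady decline marks loss of
order and is an early warning; a steady rise marks stabilisation; a sharp
drop marks a regime shift, with depth proportional to severity. Between
regimes, the more stable one has the higher mean index $\mu_{FI}$ and the
lower standard deviation $\sigma_{FI}$. The absolute value of the index
matters less than its trend.

## Parameters

* **Size of state** $\Delta y_i$ (units of each variable). Either supplied
  explicitly or estimated as $k \cdot \mathrm{sd}_i$ over an
  analyst-chosen stable reference period. Chebyshev's inequality makes the
  estimate distribution-free: at least $1 - 1/k^2$ of observations fall
  within $k$ standard deviations of the mean, whatever the distribution.
  The default $k = 2$ covers at least 75%. The package uses the *sample*
  standard deviation (denominator $T-1$); the convention is not fixed by
  the method's description, and the sample form is the conservative
  default (slightly wider bins). Automatic detection of a "stable period"
  is out of scope — it is an analyst judgement. A zero width is legal
  (only exact ties bin together) but triggers a warning, since it usually
  means a degenerate variable.
* **Window width** $w$ (time steps). At least 8 is recommended: with
  fewer points the occupancy estimate $p_i$ is too coarse. The package
  warns below 8 but computes. Width is positional, not calendar-based: a
  "40-year window" is 40 consecutive yearly rows.
* **Window increment** $h$ (time steps, default 1). Must not exceed $w$
  so that behaviour crossing a window boundary is seen by at least one
  window; $h = w$ is allowed with a warning.
* **Tightening level** TL $\in (0, 1]$: the minimum fraction of variables
  that must satisfy the size-of-state criterion. The natural grid is
  multiples of $1/n$; "strict" is TL $= 1$. In `tl = "averaged"` mode the
  per-window index is the mean of the index over the contiguous prefix of
  the grid from 1 down to the lowest level at which the window still
  resolves more than one state (lowering TL can only merge states, so the
  prefix is well defined).
* **Smoothing block** $b$ (entries, default 1 = off). Non-overlapping
  blocks of $b$ consecutive index values are replaced by their mean, the
  trailing partial block by its own mean; labels are untouched. A
  high-frequency filter; keep $b$ small or the timing of shifts blurs.
* **Trend heuristics** (`classify_trend`): trailing least-squares slope
  within ±0.05 index units per step = stable, beyond = increasing or
  declining, and a single-step drop greater than 2 index units =
  sharp_drop (which takes precedence). The interpretation rules are
  qualitative; these numbers are explicit heuristics, exposed as
  arguments. The assessment span defaults to 8 entries, matching the
  recommended minimum window width; entries with less history are
  assessed over what exists, and the very first entry is labelled stable.

## Numerical choices

* The indistinguishability comparison is inclusive ($\le$), as the
  criterion is stated; a point on the rectangle's face is inside.
* The "fraction of variables" test is `count >= tl * n - 1e-9`: the small
  slack only guards against floating-point representation of fractions
  like $1/3$; it cannot change a decision at the grid's resolution.
* States are numbered by founding order and enter the index sum in that
  order; the first point of a window always founds state 1.
* In averaged-tightening mode the reported `n_states` is the strict-level
  count, with `n_levels` recording how many levels entered the mean.
* Degenerate inputs: a single-point window is one state (index 8); an
  empty window, an empty stable period, a window wider than the series,
  and an increment above the width are errors stating the offending
  quantity.
* Published intermediate values for the worked example include two
  inner-sum terms (0.13, 0.21) that are inconsistent with their own
  expression (the exact terms are 0.0126 and 0.0214) while the printed sum
  0.534 and total 2.136 match exact computation; the package computes
  exactly and the tests check the sum and the total.

## Open design points

Two readings of "averaging the tightening levels" are possible: averaging
the *index* across the level set (implemented) or collapsing the level
fractions into one level and binning once. Likewise the level set could be
determined per window (implemented, since more than one state "in a
window" is the stated stopping rule) or fixed globally across the run.
Strict mode sidesteps all of this and is the default; averaged mode
follows the first reading of each choice.

For $\sigma_{FI}$ in regime summaries the sample standard deviation is
used (the choice is not fixed by the method; with the typical 60–97
entries per regime the difference is in the third decimal).

## The synthetic generator

`simulate_regimes()` produces piecewise-stationary series: contiguous
regimes, each drawing every variable independently as
$N(\mu_i, \sigma_i^2)$ per time step, with a mandatory seed (the global
RNG stream is saved and restored). It emulates exactly the structure the
index is designed to detect — step changes in the mean vector against
light, uncorrelated noise — which makes every pipeline stage testable with
known answers: noiseless single-regime data must sit at the ceiling
($\mathrm{FI} = 8$ in every window), and a two-regime series with mean
separation far beyond the size of state follows the closed form
$\mathrm{FI} = 4[f + (\sqrt{f} - \sqrt{1-f})^2 + (1-f)]$ in a window with
fraction $f$ of its points before the change. What it does *not* emulate:
autocorrelation, trends within regimes, heavy tails, cross-variable
correlation, seasonality, or missing data. Tests passing on this generator
therefore validate the mechanics of the method, not its behaviour on any
particular real system.

Test problem sizes are kept small because the answers are exact anyway:
property suites use on the order of 1000 random occupancy profiles,
dozens of random windows of up to 20 points in up to 5 variables, and
synthetic series of 60–136 steps — the size at which the worked example
and the yearly case study operate.

## The temperature case study, and why it is approximate

The published application of this index to global monthly temperature
anomalies (1880–2015; each calendar month one variable, so $n = 12$;
anomalies in 0.01 °C; $w = 40$, $h = 1$; the 12-entry size-of-state
vector 35.96 … 40.81) reports $\mu_{FI} = 5.09$, $\sigma_{FI} = 0.89$ for
1919–1978 and $\mu_{FI} = 4.04$, $\sigma_{FI} = 1.32$ for 1979–2015, with
the index declining from about 1978. The package ships everything needed
to re-run it — `read_gistemp_monthly()`, the delta vector as a config
(`inst/extdata/gistemp_case_study.yaml`) and
`scripts/gistemp_case_study.R` — but not the data: GISTEMP is revised
retroactively as station records are reprocessed, the exact product
version behind the published numbers is not recorded, nor are the
tightening/smoothing settings or the stable period behind the printed
delta vector (which is why it is shipped as an explicit input, not
re-estimated). Agreement within roughly 15% of the published summaries is
the realistic expectation for a present-day download; exact reproduction
is not attainable from the publication record.

## Known limitations

* The greedy binning is order-dependent by design; series differing only
  by a permutation of time points give different partitions.
* The index has no uncertainty quantification; $\sigma_{FI}$ describes
  spread across windows, not estimation error.
* Variables are treated symmetrically; there is no weighting and no
  post-hoc attribution of a shift to particular variables.
* Rows with any missing variable are dropped at ingestion (binning needs
  complete points, and the method defines no imputation), which shortens
  windows' calendar span when gaps are present.
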