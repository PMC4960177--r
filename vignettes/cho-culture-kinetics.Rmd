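---
title: "Modelling growth, glucose consumption and antibody production in CHO cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth, glucose consumption and antibody production in CHO cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chokinetics)
```

## The models

This package implements a deliberately simple, unstructured kinetic
description of Chinese hamster ovary (CHO) cell cultures producing a
monoclonal antibody (mAb), the kind of model a process engineer can fit from
routine daily samples and then use for feeding-strategy and
temperature-shift what-ifs.

**Growth.** The specific growth rate follows Monod saturation kinetics in
the glucose concentration *in excess of a threshold*:

$$\mu(S) \;=\; \mu_{max}\,\frac{S - S_t}{K_s + (S - S_t)}
\qquad (S > S_t), \qquad \mu = 0 \;\; (S \le S_t).$$

The threshold $S_t$ captures the empirical observation that CHO cultures
stop growing well before glucose is exhausted (a "kinetic growth
limitation"); for the producing line it sits near 0.6 g/L. `monod_mu()` is
continuous at the threshold, non-decreasing, and approaches $\mu_{max}$ from
below.

**Substrate.** Glucose consumption is growth-linked through a constant
cell/substrate yield, $r_s = -r_x / Y_{x/s}$, with $Y_{x/s}$ in cells per mg
glucose.

**Product.** Antibody formation follows Luedeking–Piret mixed kinetics,

$$\frac{dP}{dt} \;=\; \alpha\, r_x \;+\; \beta\, X,$$

with a growth-associated constant $\alpha$ (µg/cell) and a
non-growth-associated constant $\beta$ (µg/cell/h). With the package's
canonical units (h, cells/mL, g/L, mg/L) both terms come out in mg/L/h with
no conversion factors; all unit conversion happens at the I/O boundary,
never inside the math. The net growth rate $r_x$ (negative in the death
phase) enters the law literally by default, so a collapsing population
reduces the production rate; `clamp_rx = TRUE` floors the growth-associated
term at zero for users who prefer the conservative variant.

On the units of $\alpha$ and $\beta$: the sources for the shipped constants
print the two unit labels both ways around in different places. Dimensional
analysis of the production law fixes them unambiguously —
$\alpha r_x$ is (µg/cell)(cells/mL/h) and $\beta X$ is (µg/cell/h)(cells/mL)
— and that convention ($\alpha$ in µg/cell, $\beta$ in µg/cell/h) is used
throughout.

## Shipped parameter registry

`cho_parameter_registry()` carries the fitted parameter sets for the naive
(n-CHO) and recombinant producing (r-CHO) lines at 33 and 37 °C. Published
values for the same quantity disagree in places (the tabulated batch
parameters versus the values printed alongside the growth-rate figure), so
conflicting sets are shipped under distinct source tags (`table2`,
`fig3caption`) and a lookup of a missing key is an error, never a silent
default. For the producing line at 33 °C the non-growth-associated constant
is shipped as 7.68e-8 µg/cell/h, the value three of the four printed
occurrences agree on. At 37 °C no single $\beta$ fits all data sets; the
registry carries the midpoint of the published range (see
`beta_range_37C()`), and the temperature-recalibration test checks
containment in that range rather than a point value.

The registry serializes to a flat TOML-style text file (`write_registry()` /
`read_registry()`) with full-precision floats, so a round trip is
bit-identical and every analysis can snapshot the exact constants it used.

## Estimation procedures

The estimation module reproduces the published two-stage procedure:

1. **Threshold** from a low-glucose growth screen: the threshold is
   bracketed between the highest no-growth level and the lowest growth
   level (`estimate_threshold()`); the midpoint is the point estimate. It is
   then *held fixed* downstream.
2. **Specific growth rates** per initial glucose level as the slope of
   $\ln X$ versus $t$ over an exponential window
   (`estimate_mu_loglinear()`); $r^2$ is computed on the log scale and the
   published validity gate ($r^2 > 0.97$) applies.
3. **Monod constants** by Lineweaver–Burk linearization
   (`fit_monod_lineweaver_burk()`): regress $1/\mu$ on $1/(S_0 - S_t)$,
   unweighted on the reciprocal scale as the linearization implies;
   $\mu_{max} = 1/\text{intercept}$, $K_s = \text{slope}/\text{intercept}$.
   A direct nonlinear Monod fit (`fit_monod_nls()`) is provided as a
   diagnostic cross-check, not the default.
4. **Yield** as the through-origin slope of $r_x$ versus $-r_s$
   (`estimate_yield()`); the balance has no intercept, so the free-intercept
   variant exists for diagnostics only. Rates come from analytic
   derivatives of least-squares polynomials (`fit_polynomial_window()`,
   `differentiate()`): degree 2 for exponential-phase profiles, degree 6 for
   the full-culture cell profile used in production fitting (one source
   prints "fifth-order" for a figure; the degree is an argument, default 6).
   Derivatives are never evaluated outside the fit window — high-degree
   polynomials diverge off-window and extrapolation is an error.
5. **Production constants** two ways: `fit_lp_direct()` regresses $r_p$ on
   $(r_x, X)$ with no intercept, and errors on exactly exponential cell
   profiles where $r_x \propto X$ makes the design rank-deficient;
   `fit_lp_integral()` tunes $(\alpha, \beta) \ge 0$ so the forward-Euler
   integration of the production law matches observed titers, by coordinate
   descent with golden-section line searches (deterministic given the
   guess; convergence at 1e-10 relative objective change). The integral fit
   is the robust choice on noisy titers, because the direct fit must
   differentiate a noisy product profile.
6. **Temperature transfer** (`recalibrate_at_temperature()`): holding $S_t$
   and $\alpha$ fixed, re-fit $\mu_{max}$, $Y_{x/s}$ and $\beta$ by
   minimizing the squared mismatch between a batch simulation and observed
   $\{X, S, P\}$, each variable normalized by its observed maximum so the
   cell-count scale (~10^6) cannot swamp substrate and product. Nelder–Mead
   on log-parameters keeps the search positive and scale-free.

### Exponential-window choice

`select_exponential_window()` scans all contiguous windows of at least
`min_points` samples and keeps the longest whose log-linear $r^2$ reaches
the floor (default 0.98), ties to the earliest start. The pipeline wrapper
`estimate_growth_parameters()` defaults to `min_points = 5` (five daily
samples): with an exponential phase of roughly five days, three-point
windows make the $r^2$ criterion nearly vacuous and yield unstable slopes
whose reciprocals then leverage the Lineweaver–Burk fit badly. Replicate
fits failing the $r^2 > 0.97$ validity rule are excluded before averaging,
as in the original procedure; if that would leave fewer than three glucose
levels, all fits are kept and a warning issued.

Because the substrate is drawn down *within* the fit window, log-linear
slopes at daily sampling sit slightly below $\mu(S_0)$ — a few percent at
full-strength medium, more at the lowest level. This is a property of the
measurement design, not a bug: the round-trip tests that demand sub-percent
recovery therefore generate from the estimation model itself (constant
$\mu(S_0)$, `substrate_dynamics = FALSE`), while the stochastic-recovery
test runs the full ODE generator and tolerates the combined
mismatch-plus-noise error.

## Simulation

`simulate_batch()` integrates the coupled balances with fixed-step RK4
(default `dt = 0.1` h; forward Euler selectable to mirror the discrete
production update). Substrate, product and lactate are clamped at zero.
With no death or maintenance, $X + Y_{x/s} S$ is conserved *exactly* by the
integrator (the invariant is linear, so every Runge–Kutta stage preserves
it), which the tests exploit: $X - X_0 = Y_{x/s}(S_0 - S)$ holds to
floating-point error at all times.

`simulate_fed_batch()` adds bolus feed events — volume increases and every
concentration mixes as $C \leftarrow (CV + C_{feed}V_f)/(V + V_f)$, with
cell-, product- and lactate-free feed — and temperature shifts that swap
the active registry parameter set. All registry entries a schedule needs
are resolved before integration starts. The exact pre/post states at each
feed are returned in the `feed_log` attribute so conservation at events can
be verified exactly. The default protocol mirrors the published bioreactor
experiments: five daily feeds of 10% of the initial volume from day 1, and
a temperature shift on day 7. The shift target is 33 °C (the protocol
described for the fed-batch figure); the alternative 31 °C variant from the
methods description requires a user-supplied registry entry at 31 °C, since
no 31 °C parameter set was published. The feed's glucose concentration is
not published either; the default is 45 g/L, typical of concentrated
commercial CHO feeds, and is an explicit `feed_event()` field.

## Synthetic data: what it emulates, and what it does not

The study's raw time series are shown only as figures, so
`generate_batch_dataset()` stands in for them: seeding at 2×10^5 cells/mL,
initial glucose 1.2/2.4/3.6/4.8 g/L, triplicates, daily sampling, 7-day
(r-CHO) or 10-day (n-CHO) cultures, concentration-dependent lag phases for
naive cells (0/24/48/72 h as the medium is diluted), and measurement noise
applied after sampling, never inside the ODE: mean-unbiased multiplicative
lognormal on counts (CV 5%) and titers (CV 10%), additive Gaussian on
glucose and lactate (SD 0.05 g/L). A seed makes every dataset bit-for-bit
reproducible.

The published equations alone cannot produce two prominent features of the
real trajectories — the post-peak death phase and complete glucose
depletion (growth-linked consumption asymptotes at the threshold). The
fixture parameter sets (`fixture_parameters()`) therefore add scaffolding
that is clearly flagged as beyond the published model: a first-order death
rate $k_d = 0.01$ h⁻¹ active once glucose is at or below the threshold, and
a maintenance consumption $m_s$ = 4e-9 mg/cell/h calibrated once, by
forward simulation, so glucose runs out just before day 6 as observed
(simulated: depletion at day 5.9, peak 7.9×10^6 cells/mL on day 5, peak
lactate 0.93 g/L). The two-regime lactate sub-model (production
proportional to growth, then constant per-cell consumption of
0.05 ng/cell/day after depletion) is scaled so growth-phase production is
about 0.1 ng/cell/day with peak lactate below 1 g/L.

What passing tests on these data do **not** show about real cultures: there
is no density-dependent growth limitation (a generously fed simulated
culture overshoots observed peak densities), no lactate inhibition of
production, no glutamine or amino-acid balances, no product degradation,
and temperature enters only through discrete per-temperature parameter
sets. Maintenance consumption also depresses the *apparent* yield recovered
by the rate pipeline below the generating growth yield — visible in the
analysis scripts and expected whenever substrate is diverted from growth.

## Numerical choices

- RK4 fixed step, default 0.1 h; the last step of a segment absorbs grid
  rounding. Integration aborts with a step report on non-finite state.
- Polynomial bases are centred at the window midpoint before least squares;
  raw powers of times up to 240 h at degree 6 are badly conditioned.
  Coefficients are reported in the centred variable with the shift
  recorded.
- $r^2$ on constant data with an exact fit is reported as 1 (not 0/0);
  through-origin fits use the uncentered $R^2$ convention.
- The forward-Euler product update uses the left endpoint, so the
  growth-associated term telescopes exactly to $\alpha \Delta X$ when $r_x$
  is supplied as forward differences — the property the round-trip tests
  rely on.
- The integral production fit brackets each constant in
  $[0, \text{scale-derived upper bound}]$ and stops when a full coordinate
  sweep improves the objective by less than 1e-10 relatively; exceeding the
  sweep cap is an error that reports the objective trace.
- Trapezoidal quadrature for the integral of viable cells (the quadrature
  was not specified; the trapezoid is additive over adjacent windows, which
  the specific-rate bookkeeping relies on).

## Problem sizes used in the validation suite

The shipped validation suite runs the full estimator battery at the study's
own scale: 0.1 h integration grids over 7–20 day cultures, daily sampling,
triplicates, and a 20-seed replication of the stochastic recovery
experiment. Measured at those conditions, the median error of the recovered
$\mu_{max}$ across seeds is about 3–6% with a bias of −3%, comfortably
inside the 15%/5% bands the tests assert; the whole suite completes in
about half a minute.
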