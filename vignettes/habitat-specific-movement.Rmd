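---
title: "Habitat-specific butterfly movement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-specific butterfly movement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mjmove studies how habitat-dependent *activity* (how much time a butterfly
spends flying) and habitat-dependent *movement rate* (how fast and how
straight it flies) jointly shape dispersal in heterogeneous grassland.  The
package covers the full chain: synthetic field observations, movement
statistics, empirically parameterized samplers, an individual-based
correlated random walk with explicit activity budgets, and dispersal-kernel
summaries across neutral fractal landscapes.

## The movement model

An individual is, at any moment, either **stationary** (an inter-flight bout:
nectaring, basking, inactive or ovipositing) or **flying**.  The
individual-based model (IBM) alternates the two states:

1. Draw an inter-flight duration and wait.
2. Draw a flight duration $T$ and split it into $\lceil T/15 \rceil$
   segments of 15 s each (the final one the remainder), matching the field
   protocol in which positions are flagged at every landing and every 15 s
   of continuous flight.
3. For each segment, turn by a von Mises angle added to the current heading
   and draw a step length from the empirical marginal distribution of step
   lengths *for segments of that duration*; move in a straight line so the
   step is completed exactly in the segment time.  This decouples movement
   rate from flight time: a long flight is a chain of redrawn steps, not one
   enormous step.
4. At flight end, draw one further turn, then return to 1.

All four input components — flight durations, inter-flight durations, step
lengths, turning angles — are fitted per sex.  The four model variants cross
two switches: variant I uses pooled parameters throughout; variant II keys
the *activity* components (flight and inter-flight durations) by the habitat
class under the agent; variant III keys the *movement* components (steps and
turns); variant IV keys everything.  Habitat is re-queried at the agent's
instantaneous position at every draw.

Dispersal is the Euclidean displacement accumulated over the simulated
activity time.  The full-scale experiment uses 5000 agents for 5 days of 8
activity hours each after an 8-h burn-in; displacement is measured from each
agent's position at the end of the burn-in, removing the influence of the
uniform-random initial positions.  Nights are not simulated: the clock
counts activity time only.

## Samplers

* **Durations** are drawn by linear interpolation of the inverse empirical
  CDF (`fit_ecdf()` / `sample_ecdf()`).  Draws are bounded by the observed
  minimum and maximum; there is no tail extrapolation.  This is a stated
  limitation: the simulated kernels cannot contain bout durations more
  extreme than the fitted sample.
* **Step lengths** are conditioned on segment duration by a k-nearest
  neighbour rule (`conditional_step_sampler()`, default `k = 20`): the k
  pairs with durations nearest the query are pooled and one of their step
  lengths is drawn uniformly.  kNN pooling was chosen over fixed-width
  duration bins because the observed durations are continuous and sparse at
  the long end, where fixed bins would be empty; ties prefer the smaller
  duration, then input order, so draws are reproducible.  When pairs are
  built from tracks, a flight spanning a single flag interval contributes
  one (flight duration, landing-to-landing length) pair; longer flights
  contribute one pair per 15-s airborne segment plus the final remainder
  segment at its actual duration, so that short-duration marginals keep
  mass.
* **Turning angles** are fitted by maximum likelihood for the von Mises
  family (`fit_vonmises()`): location = circular mean; concentration by
  inverting $A_1(\kappa) = \bar R$ from the Best–Fisher series start with
  Newton refinement on the exact Bessel ratio.  $\kappa$ is set to 0 when
  $\bar R \le 1/\sqrt{n}$ (indistinguishable from uniform).  The fitted
  location is kept as estimated; no symmetrization around zero is forced.
  Sampling uses the Best–Fisher rejection algorithm, with two explicit
  degenerate regimes: $\kappa = 0$ is circular uniform and
  $\kappa \ge 10^6$ returns the location exactly (circular sd below
  $10^{-3}$ rad), which makes straight-walker configurations exactly
  straight — useful for closed-form oracles.

## The synthetic field campaign

Real flag-based tracking data for this design are not publicly deposited, so
the package ships a generator (`generate_tracks()`) that emulates the field
protocol: 2 habitats (resource-rich meadow, resource-poor mown turf) × 2
sexes, 50 individuals per cell (200 in total), each followed until 600 s or
15 flags, with flags at landings and 15-s airborne marks.  Durations and
speeds are lognormal — the field literature analyses these quantities on a
log scale, and the true empirical CDFs are unknown — with a von Mises turn
at flight start and at each 15-s mark, and speed drawn once per flight
(the simplest structure consistent with flag-to-flag step speeds).

Default parameters (shipped in
`inst/extdata/default_generator_config.yaml`, loaded by
`default_generator_config()`) were calibrated once, on realism grounds:

* effect directions: on poor habitat both sexes fly faster, straighter
  (higher $\kappa$), longer, with shorter inter-flight intervals;
* flying fractions of total time approximate observed budgets (~65%/45% for
  males on poor/rich, ~20%/<10% for females), via the ratio of mean flight
  to mean inter-flight duration;
* non-flight time is dominated by nectaring on rich habitat and inactivity
  on poor habitat; ovipositing occurs only for females on poor habitat;
* the resulting short-term net displacement is roughly three times larger
  on poor than on rich habitat, the headline field contrast.

What the generator does **not** emulate: weather, time of day, conspecific
interaction, edge responses (each synthetic track lives in homogeneous
habitat), observation stops for lost identity, and any within-individual
behavioural correlation beyond the bout structure.  Passing tests therefore
demonstrate internal consistency of the pipeline and parameter recovery
under the assumed structure — not validity of the lognormal/von Mises
assumptions for real butterflies.

Each generated track carries its realized bout schedule, and
`generate_behaviour_log()` labels flight bouts `flying` and assigns each
inter-flight bout one non-flight category.  Statistics follow the field
definitions: step speed is literal flag-to-flag distance over time (which
may bracket stationary time across a landing); turning angles are signed
angles between successive step vectors, regardless of intervening landings;
flight durations are the fully observed flight bouts; inter-flight durations
only the stationary intervals flanked by flights on both sides (edge bouts
are censored, not imputed); individuals that never flew contribute no
flight-duration mean rather than a zero.

## Numerical and design choices

* **Event-driven clock.** The model is conceptually a 1-s-tick machine, but
  every process in it is piecewise linear between events (bout boundaries
  and 15-s segment boundaries), so the core advances event-to-event in
  continuous time.  This is exact — the distance moved over a segment
  equals the drawn step length to machine precision — and avoids cumulative
  rounding from tick quantization.  A pure-R single-agent event stepper
  (`simulate_agent()`) is implemented independently of the compiled core
  and cross-checked against it in the tests.
* **Exactly one turn per segment boundary** and one at flight end.  Whether
  a landing/take-off pair should compose two turns is ambiguous in the
  verbal protocol; since no movement occurs between them, a single draw is
  behaviourally equivalent and keeps the turn count per flight well
  defined.
* **Landscape.** Diamond-square midpoint displacement on a 257 × 257 grid
  (side 2^8 + 1) covering 3 km², i.e. 6.74-m cells — fine enough to resolve
  patches far smaller than a 60 × 100 m field patch.  Displacement sd
  scales by $2^{-H}$ per subdivision level.  Cells above the empirical
  $(1-p)$-quantile are rich, so the rich-cell count is exactly
  `round(p * n²)` and the achieved proportion is not a nuisance dimension.
  Movement wraps toroidally (the protocol is silent on boundaries);
  displacements accumulate in unwrapped coordinates, so wrapping does not
  distort kernels.  Clumping is monitored by the same-class join-count
  proportion, which rises with $H$.
* **Validation spans.** Field observations stop at the 15-flag quota as
  well as the 10-min clock, so fast individuals are observed for well under
  600 s.  `model_comparison()` therefore simulates each sex × habitat cell
  for that cell's mean observed span; comparing full-600-s simulations
  against quota-truncated observations would penalise precisely the
  variants that match the fast cells best.
* **Sweep seed schedule.** In `landscape_sweep()` the fractal surface seed
  depends only on the root seed and $H$, so the rich masks are nested in
  $p$; the simulation stream seed depends on variant, $H$ and sex but not
  $p$ (common random numbers across the proportion grid).  Variant
  responses to $p$ are therefore not blurred by between-run sampling noise,
  and variant I — which never consults habitat — is exactly flat in $p$.
* **Kurtosis** is Pearson moment kurtosis $m_4/m_2^2$ on the 1-D sample of
  displacement magnitudes, computed with population moments: the normal
  reference is 3, the two-point lower bound 1, and the large-sample 95%
  half-width $1.96\sqrt{24/n}$ (0.14 at $n = 5000$) presumes exactly this
  convention.

## Problem sizes

The shipped analyses use deliberately moderate sizes chosen to give stable
Monte-Carlo estimates: 200 synthetic individuals (the field campaign size),
1000 simulated observations per cell for the RMSE validation, and for the
sweep summaries 2000 agents per run over one simulated day (8 activity
hours after an 8-h burn-in) on the 9-point proportion grid at $H = 0.5$.
The full paper-scale experiment (5000 agents, 5 days, three $H$ levels,
both sexes) runs with the same functions by changing the arguments.

## Known limitations

* Inverse-CDF samplers cannot generate values outside the fitted range, so
  extreme-tail dispersal is bounded by the source data.
* The normal-theory kurtosis CI ($\pm 1.96\sqrt{24/n}$) badly understates
  the sampling variability of kurtosis for leptokurtic samples; it is
  reported for comparability, not as an honest error bar.
* In strongly contrasted landscapes the kernel's kurtosis need not peak
  exactly at equal habitat shares: near the rich-dominated edge the scarce
  poor habitat supports a small, fast-moving subpopulation, and a scale
  mixture's kurtosis is largest when the wide component has small weight.
  The kurtosis maximum in the sweep accordingly sits in the interior but
  can sit above $p = 0.5$, and the rich-dominated edge can stay elevated;
  kurtosis collapses only as $p \to 1$ removes the fast component
  altogether.
* Habitat-edge behaviour (crossing reluctance), energetics, mortality and
  reproduction are out of scope; agents respond to habitat only through
  the parameter keying described above.
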