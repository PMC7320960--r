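# mjmove

Habitat-specific butterfly movement analysis and individual-based dispersal
simulation.

Grassland butterflies such as the meadow brown (*Maniola jurtina*) change
both their **activity budget** (how much time they spend flying) and their
**movement rate** (how fast and how straight they fly) between resource-rich
meadow and resource-poor mown grassland.  Classic correlated-random-walk
dispersal models carry only steps and turns, so they miss the activity side
of this response.  mjmove is for movement ecologists who want to quantify
both effects from flag-based field tracks and to propagate them into
dispersal forecasts over heterogeneous landscapes.

The core model alternates stationary inter-flight bouts and flights.  A
flight of duration $T$ is split into $\lceil T/15\rceil$ segments (15 s
each, final remainder shorter); each segment gets a von Mises turn
$\theta \sim \mathrm{vM}(\mu, \kappa)$ added to the heading and a step
length drawn from the empirical marginal distribution of step lengths for
segments of that duration, completed at constant speed within the segment;
one further turn follows each flight.  Durations are drawn by linear
interpolation of inverse empirical CDFs.  Four variants cross two switches —
are the *activity* components (flight/inter-flight durations) habitat
specific, and are the *movement* components (steps/turns)? — giving models
I (neither), II (activity), III (movement) and IV (both).  Kernels are
summarised by mean displacement and Pearson kurtosis $m_4/m_2^2$
(leptokurtic above 3), with large-sample 95% CI half-width
$1.96\sqrt{24/n}$.  Landscapes are neutral fractals: diamond-square midpoint
displacement with Hurst parameter $H$ (clumping) and an exact rich-cell
proportion $p$ via quantile thresholding.

Since the original field tracks are not deposited, the package ships a
calibrated synthetic field campaign (`default_generator_config()`,
`generate_tracks()`) that emulates the protocol: 200 individuals followed up
to 600 s or 15 flags, flags at landings and 15-s airborne marks, lognormal
bout durations and speeds, von Mises turns, and behaviour logs (flying,
nectaring, basking, inactive, ovipositing).

## Worked example

```r
library(mjmove)

cfg    <- default_generator_config()          # the shipped study conditions
tracks <- generate_tracks(cfg, seed = 2024)   # 200 synthetic individuals
gm     <- group_means(summarise_tracks(tracks))
gm[, c("sex", "habitat", "mean_step_speed", "mean_flight_duration_s",
       "mean_interflight_duration_s", "net_displacement_m")]
#>   sex habitat mean_step_speed mean_flight_duration_s mean_interflight_duration_s net_displacement_m
#> 1   F    poor          0.2685                   6.48                       30.39               39.0
#> 2   F    rich          0.0768                   4.17                       61.96               10.5
#> 3   M    poor          0.5996                  14.38                        9.11               54.7
#> 4   M    rich          0.2554                   8.47                       11.83               19.6
```

Both sexes fly faster and longer with shorter rests on poor habitat, and
10-min net displacement is roughly three times larger there (39 vs 10.5 m
for females) — the habitat contrast the models must reproduce.

```r
model_comparison(tracks, n_obs = 1000, seed = 2025)
#>   variant rmse_m
#> 1       I  18.93
#> 2      II  14.09
#> 3     III   9.53
#> 4      IV   5.06
```

Predicted short-term displacement improves monotonically as activity (II),
movement (III) or both (IV) become habitat specific: ignoring the activity
response costs accuracy that step-and-turn corrections alone cannot recover.

```r
params <- merge_parameter_sets(build_parameter_set(tracks, FALSE),
                               build_parameter_set(tracks, TRUE))
landscape_sweep(params, variants = c("I", "IV"), p_rich = c(0.2, 0.5, 0.8),
                hurst = 0.5, sexes = "F", n_agents = 1000, days = 1,
                seed = 2026)[, c("variant", "p_rich", "mean_displacement_m", "kurtosis")]
#>   variant p_rich mean_displacement_m kurtosis
#> 1       I    0.2               162.1     3.22
#> 2       I    0.5               162.1     3.22
#> 3       I    0.8               162.1     3.22
#> 4      IV    0.2               188.0     3.41
#> 5      IV    0.5               121.5     5.32
#> 6      IV    0.8                90.2     9.52
```

Under the null model I the kernel ignores landscape composition (identical
rows: it never consults habitat, and the sweep uses common random numbers
across `p_rich`).  Under model IV, mean 1-day displacement falls by half as
rich habitat saturates the landscape, and the kernels become strongly
leptokurtic — far-moving individuals dominate dispersal — once the two
habitats mix.

A thin CLI wraps the same functions
(`exec/mjmove generate|stats|fit|landscape|simulate|compare|sweep`); the
methods vignette (`vignettes/habitat-specific-movement.Rmd`) documents the
model, the calibration of the synthetic campaign, and the numerical choices.

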