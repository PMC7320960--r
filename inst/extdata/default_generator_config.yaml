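# Default synthetic field-observation conditions for mjmove.
#
# One cell per habitat (resource-rich meadow vs resource-poor mown turf) and
# sex.  Durations and speeds are lognormal: *_logmu is the log of the median
# (log-seconds or log m/s), *_logsigma the log-scale sd.  turn_kappa is the
# von Mises concentration of turning angles (higher = straighter flight).
# behaviour_proportions partition non-flight time and must sum to 1.
#
# Calibration (chosen once, on field realism grounds):
#  - effect directions: in resource-poor habitat both sexes fly faster,
#    straighter, longer, with shorter inter-flight intervals;
#  - implied flying fractions of total time approximate the observed budgets
#    (males ~65% poor / ~45% rich; females ~20% poor / <10% rich);
#  - within non-flight time, nectaring dominates in rich habitat, inactivity
#    in poor habitat; ovipositing occurs only for females in poor habitat;
#  - females fly faster than males but rest longer, so displace less.
n_individuals: 50
max_obs_duration_s: 600
max_flags: 15
flag_interval_s: 15
rng_seed: null
cells:
  rich:
    F:
      flight_dur_logmu: 1.2528       # median 3.5 s
      flight_dur_logsigma: 0.6
      interflight_dur_logmu: 3.6889  # median 40 s
      interflight_dur_logsigma: 0.9
      speed_logmu: -0.5978           # median 0.55 m/s
      speed_logsigma: 0.5
      turn_kappa: 0.5
      behaviour_proportions:
        nectaring: 0.45
        basking: 0.05
        inactive: 0.50
        ovipositing: 0.0
    M:
      flight_dur_logmu: 1.9459       # median 7 s
      flight_dur_logsigma: 0.6
      interflight_dur_logmu: 2.1401  # median 8.5 s
      interflight_dur_logsigma: 0.8
      speed_logmu: -0.7985           # median 0.45 m/s
      speed_logsigma: 0.5
      turn_kappa: 0.7
      behaviour_proportions:
        nectaring: 0.35
        basking: 0.10
        inactive: 0.55
        ovipositing: 0.0
  poor:
    F:
      flight_dur_logmu: 1.7047       # median 5.5 s
      flight_dur_logsigma: 0.6
      interflight_dur_logmu: 2.9957  # median 20 s
      interflight_dur_logsigma: 0.9
      speed_logmu: -0.1054           # median 0.9 m/s
      speed_logsigma: 0.5
      turn_kappa: 1.2
      behaviour_proportions:
        nectaring: 0.03
        basking: 0.04
        inactive: 0.83
        ovipositing: 0.10
    M:
      flight_dur_logmu: 2.4849       # median 12 s
      flight_dur_logsigma: 0.6
      interflight_dur_logmu: 1.8718  # median 6.5 s
      interflight_dur_logsigma: 0.8
      speed_logmu: -0.2877           # median 0.75 m/s
      speed_logsigma: 0.5
      turn_kappa: 1.6
      behaviour_proportions:
        nectaring: 0.07
        basking: 0.08
        inactive: 0.85
        ovipositing: 0.0
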