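# Shared fixtures: degenerate parameter sets and generator configs built in
# code, plus a two-sample Kolmogorov-Smirnov distance helper.

# constant-bout parameter set: every flight lasts flight_s seconds, every
# inter-flight inter_s seconds, every segment covers step_m metres, turns are
# von Mises(mu, kappa); same components under pooled, rich and poor keys
constant_params <- function(flight_s = 15, inter_s = 0, step_m = 15,
                            kappa = 1e6, mu = 0, sexes = c("F", "M")) {
  comp <- list(flight = fit_ecdf(rep(flight_s, 2)),
               interflight = fit_ecdf(rep(inter_s, 2)),
               steps = conditional_step_sampler(rep(flight_s, 2), rep(step_m, 2)),
               turn = turn_model(mu, kappa))
  sets <- list()
  for (sex in sexes) {
    sets[[sex]] <- list(pooled = comp, rich = comp, poor = comp)
  }
  movement_parameter_set(sets)
}

# one-cell override of the default generator config
config_with <- function(..., n_individuals = 5) {
  cfg <- default_generator_config(n_individuals = n_individuals)
  over <- list(...)
  for (hab in c("rich", "poor")) {
    for (sex in c("F", "M")) {
      for (nm in names(over)) cfg$cells[[hab]][[sex]][[nm]] <- over[[nm]]
    }
  }
  validate_generator_config(cfg)
  cfg
}

# config whose individuals never take off within the observation window
never_fly_config <- function(n_individuals = 5) {
  config_with(interflight_dur_logmu = log(1e9), interflight_dur_logsigma = 0,
              n_individuals = n_individuals)
}

# deterministic straight walker: constant speed 1 m/s, 15-s flights,
# ~instantaneous inter-flights, no turning
straight_walker_config <- function(n_individuals = 3) {
  config_with(flight_dur_logmu = log(15), flight_dur_logsigma = 0,
              interflight_dur_logmu = log(1e-9), interflight_dur_logsigma = 0,
              speed_logmu = log(1), speed_logsigma = 0,
              turn_kappa = 1e6,
              n_individuals = n_individuals)
}

# hand-built track from flag coordinates
toy_track <- function(x, y, t, landed = NULL, ...) {
  if (is.null(landed)) landed <- rep(1L, length(x))
  track(individual_id = "toy", sex = "F", habitat = "rich",
        flags = data.frame(x_m = x, y_m = y, t_s = t, landed = landed),
        obs_duration_s = max(t), ...)
}

# sup-distance between the ECDFs of two samples
ks_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}
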