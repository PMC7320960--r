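#' Root mean squared error
#'
#' Average observed-vs-predicted mismatch in the original units (metres for
#' displacement means): `sqrt(mean((observed - predicted)^2))`.
#'
#' @param observed,predicted equal-length aligned numeric vectors (for the
#'   model validation: the four sex x habitat cell means).
#' @return non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  sqrt(mean((observed - predicted)^2))
}

#' Pearson moment kurtosis
#'
#' `m4 / m2^2` with population (biased) central moments.  Equals 3 for a
#' normal distribution; values above 3 mark leptokurtic ("fat-tailed")
#' dispersal kernels, in which far-moving individuals contribute
#' disproportionately.  Bounded below by 1 for any sample.
#'
#' @param values numeric vector, n >= 4, with positive variance.
#' @return unitless scalar >= 1.
#' @export
kurtosis <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) stop("kurtosis() needs n >= 4")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("kurtosis() undefined for zero variance")
  mean((values - m)^4) / m2^2
}

#' Large-sample 95% confidence half-width for kurtosis
#'
#' Under normal-theory large-sample results the variance of the sample
#' kurtosis is 24/n, giving a 95% half-width of `1.96 * sqrt(24/n)` — 0.14 at
#' n = 5000.
#'
#' @param n sample size.
#' @return half-width (unitless).
#' @export
kurtosis_ci_halfwidth <- function(n) {
  stopifnot(n > 0)
  1.96 * sqrt(24 / n)
}

#' Validate model variants against observed short-term displacement
#'
#' For each model variant, simulates the field observation window
#' ([simulate_observation()]) in homogeneous rich and poor habitat for both
#' sexes, and compares the predicted mean net displacements with the observed
#' sex x habitat group means from the tracks.  The result is one RMSE per
#' variant (in metres, over the four cells); with habitat-dependent activity
#' and movement in the data, RMSE should fall from variant I (pooled) to
#' variant IV (fully habitat specific).
#'
#' Observation spans: field observations are truncated at the flag quota as
#' well as at the 10-min clock, so fast individuals are observed for well
#' under 600 s.  To compare like with like, each cell is simulated for that
#' cell's mean observed observation span (the default); pass a fixed
#' `duration_s` to override.
#'
#' @param tracks list of [track()] objects with bout information.
#' @param variants variant labels to evaluate (default all four).
#' @param n_obs simulated observations per sex x habitat cell.
#' @param duration_s observation span in seconds; `NULL` (default) matches
#'   each cell's mean observed span.
#' @param k step-sampler neighbourhood size passed to [build_parameter_set()].
#' @param seed optional integer root seed; each variant x cell run gets a
#'   seed derived from it.
#' @return data.frame with columns `variant` and `rmse_m`; the per-cell
#'   observed and predicted means are attached as attribute `"cells"`.
#' @export
model_comparison <- function(tracks, variants = c("I", "II", "III", "IV"),
                             n_obs = 1000, duration_s = NULL, k = 20,
                             seed = NULL) {
  params <- merge_parameter_sets(build_parameter_set(tracks, FALSE, k = k),
                                 build_parameter_set(tracks, TRUE, k = k))
  gm <- group_means(summarise_tracks(tracks))
  cells <- list()
  out <- data.frame(variant = character(), rmse_m = numeric(),
                    stringsAsFactors = FALSE)
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    obs <- numeric(0); pred <- numeric(0)
    for (sex in c("F", "M")) {
      for (hab in c("rich", "poor")) {
        o <- gm$net_displacement_m[gm$sex == sex & gm$habitat == hab]
        cell_dur <- duration_s %||%
          gm$observation_duration_s[gm$sex == sex & gm$habitat == hab]
        run_seed <- if (is.null(seed)) NULL else seed + 101L * vi +
          13L * (sex == "M") + 7L * (hab == "poor")
        p <- mean(simulate_observation(params, v, hab, duration_s = cell_dur,
                                       n_agents = n_obs, sex = sex,
                                       seed = run_seed))
        obs <- c(obs, o); pred <- c(pred, p)
        cells[[length(cells) + 1]] <- data.frame(
          variant = v, sex = sex, habitat = hab,
          observed_m = o, predicted_m = p, stringsAsFactors = FALSE)
      }
    }
    out <- rbind(out, data.frame(variant = v, rmse_m = rmse(obs, pred),
                                 stringsAsFactors = FALSE))
  }
  attr(out, "cells") <- do.call(rbind, cells)
  out
}

#' Dispersal-kernel summaries across a landscape sweep
#'
#' Runs [run_simulation()] for every combination of model variant, rich-cell
#' proportion `p_rich`, Hurst parameter and sex, and summarises each
#' displacement sample by its mean, Pearson kurtosis and the large-sample
#' kurtosis confidence half-width.
#'
#' Seed schedule (documented so sweeps are reproducible and comparable):
#' the fractal surface seed depends on (`seed`, H) only, so the rich-cell
#' sets are nested across `p_rich` by quantile thresholding; the simulation
#' stream seed depends on (`seed`, variant, H, sex) but *not* on `p_rich`,
#' i.e. common random numbers across the proportion grid, which removes
#' sampling noise from the p-response of each variant.
#'
#' @param params a [movement_parameter_set()] with the keys the variants need.
#' @param variants variant labels (default I, III, IV as in the kernel
#'   forecasts).
#' @param p_rich grid of rich-cell proportions.
#' @param hurst Hurst parameter(s).
#' @param sexes sexes to simulate (default female, the headline kernel).
#' @param n_agents,days,active_hours_per_day,burn_in_hours passed to
#'   [run_simulation()]; defaults are the full-scale run (5000 agents,
#'   5 days x 8 h after an 8-h burn-in).
#' @param n_cells landscape grid side (2^k + 1).
#' @param seed integer root seed for the schedule above.
#' @return data.frame with one row per variant x sex x hurst x p_rich:
#'   `n`, `mean_displacement_m`, `kurtosis`, `kurtosis_ci_halfwidth`.
#' @export
landscape_sweep <- function(params, variants = c("I", "III", "IV"),
                            p_rich = seq(0.1, 0.9, by = 0.1),
                            hurst = 0.5, sexes = "F",
                            n_agents = 5000, days = 5,
                            active_hours_per_day = 8, burn_in_hours = 8,
                            n_cells = 257, seed = 1) {
  rows <- list()
  for (hi in seq_along(hurst)) {
    H <- hurst[hi]
    land_seed <- seed + 101L * hi
    for (vi in seq_along(variants)) {
      v <- variants[[vi]]
      for (si in seq_along(sexes)) {
        sex <- sexes[[si]]
        sim_seed <- seed + 1009L * vi + 97L * hi + 17L * si
        for (p in p_rich) {
          land <- fractal_landscape(n_cells = n_cells, hurst = H, p_rich = p,
                                    seed = land_seed)
          disp <- run_simulation(params, v, sex, landscape = land,
                                 n_agents = n_agents, days = days,
                                 active_hours_per_day = active_hours_per_day,
                                 burn_in_hours = burn_in_hours,
                                 seed = sim_seed)
          rows[[length(rows) + 1]] <- data.frame(
            variant = v, sex = sex, hurst = H, p_rich = p,
            n = length(disp),
            mean_displacement_m = mean(disp),
            kurtosis = kurtosis(disp),
            kurtosis_ci_halfwidth = kurtosis_ci_halfwidth(length(disp)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
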