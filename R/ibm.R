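#' Model parameterization variant
#'
#' The four variants cross habitat-specific *activity* (flight and
#' inter-flight durations) with habitat-specific *movement rate* (step
#' lengths and turning angles): variant I uses pooled parameters for both,
#' II makes activity habitat specific, III movement, and IV both.
#'
#' @param x `"I"`, `"II"`, `"III"`, `"IV"`, or a logical vector
#'   `c(activity_habitat_specific, movement_habitat_specific)`.
#' @return An object of class `model_variant` with logical fields
#'   `activity_habitat_specific` and `movement_habitat_specific`.
#' @export
model_variant <- function(x) {
  if (inherits(x, "model_variant")) return(x)
  if (is.character(x)) {
    x <- match.arg(x, c("I", "II", "III", "IV"))
    flags <- switch(x,
                    I = c(FALSE, FALSE), II = c(TRUE, FALSE),
                    III = c(FALSE, TRUE), IV = c(TRUE, TRUE))
  } else {
    stopifnot(is.logical(x), length(x) == 2L, !anyNA(x))
    flags <- x
  }
  structure(list(activity_habitat_specific = flags[1],
                 movement_habitat_specific = flags[2]),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant> %s (activity %s, movement %s)\n",
              variant_label(x),
              if (x$activity_habitat_specific) "habitat-specific" else "pooled",
              if (x$movement_habitat_specific) "habitat-specific" else "pooled"))
  invisible(x)
}

variant_label <- function(v) {
  idx <- 1 + v$activity_habitat_specific + 2 * v$movement_habitat_specific
  c("I", "II", "III", "IV")[idx]
}

# resolve a parameter set to per-habitat-class component lists for the C++
# core: element 1 = poor, element 2 = rich; pooled components are duplicated
resolve_params <- function(params, variant, sex) {
  stopifnot(inherits(params, "movement_parameter_set"))
  variant <- model_variant(variant)
  sets <- params$sets[[sex]]
  if (is.null(sets)) stop("parameter set has no entry for sex ", sex)
  pick <- function(specific) {
    need <- if (specific) c("poor", "rich") else c("pooled", "pooled")
    missing <- setdiff(unique(need), names(sets))
    if (length(missing) > 0L) {
      stop("parameter set for sex ", sex, " lacks key(s) ",
           paste(missing, collapse = ", "), " required by variant ",
           variant_label(variant))
    }
    lapply(need, function(k) sets[[k]])
  }
  act <- pick(variant$activity_habitat_specific)
  mov <- pick(variant$movement_habitat_specific)
  list(flight = lapply(act, function(s) s$flight$sorted),
       interflight = lapply(act, function(s) s$interflight$sorted),
       step_dur = lapply(mov, function(s) s$steps$durations_s),
       step_len = lapply(mov, function(s) s$steps$steps_m),
       turn_mu = vapply(mov, function(s) s$turn$mu, numeric(1)),
       turn_kappa = vapply(mov, function(s) s$turn$kappa, numeric(1)),
       k = max(vapply(mov, function(s) s$steps$k, numeric(1))))
}

#' Run the dispersal simulation
#'
#' Simulates `n_agents` butterflies of one sex on a fractal landscape (or in
#' homogeneous habitat) for `days` days of `active_hours_per_day` hours of
#' activity each, after a burn-in of `burn_in_hours` of activity that removes
#' the influence of the randomized starting locations: each agent's
#' displacement is measured from its position at the end of the burn-in.
#' Nights are not simulated; the clock counts activity time only.
#'
#' Agents start at uniform-random positions and headings and alternate
#' inter-flight and flight bouts drawn from `params`, keyed by the habitat
#' class at their instantaneous position for whichever components the
#' `variant` makes habitat specific (pooled otherwise).  Coordinates wrap
#' toroidally for habitat lookup but displacements are accumulated unwrapped.
#'
#' @param params a [movement_parameter_set()] containing the keys the variant
#'   needs (`pooled` and/or `rich`+`poor`).
#' @param variant a [model_variant()] or its label.
#' @param sex `"F"` or `"M"`.
#' @param landscape a [fractal_landscape()], or `NULL` with `habitat` set for
#'   a homogeneous-habitat run.
#' @param n_agents number of simulated butterflies.
#' @param days days of simulated activity.
#' @param active_hours_per_day hours of activity per day (default 8).
#' @param burn_in_hours burn-in activity hours (default 8).
#' @param habitat `"rich"` or `"poor"` for homogeneous runs.
#' @param seed optional integer seed.
#' @return numeric vector of per-agent net displacements (m).
#' @export
run_simulation <- function(params, variant, sex, landscape = NULL,
                           n_agents = 5000, days = 5,
                           active_hours_per_day = 8, burn_in_hours = 8,
                           habitat = NULL, seed = NULL) {
  variant <- model_variant(variant)
  sex <- match.arg(sex, c("F", "M"))
  rp <- resolve_params(params, variant, sex)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(landscape)) {
    stopifnot(inherits(landscape, "landscape"))
    grid <- landscape$grid
    cell <- landscape$cell_size_m
    side <- landscape$side_m
    fixed <- -1L
  } else {
    if (is.null(habitat)) stop("supply a landscape or a homogeneous habitat class")
    habitat <- match.arg(habitat, c("rich", "poor"))
    grid <- NULL
    cell <- 1
    side <- 1
    fixed <- if (habitat == "rich") 1L else 0L
  }
  active_s <- days * active_hours_per_day * 3600
  burnin_s <- burn_in_hours * 3600
  ibm_run_cpp(rp$flight, rp$interflight, rp$step_dur, rp$step_len,
              rp$turn_mu, rp$turn_kappa, as.integer(rp$k),
              grid, cell, side, fixed,
              as.integer(n_agents), active_s, burnin_s)
}

#' Simulate short-term observations in homogeneous habitat
#'
#' Replicates the field observation window in silico: each agent runs for
#' `duration_s` of activity (default the 10-min field window) in uniform
#' habitat with no burn-in, and its net displacement from the start position
#' is returned.  Used to validate the model variants against observed
#' short-term displacement.
#'
#' @param params a [movement_parameter_set()].
#' @param variant a [model_variant()] or its label.
#' @param habitat `"rich"` or `"poor"`.
#' @param duration_s observation span (default 600 s).
#' @param n_agents number of simulated observations.
#' @param sex `"F"` or `"M"`.
#' @param seed optional integer seed.
#' @return numeric vector of per-agent net displacements (m).
#' @export
simulate_observation <- function(params, variant, habitat, duration_s = 600,
                                 n_agents = 1000, sex = "F", seed = NULL) {
  run_simulation(params, variant, sex, landscape = NULL,
                 n_agents = n_agents, days = duration_s / 3600,
                 active_hours_per_day = 1, burn_in_hours = 0,
                 habitat = habitat, seed = seed)
}

#' Advance one agent through its bout sequence (reference implementation)
#'
#' A pure-R, single-agent version of the simulation core that records every
#' event (bout boundaries, turns, segment moves).  It implements the same
#' state machine as the compiled core — inter-flight wait, flight split into
#' 15-s segments with a turn and a duration-conditioned step per segment,
#' post-flight turn — and exists as an independently coded cross-check and as
#' a trace generator for small runs; large simulations use the compiled core.
#'
#' @param params a [movement_parameter_set()].
#' @param variant a [model_variant()] or its label.
#' @param sex `"F"` or `"M"`.
#' @param habitat `"rich"` or `"poor"` (homogeneous), or a
#'   [fractal_landscape()].
#' @param duration_s total activity time to simulate.
#' @param seed optional integer seed.
#' @return list with `displacement_m`, `path` (data.frame `t_s`, `x_m`,
#'   `y_m`, `mode`), and `bouts` (data.frame `mode`, `start_s`, `end_s`).
#' @export
simulate_agent <- function(params, variant, sex, habitat, duration_s,
                           seed = NULL) {
  variant <- model_variant(variant)
  rp <- resolve_params(params, variant, sex)
  if (!is.null(seed)) set.seed(seed)
  land <- NULL
  if (inherits(habitat, "landscape")) {
    land <- habitat
  } else {
    habitat <- match.arg(habitat, c("rich", "poor"))
  }
  hab_class <- function(x, y) {
    if (is.null(land)) {
      if (habitat == "rich") 2L else 1L
    } else {
      if (habitat_at(land, x, y) == "rich") 2L else 1L
    }
  }
  seg_cadence <- 15
  x <- 0; y <- 0
  if (!is.null(land)) {
    x <- stats::runif(1) * land$side_m
    y <- stats::runif(1) * land$side_m
  }
  heading <- (2 * stats::runif(1) - 1) * pi
  t <- 0
  x0 <- x; y0 <- y
  path <- list(data.frame(t_s = 0, x_m = x, y_m = y, mode = "interflight"))
  bm <- character(); bs <- numeric(); be <- numeric()
  draw_ecdf <- function(sorted) sample_ecdf(fit_ecdf(sorted), stats::runif(1))
  repeat {
    h <- hab_class(x, y)
    d <- draw_ecdf(rp$interflight[[h]])
    bstart <- t
    t <- t + d
    ended <- t >= duration_s
    if (ended) t <- duration_s
    bm <- c(bm, "interflight"); bs <- c(bs, bstart); be <- c(be, t)
    path[[length(path) + 1]] <- data.frame(t_s = t, x_m = x, y_m = y,
                                           mode = "interflight")
    if (ended) break
    h <- hab_class(x, y)
    Tfl <- draw_ecdf(rp$flight[[h]])
    rem <- Tfl
    fstart <- t
    stopped <- FALSE
    while (rem > 1e-12) {
      seg <- min(seg_cadence, rem)
      hm <- hab_class(x, y)
      heading <- wrap_angle(heading + rvonmises(1, rp$turn_mu[hm], rp$turn_kappa[hm]))
      css <- conditional_step_sampler(rp$step_dur[[hm]], rp$step_len[[hm]], rp$k)
      L <- sample_step(css, seg, stats::runif(1))
      v <- if (seg > 0) L / seg else 0
      dt <- seg
      if (t + dt >= duration_s) {
        dt <- duration_s - t
        stopped <- TRUE
      }
      x <- x + v * dt * cos(heading); y <- y + v * dt * sin(heading)
      t <- t + dt
      path[[length(path) + 1]] <- data.frame(t_s = t, x_m = x, y_m = y, mode = "flight")
      if (stopped) break
      rem <- rem - seg
    }
    bm <- c(bm, "flight"); bs <- c(bs, fstart); be <- c(be, t)
    if (stopped || t >= duration_s) break
    hp <- hab_class(x, y)
    heading <- wrap_angle(heading + rvonmises(1, rp$turn_mu[hp], rp$turn_kappa[hp]))
  }
  list(displacement_m = sqrt((x - x0)^2 + (y - y0)^2),
       path = do.call(rbind, path),
       bouts = data.frame(mode = bm, start_s = bs, end_s = be,
                          stringsAsFactors = FALSE))
}
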