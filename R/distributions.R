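#' Empirical-CDF inverse-transform sampler
#'
#' Stores a sorted sample and samples new values by linear interpolation of
#' the inverse empirical cumulative distribution function: `sample_ecdf(s, 0)`
#' returns the sample minimum, `sample_ecdf(s, 1)` the maximum, and the map is
#' monotone non-decreasing in `u`.  Output is bounded by the observed range —
#' no tail extrapolation.
#'
#' @param samples numeric vector, length >= 2, finite and >= 0.
#' @return An object of class `ecdf_sampler`.
#' @export
fit_ecdf <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("fit_ecdf() needs at least 2 samples, got ", length(samples))
  }
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("fit_ecdf() samples must be finite and >= 0")
  }
  structure(list(sorted = sort(samples)), class = "ecdf_sampler")
}

#' @export
print.ecdf_sampler <- function(x, ...) {
  cat(sprintf("<ecdf_sampler> n = %d, range [%.4g, %.4g], median %.4g\n",
              length(x$sorted), x$sorted[1], x$sorted[length(x$sorted)],
              stats::median(x$sorted)))
  invisible(x)
}

#' Draw from an empirical sampler by inverse-CDF interpolation
#'
#' @param sampler an [fit_ecdf()] object.
#' @param u probabilities in \[0, 1\] (vectorized); supply `runif(n)` for
#'   random draws.
#' @return numeric vector of sampled values.
#' @export
sample_ecdf <- function(sampler, u) {
  stopifnot(inherits(sampler, "ecdf_sampler"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  y <- sampler$sorted
  n <- length(y)
  pos <- u * (n - 1)
  i <- pmin(floor(pos), n - 2)
  frac <- pos - i
  y[i + 1] + frac * (y[i + 2] - y[i + 1])
}

#' Duration-conditioned step-length sampler
#'
#' Holds paired observations (flight or segment duration, step length).  A
#' query duration selects the `k` pairs with nearest durations (ties broken
#' towards the smaller duration, then input order) and draws uniformly among
#' their step lengths — the empirical marginal distribution of step lengths
#' "for flights of that duration", pooled over a k-nearest neighbourhood so
#' sparse durations never yield an empty bin.
#'
#' @param durations_s numeric vector of durations (s), >= 0.
#' @param steps_m numeric vector of step lengths (m), >= 0, same length.
#' @param k neighbourhood size (default 20, capped at the number of pairs).
#' @return An object of class `conditional_step_sampler`.
#' @export
conditional_step_sampler <- function(durations_s, steps_m, k = 20) {
  durations_s <- as.numeric(durations_s)
  steps_m <- as.numeric(steps_m)
  if (length(durations_s) != length(steps_m) || length(durations_s) < 1L) {
    stop("need >= 1 (duration, step) pair with equal lengths")
  }
  if (any(!is.finite(durations_s)) || any(!is.finite(steps_m)) ||
      any(durations_s < 0) || any(steps_m < 0)) {
    stop("durations and step lengths must be finite and >= 0")
  }
  k <- min(as.integer(k), length(durations_s))
  if (k < 1L) stop("k must be >= 1")
  ord <- order(durations_s)  # stable: equal durations keep input order
  structure(list(durations_s = durations_s[ord], steps_m = steps_m[ord], k = k),
            class = "conditional_step_sampler")
}

#' @export
print.conditional_step_sampler <- function(x, ...) {
  cat(sprintf("<conditional_step_sampler> %d pairs, k = %d, durations [%.3g, %.3g] s\n",
              length(x$durations_s), x$k, x$durations_s[1],
              x$durations_s[length(x$durations_s)]))
  invisible(x)
}

#' Draw a step length conditioned on a flight duration
#'
#' @param css a [conditional_step_sampler()].
#' @param flight_duration_s query duration in seconds.
#' @param u a probability in \[0, 1\] selecting uniformly among the k
#'   neighbouring step lengths.
#' @return step length in metres.
#' @export
sample_step <- function(css, flight_duration_s, u) {
  stopifnot(inherits(css, "conditional_step_sampler"),
            length(flight_duration_s) == 1L, u >= 0, u <= 1)
  dur <- css$durations_s
  n <- length(dur)
  k <- css$k
  lo <- findInterval(flight_duration_s, dur)  # last index <= query
  l <- lo; r <- lo + 1L
  for (i in seq_len(k)) {
    if (l < 1L) r <- r + 1L
    else if (r > n) l <- l - 1L
    else if (flight_duration_s - dur[l] <= dur[r] - flight_duration_s) l <- l - 1L
    else r <- r + 1L
  }
  window <- css$steps_m[(l + 1L):(r - 1L)]
  j <- min(floor(u * k), k - 1)
  window[j + 1]
}

#' Sex- and habitat-keyed movement parameter set
#'
#' Bundles, per sex and habitat key, the four components the individual-based
#' model draws from: a flight-duration sampler, an inter-flight-duration
#' sampler, a duration-conditioned step-length sampler, and a von Mises
#' turning-angle model.  Keys are `rich`/`poor` for habitat-specific fits and
#' `pooled` for fits to the concatenated raw observations of both habitats.
#'
#' @param sets nested list `sets[[sex]][[key]]`, each element a list with
#'   components `flight` ([fit_ecdf()]), `interflight` ([fit_ecdf()]),
#'   `steps` ([conditional_step_sampler()]) and `turn` ([turn_model()]).
#' @return An object of class `movement_parameter_set`.
#' @export
movement_parameter_set <- function(sets) {
  for (sex in names(sets)) {
    for (key in names(sets[[sex]])) {
      comp <- sets[[sex]][[key]]
      if (!inherits(comp$flight, "ecdf_sampler") ||
          !inherits(comp$interflight, "ecdf_sampler") ||
          !inherits(comp$steps, "conditional_step_sampler") ||
          !inherits(comp$turn, "turn_model")) {
        stop("parameter set ", sex, "/", key,
             ": needs flight, interflight, steps, turn components")
      }
      if (max(comp$flight$sorted) <= 0) {
        stop("parameter set ", sex, "/", key,
             ": flight-duration sample must contain positive durations")
      }
    }
  }
  structure(list(sets = sets), class = "movement_parameter_set")
}

#' @export
print.movement_parameter_set <- function(x, ...) {
  cat("<movement_parameter_set>\n")
  for (sex in names(x$sets)) for (key in names(x$sets[[sex]])) {
    comp <- x$sets[[sex]][[key]]
    cat(sprintf("  %s/%-6s: %4d flights, %4d inter-flights, %4d step pairs, kappa %.2f\n",
                sex, key, length(comp$flight$sorted),
                length(comp$interflight$sorted),
                length(comp$steps$durations_s), comp$turn$kappa))
  }
  invisible(x)
}

# (duration, step length) pairs for the fully observed flights of a track:
# flights spanning a single flag interval give one landing-to-landing pair;
# longer flights give one pair per airborne segment (15 s each, plus the
# final remainder at its actual duration)
step_pairs <- function(track) {
  b <- track$bouts
  if (is.null(b)) stop("track ", track$individual_id, " has no bout information")
  f <- track$flags
  durs <- numeric(0); lens <- numeric(0)
  fl <- b[b$mode == "flight" & b$complete, , drop = FALSE]
  for (i in seq_len(nrow(fl))) {
    s <- fl$start_s[i]; e <- fl$end_s[i]
    idx <- which(f$t_s > s + 1e-9 & f$t_s <= e + 1e-9)
    prev <- which(f$t_s <= s + 1e-9)
    if (length(prev) == 0L || length(idx) == 0L) next
    prev <- max(prev)
    xs <- c(f$x_m[prev], f$x_m[idx]); ys <- c(f$y_m[prev], f$y_m[idx])
    ts <- c(s, f$t_s[idx])
    durs <- c(durs, diff(ts))
    lens <- c(lens, sqrt(diff(xs)^2 + diff(ys)^2))
  }
  list(durations_s = durs, steps_m = lens)
}

#' Build a movement parameter set from tracks
#'
#' Fits, per sex (always separately) and either per habitat or pooled across
#' habitats, the four IBM input components from the raw observations of a
#' track collection: empirical-CDF samplers for flight and inter-flight
#' durations, the duration-conditioned step-length sampler from per-segment
#' (duration, length) pairs, and a von Mises model of turning angles.  The
#' pooled fit uses the concatenated raw observations of both habitats.
#'
#' @param tracks list of [track()] objects with bout information.
#' @param habitat_specific logical: fit per habitat (`rich`, `poor` keys) or
#'   pooled (`pooled` key)?
#' @param k step-sampler neighbourhood size (default 20).
#' @return A [movement_parameter_set()].
#' @export
build_parameter_set <- function(tracks, habitat_specific, k = 20) {
  stopifnot(is.logical(habitat_specific), length(habitat_specific) == 1L)
  keys <- if (habitat_specific) c("rich", "poor") else "pooled"
  sets <- list()
  for (sex in c("F", "M")) {
    for (key in keys) {
      sel <- Filter(function(tr) {
        tr$sex == sex && (key == "pooled" || tr$habitat == key)
      }, tracks)
      if (length(sel) == 0L) {
        stop("no tracks for sex ", sex, ", key ", key)
      }
      bd <- lapply(sel, bout_durations)
      flight <- unlist(lapply(bd, `[[`, "flight_durations_s"))
      inter <- unlist(lapply(bd, `[[`, "interflight_durations_s"))
      pairs <- lapply(sel, step_pairs)
      durs <- unlist(lapply(pairs, `[[`, "durations_s"))
      lens <- unlist(lapply(pairs, `[[`, "steps_m"))
      angles <- unlist(lapply(sel, function(tr) {
        if (nrow(tr$flags) >= 3L) turning_angles(tr) else numeric(0)
      }))
      sets[[sex]][[key]] <- list(
        flight = fit_ecdf(flight),
        interflight = fit_ecdf(inter),
        steps = conditional_step_sampler(durs, lens, k),
        turn = fit_vonmises(angles))
    }
  }
  movement_parameter_set(sets)
}

#' Merge movement parameter sets
#'
#' Combines the keys of several parameter sets (e.g. a pooled and a
#' habitat-specific fit) into one set so that mixed model variants (activity
#' habitat-specific but movement pooled, or vice versa) can look up both.
#'
#' @param ... [movement_parameter_set()] objects.
#' @return A [movement_parameter_set()] containing all keys.
#' @export
merge_parameter_sets <- function(...) {
  inputs <- list(...)
  sets <- list()
  for (ps in inputs) {
    stopifnot(inherits(ps, "movement_parameter_set"))
    for (sex in names(ps$sets)) {
      for (key in names(ps$sets[[sex]])) {
        sets[[sex]][[key]] <- ps$sets[[sex]][[key]]
      }
    }
  }
  movement_parameter_set(sets)
}

#' Serialize / deserialize a movement parameter set as JSON
#'
#' Raw sample arrays and von Mises parameters are written to a single JSON
#' file so simulation runs are reproducible without refitting.
#'
#' @param params a [movement_parameter_set()].
#' @param path JSON file path.
#' @return `write_parameter_set` returns `path` invisibly;
#'   `read_parameter_set` returns the reconstructed set.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "movement_parameter_set"))
  out <- lapply(params$sets, function(by_key) {
    lapply(by_key, function(comp) {
      list(flight = comp$flight$sorted,
           interflight = comp$interflight$sorted,
           step_durations_s = comp$steps$durations_s,
           step_lengths_m = comp$steps$steps_m,
           k = comp$steps$k,
           turn = list(mu = comp$turn$mu, kappa = comp$turn$kappa))
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(raw, function(by_key) {
    lapply(by_key, function(comp) {
      list(flight = fit_ecdf(comp$flight),
           interflight = fit_ecdf(comp$interflight),
           steps = conditional_step_sampler(comp$step_durations_s,
                                            comp$step_lengths_m, comp$k),
           turn = turn_model(comp$turn$mu, comp$turn$kappa))
    })
  })
  movement_parameter_set(sets)
}
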