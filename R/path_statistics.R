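#' Step speeds of a track
#'
#' Step speed is (Euclidean distance between successive flags) / (time
#' between them), for every consecutive flag pair whose later flag was
#' reached by flying.  Flags are only emitted at landings and at airborne
#' marks, so every flag after the first qualifies; the initial flag marks the
#' observation start.  Time between flags may include stationary time when a
#' step brackets a landing-plus-inter-flight interval: the statistic is the
#' literal flag-to-flag speed of the field protocol.
#'
#' @param track a [track()] with >= 2 flags.
#' @return numeric vector of speeds (m/s), one per qualifying flag pair.
#' @export
step_speeds <- function(track) {
  stopifnot(inherits(track, "track"))
  f <- track$flags
  if (nrow(f) < 2L) stop("step_speeds() needs at least 2 flags")
  dt <- diff(f$t_s)
  if (any(dt == 0)) stop("corrupt track: zero time between flags")
  sqrt(diff(f$x_m)^2 + diff(f$y_m)^2) / dt
}

#' Turning angles of a track
#'
#' The signed angle in (-pi, pi] subtended between successive step vectors
#' (flag-to-flag displacement vectors).  Zero-length steps are skipped: the
#' angle is computed between the surviving non-degenerate steps.
#'
#' @param track a [track()] with >= 3 flags.
#' @return numeric vector of angles in radians.
#' @export
turning_angles <- function(track) {
  stopifnot(inherits(track, "track"))
  f <- track$flags
  if (nrow(f) < 3L) stop("turning_angles() needs at least 3 flags")
  dx <- diff(f$x_m); dy <- diff(f$y_m)
  len <- sqrt(dx^2 + dy^2)
  keep <- len > 1e-12
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) < 2L) return(numeric(0))
  h <- atan2(dy, dx)
  wrap_angle(diff(h))
}

#' Flight and inter-flight bout durations
#'
#' Partitions the observation into alternating flight and inter-flight bouts
#' and returns their durations.  Only fully observed bouts enter the samples:
#' flight bouts truncated by the observation end are dropped, and
#' inter-flight durations are the stationary intervals strictly *between* two
#' flights (the lead-in before the first flight and any trailing stationary
#' time are excluded), matching the field definitions.
#'
#' Bout boundaries come from the track's bout log (generator bookkeeping, or
#' reconstructed from a behaviour log's flying intervals by [read_tracks()]);
#' flag positions alone cannot locate flight take-offs.
#'
#' @param track a [track()] carrying bout information.
#' @return list with components `flight_durations_s` and
#'   `interflight_durations_s`.
#' @export
bout_durations <- function(track) {
  stopifnot(inherits(track, "track"))
  b <- track$bouts
  if (is.null(b)) {
    stop("track ", track$individual_id, " has no bout information; ",
         "attach a behaviour log (flying intervals) to recover bouts")
  }
  dur <- b$end_s - b$start_s
  if (any(dur < -1e-9)) stop("corrupt bouts: negative duration")
  is_fl <- b$mode == "flight"
  flight <- dur[is_fl & b$complete]
  # inter-flight bouts flanked by flights on both sides
  idx <- which(!is_fl)
  interior <- idx[idx > 1L & idx < nrow(b)]
  inter <- dur[interior]
  list(flight_durations_s = as.numeric(flight),
       interflight_durations_s = as.numeric(inter))
}

#' Net displacement of a track
#'
#' Euclidean distance between the start and end locations of the observation.
#'
#' @param track a [track()].
#' @return displacement in metres (0 for a single-flag track).
#' @export
net_displacement <- function(track) {
  stopifnot(inherits(track, "track"))
  f <- track$flags
  n <- nrow(f)
  sqrt((f$x_m[n] - f$x_m[1])^2 + (f$y_m[n] - f$y_m[1])^2)
}

#' Behavioural time budget
#'
#' Fraction of the observation spent in each behaviour category (flying,
#' nectaring, basking, inactive, ovipositing), from a behaviour log whose
#' intervals tile the observation.
#'
#' @param x a [track()] with a behaviour log attached, or a behaviour
#'   data.frame with columns `behaviour`, `start_s`, `end_s`.
#' @return named numeric vector of fractions summing to 1.
#' @export
time_budget <- function(x) {
  beh <- if (inherits(x, "track")) x$behaviour else x
  if (is.null(beh) || nrow(beh) == 0L) stop("no behaviour intervals available")
  cats <- c("flying", behaviour_categories)
  dur <- beh$end_s - beh$start_s
  tot <- sum(dur)
  out <- vapply(cats, function(cc) sum(dur[beh$behaviour == cc]), numeric(1))
  out / tot
}

#' Per-individual path summaries
#'
#' One row per track with the five movement statistics averaged over the
#' observation (the individual is the statistical unit) plus, when behaviour
#' logs are present, the time-budget fractions.  Metrics with no contributing
#' components (e.g. flight-duration mean of an individual that never flew)
#' are `NA`, not zero, and are excluded from group means.
#'
#' @param tracks list of [track()] objects.
#' @return data.frame with columns `individual_id`, `sex`, `habitat`,
#'   `n_flags`, `observation_duration_s`, `mean_step_speed`,
#'   `mean_flight_duration_s`, `mean_interflight_duration_s`,
#'   `mean_abs_turning_angle`, `net_displacement_m`, and `frac_*` columns
#'   when behaviour logs are attached.
#' @export
summarise_tracks <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    sp <- if (nrow(tr$flags) >= 2L) step_speeds(tr) else numeric(0)
    ta <- if (nrow(tr$flags) >= 3L) turning_angles(tr) else numeric(0)
    bd <- if (!is.null(tr$bouts)) bout_durations(tr) else
      list(flight_durations_s = numeric(0), interflight_durations_s = numeric(0))
    mean_or_na <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
    row <- data.frame(
      individual_id = tr$individual_id, sex = tr$sex, habitat = tr$habitat,
      n_flags = nrow(tr$flags),
      observation_duration_s = tr$obs_duration_s,
      mean_step_speed = mean_or_na(sp),
      mean_flight_duration_s = mean_or_na(bd$flight_durations_s),
      mean_interflight_duration_s = mean_or_na(bd$interflight_durations_s),
      mean_abs_turning_angle = mean_or_na(abs(ta)),
      net_displacement_m = net_displacement(tr),
      stringsAsFactors = FALSE)
    if (!is.null(tr$behaviour) && nrow(tr$behaviour) > 0L) {
      tb <- time_budget(tr)
      for (nm in names(tb)) row[[paste0("frac_", nm)]] <- tb[[nm]]
    }
    row
  })
  # tracks with behaviour and without may mix; fill missing columns with NA
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA_real_
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means of path summaries by sex and habitat
#'
#' @param summaries output of [summarise_tracks()].
#' @return data.frame with one row per sex x habitat cell: `n` individuals
#'   and the mean of every numeric metric (`NA` components excluded).
#' @export
group_means <- function(summaries) {
  num <- setdiff(names(summaries)[vapply(summaries, is.numeric, logical(1))],
                 c("n_flags"))
  key <- interaction(summaries$sex, summaries$habitat, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- summaries[key == k, , drop = FALSE]
    row <- data.frame(sex = sub$sex[1], habitat = sub$habitat[1],
                      n = nrow(sub), stringsAsFactors = FALSE)
    for (nm in num) row[[nm]] <- mean(sub[[nm]], na.rm = TRUE)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sex, out$habitat), , drop = FALSE]
  rownames(out) <- NULL
  out
}
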