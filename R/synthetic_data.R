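#' Construct a track object
#'
#' A track is one followed individual: an ordered set of flags (position,
#' time, landed marker), the sex and habitat of the observation, and
#' optionally the bout partition (flight / inter-flight intervals) and a
#' behaviour log.  Flags are recorded at every landing and every
#' `flag_interval_s` of continuous flight, as in flag-based field protocols.
#'
#' @param individual_id character scalar.
#' @param sex "F" or "M".
#' @param habitat "rich" or "poor".
#' @param flags data.frame with columns `x_m`, `y_m`, `t_s`, `landed` (0/1),
#'   times strictly increasing, coordinates finite, >= 1 row.
#' @param obs_duration_s observation span in seconds (>= last flag time).
#' @param bouts optional data.frame `mode` ("flight"/"interflight"),
#'   `start_s`, `end_s`, `complete` tiling `[0, obs_duration_s]`.
#' @param behaviour optional data.frame `behaviour`, `start_s`, `end_s`.
#' @param cell_params optional list of generator parameters (bookkeeping).
#' @return An object of class `track`.
#' @export
track <- function(individual_id, sex, habitat, flags, obs_duration_s,
                  bouts = NULL, behaviour = NULL, cell_params = NULL) {
  stopifnot(is.data.frame(flags), nrow(flags) >= 1L,
            all(c("x_m", "y_m", "t_s", "landed") %in% names(flags)))
  if (any(!is.finite(flags$x_m)) || any(!is.finite(flags$y_m))) {
    stop("track ", individual_id, ": flag coordinates must be finite")
  }
  if (nrow(flags) > 1L && any(diff(flags$t_s) <= 0)) {
    stop("track ", individual_id, ": flag times must be strictly increasing")
  }
  if (obs_duration_s < max(flags$t_s) - 1e-9) {
    stop("track ", individual_id, ": obs_duration_s earlier than last flag")
  }
  sex <- match.arg(sex, c("F", "M"))
  habitat <- match.arg(habitat, c("rich", "poor"))
  structure(list(individual_id = as.character(individual_id),
                 sex = sex, habitat = habitat,
                 flags = flags, obs_duration_s = as.numeric(obs_duration_s),
                 bouts = bouts, behaviour = behaviour,
                 cell_params = cell_params),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %s (%s, %s habitat): %d flags over %.1f s\n",
              x$individual_id, x$sex, x$habitat, nrow(x$flags), x$obs_duration_s))
  invisible(x)
}

# simulate one individual; returns a track with bout bookkeeping
simulate_one_track <- function(cell, cfg, id, sex, habitat) {
  max_t <- cfg$max_obs_duration_s
  max_flags <- cfg$max_flags
  fi <- cfg$flag_interval_s
  x <- 0; y <- 0
  heading <- stats::runif(1, -pi, pi)
  t <- 0
  fx <- c(0); fy <- c(0); ft <- c(0); fl <- c(1L)
  bm <- character(); bs <- numeric(); be <- numeric(); bc <- logical()
  obs_end <- max_t
  repeat {
    if (t >= max_t - 1e-12) { obs_end <- max_t; break }
    # inter-flight bout
    d <- stats::rlnorm(1, cell$interflight_dur_logmu, cell$interflight_dur_logsigma)
    if (t + d >= max_t) {
      bm <- c(bm, "interflight"); bs <- c(bs, t); be <- c(be, max_t); bc <- c(bc, FALSE)
      obs_end <- max_t
      break
    }
    bm <- c(bm, "interflight"); bs <- c(bs, t); be <- c(be, t + d); bc <- c(bc, TRUE)
    t <- t + d
    # flight bout
    Tfl <- stats::rlnorm(1, cell$flight_dur_logmu, cell$flight_dur_logsigma)
    v <- stats::rlnorm(1, cell$speed_logmu, cell$speed_logsigma)
    fstart <- t
    rem <- Tfl
    stopped <- FALSE
    while (rem > 1e-12) {
      seg <- min(fi, rem)
      heading <- wrap_angle(heading + rvonmises(1, 0, cell$turn_kappa))
      if (t + seg > max_t) {
        # observation clock runs out mid-segment: no flag at truncation
        dt <- max_t - t
        x <- x + v * dt * cos(heading); y <- y + v * dt * sin(heading)
        bm <- c(bm, "flight"); bs <- c(bs, fstart); be <- c(be, max_t); bc <- c(bc, FALSE)
        t <- max_t; obs_end <- max_t; stopped <- TRUE
        break
      }
      x <- x + v * seg * cos(heading); y <- y + v * seg * sin(heading)
      t <- t + seg
      rem <- rem - seg
      landed <- rem <= 1e-12
      fx <- c(fx, x); fy <- c(fy, y); ft <- c(ft, t); fl <- c(fl, as.integer(landed))
      if (length(ft) >= max_flags) {
        # flag quota reached: observation ends at this flag
        bm <- c(bm, "flight"); bs <- c(bs, fstart); be <- c(be, t); bc <- c(bc, landed)
        obs_end <- t; stopped <- TRUE
        break
      }
      if (landed) {
        bm <- c(bm, "flight"); bs <- c(bs, fstart); be <- c(be, t); bc <- c(bc, TRUE)
        break
      }
    }
    if (stopped) break
  }
  track(individual_id = id, sex = sex, habitat = habitat,
        flags = data.frame(x_m = fx, y_m = fy, t_s = ft, landed = fl),
        obs_duration_s = obs_end,
        bouts = data.frame(mode = bm, start_s = bs, end_s = be, complete = bc,
                           stringsAsFactors = FALSE),
        cell_params = cell)
}

#' Generate synthetic field tracks
#'
#' Simulates flag-based observations of individual butterflies under a
#' [generator_config()].  Each individual alternates inter-flight (stationary)
#' and flight bouts with lognormal durations; during flight it moves at a
#' per-flight lognormal speed, with its heading updated by a von Mises turn at
#' flight start and at every `flag_interval_s` of continuous flight.  A flag
#' is emitted at the observation start, at every landing, and at every
#' `flag_interval_s` airborne mark; the observation ends at
#' `max_obs_duration_s` or at `max_flags` flags, whichever comes first.
#'
#' @param config a [generator_config()].
#' @param seed optional integer seed (overrides `config$rng_seed`).
#' @return A list of [track()] objects (one per individual), ordered by
#'   habitat (rich, poor), sex (F, M), then individual.
#' @export
generate_tracks <- function(config, seed = NULL) {
  validate_generator_config(config)
  seed <- seed %||% config$rng_seed
  if (!is.null(seed)) set.seed(seed)
  tracks <- list()
  for (hab in c("rich", "poor")) {
    for (sex in c("F", "M")) {
      cell <- config$cells[[hab]][[sex]]
      for (i in seq_len(config$n_individuals)) {
        id <- sprintf("%s_%s_%03d", hab, sex, i)
        tracks[[id]] <- simulate_one_track(cell, config, id, sex, hab)
      }
    }
  }
  tracks
}

#' Generate a behaviour log for a track
#'
#' Flight bouts are labelled `flying`; each inter-flight bout is assigned a
#' single non-flight behaviour (nectaring, basking, inactive or ovipositing)
#' drawn with the cell's `behaviour_proportions`.  The returned intervals tile
#' the observation with no gaps or overlaps.
#'
#' @param config the [generator_config()] the track was generated under.
#' @param track a [track()] from [generate_tracks()].
#' @return data.frame with columns `individual_id`, `behaviour`, `start_s`,
#'   `end_s`.
#' @export
generate_behaviour_log <- function(config, track) {
  validate_generator_config(config)
  stopifnot(inherits(track, "track"))
  cell <- config$cells[[track$habitat]][[track$sex]]
  if (!is.null(track$cell_params) &&
      !isTRUE(all.equal(track$cell_params[names(track$cell_params) != "behaviour_proportions"],
                        cell[names(cell) != "behaviour_proportions"], tolerance = 1e-12))) {
    stop("track ", track$individual_id,
         " was not generated under this config (cell parameters differ)")
  }
  if (is.null(track$bouts)) {
    stop("track ", track$individual_id, " carries no bout bookkeeping")
  }
  b <- track$bouts
  if (nrow(b) == 0L) {
    b <- data.frame(mode = "interflight", start_s = 0,
                    end_s = track$obs_duration_s, complete = FALSE)
  }
  probs <- unlist(cell$behaviour_proportions)[behaviour_categories]
  lab <- character(nrow(b))
  lab[b$mode == "flight"] <- "flying"
  n_if <- sum(b$mode == "interflight")
  lab[b$mode == "interflight"] <-
    sample(behaviour_categories, n_if, replace = TRUE, prob = probs)
  data.frame(individual_id = track$individual_id,
             behaviour = lab, start_s = b$start_s, end_s = b$end_s,
             stringsAsFactors = FALSE)
}

#' Generate and attach behaviour logs for a list of tracks
#'
#' @param config the [generator_config()] used for the tracks.
#' @param tracks list of [track()] objects.
#' @param seed optional integer seed.
#' @return The track list with `$behaviour` filled in on every track.
#' @export
generate_behaviour_logs <- function(config, tracks, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(tracks, function(tr) {
    tr$behaviour <- generate_behaviour_log(config, tr)
    tr
  })
}

#' Write / read track tables
#'
#' Tracks are serialized as one CSV row per flag with columns
#' `individual_id`, `sex`, `habitat`, `flag_index`, `x_m`, `y_m`, `t_s`,
#' `landed`; behaviour logs as `individual_id`, `behaviour`, `start_s`,
#' `end_s`.  When a behaviour file is supplied to [read_tracks()], bout
#' partitions are reconstructed from the flying intervals.
#'
#' @param tracks list of [track()] objects.
#' @param path CSV file path.
#' @return `write_tracks`/`write_behaviour` return `path` invisibly;
#'   `read_tracks` returns a list of tracks.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(individual_id = tr$individual_id, sex = tr$sex,
               habitat = tr$habitat,
               flag_index = seq_len(nrow(tr$flags)) - 1L,
               x_m = tr$flags$x_m, y_m = tr$flags$y_m,
               t_s = tr$flags$t_s, landed = tr$flags$landed,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
write_behaviour <- function(tracks, path) {
  logs <- lapply(tracks, function(tr) tr$behaviour)
  logs <- logs[!vapply(logs, is.null, logical(1))]
  if (length(logs) == 0L) stop("no behaviour logs attached to these tracks")
  utils::write.csv(do.call(rbind, logs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param behaviour_path optional behaviour-log CSV matching the tracks.
#' @export
read_tracks <- function(path, behaviour_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  beh <- if (!is.null(behaviour_path)) {
    utils::read.csv(behaviour_path, stringsAsFactors = FALSE)
  }
  out <- list()
  for (id in unique(df$individual_id)) {
    sub <- df[df$individual_id == id, , drop = FALSE]
    sub <- sub[order(sub$flag_index), , drop = FALSE]
    bsub <- if (!is.null(beh)) beh[beh$individual_id == id, , drop = FALSE]
    obs_end <- if (!is.null(bsub) && nrow(bsub) > 0L) max(bsub$end_s) else max(sub$t_s)
    bouts <- if (!is.null(bsub) && nrow(bsub) > 0L) {
      bouts_from_behaviour(bsub, sub, obs_end)
    }
    out[[id]] <- track(individual_id = id, sex = sub$sex[1], habitat = sub$habitat[1],
                       flags = data.frame(x_m = sub$x_m, y_m = sub$y_m,
                                          t_s = sub$t_s, landed = sub$landed),
                       obs_duration_s = obs_end,
                       bouts = bouts,
                       behaviour = bsub)
  }
  out
}

# rebuild the flight/inter-flight bout partition from a behaviour log;
# a flight ending at the observation end is complete only if the last flag
# is a landing at that time (flag-quota stop), otherwise it was cut short
bouts_from_behaviour <- function(beh, flags, obs_end) {
  beh <- beh[order(beh$start_s), , drop = FALSE]
  mode <- ifelse(beh$behaviour == "flying", "flight", "interflight")
  # merge consecutive non-flight intervals into single inter-flight bouts
  keep <- c(TRUE, mode[-1] != mode[-length(mode)])
  grp <- cumsum(keep)
  b <- data.frame(mode = mode[keep],
                  start_s = tapply(beh$start_s, grp, min),
                  end_s = tapply(beh$end_s, grp, max),
                  stringsAsFactors = FALSE)
  last_flag_landing <- flags$landed[nrow(flags)] == 1L &&
    abs(flags$t_s[nrow(flags)] - obs_end) < 1e-9
  b$complete <- b$end_s < obs_end - 1e-9 |
    (b$mode == "flight" & last_flag_landing)
  rownames(b) <- NULL
  b
}
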