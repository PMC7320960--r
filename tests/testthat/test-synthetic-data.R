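test_that("an individual that never takes off yields one flag and zero displacement", {
  cfg <- never_fly_config(n_individuals = 4)
  tracks <- generate_tracks(cfg, seed = 1)
  for (tr in tracks) {
    expect_equal(nrow(tr$flags), 1L)
    expect_equal(net_displacement(tr), 0)
    expect_equal(tr$obs_duration_s, cfg$max_obs_duration_s)
  }
})

test_that("a degenerate straight walker lays flags on a line 15 m apart", {
  cfg <- straight_walker_config(n_individuals = 2)
  tracks <- generate_tracks(cfg, seed = 2)
  for (tr in tracks) {
    f <- tr$flags
    expect_equal(nrow(f), cfg$max_flags)
    steps <- sqrt(diff(f$x_m)^2 + diff(f$y_m)^2)
    expect_equal(steps, rep(15, nrow(f) - 1), tolerance = 1e-6)
    # collinear: all turning angles zero
    expect_equal(turning_angles(tr), rep(0, nrow(f) - 2), tolerance = 1e-9)
    expect_equal(net_displacement(tr), 15 * (nrow(f) - 1), tolerance = 1e-6)
  }
})

test_that("flag bookkeeping invariants hold on default tracks", {
  cfg <- default_generator_config(n_individuals = 10)
  tracks <- generate_tracks(cfg, seed = 3)
  for (tr in tracks) {
    f <- tr$flags
    expect_true(all(diff(f$t_s) > 0))
    expect_true(all(is.finite(c(f$x_m, f$y_m))))
    expect_lte(nrow(f), cfg$max_flags)
    expect_lte(tr$obs_duration_s, cfg$max_obs_duration_s)
    # any flag following an airborne mark arrives within one flag interval
    if (nrow(f) > 1) {
      airborne_prev <- f$landed[-nrow(f)] == 0L
      expect_true(all(diff(f$t_s)[airborne_prev] <= cfg$flag_interval_s + 1e-9))
    }
    # bouts tile the observation exactly
    b <- tr$bouts
    expect_equal(b$start_s[1], 0)
    expect_equal(b$end_s[nrow(b)], tr$obs_duration_s)
    if (nrow(b) > 1) expect_equal(b$start_s[-1], b$end_s[-nrow(b)])
    expect_equal(sum(b$end_s - b$start_s), tr$obs_duration_s)
  }
})

test_that("shipped defaults encode the habitat effect directions", {
  cfg <- default_generator_config()
  for (sex in c("F", "M")) {
    rich <- cfg$cells$rich[[sex]]
    poor <- cfg$cells$poor[[sex]]
    expect_gt(poor$speed_logmu, rich$speed_logmu)
    expect_gt(poor$turn_kappa, rich$turn_kappa)
    expect_gt(poor$flight_dur_logmu, rich$flight_dur_logmu)
    expect_lt(poor$interflight_dur_logmu, rich$interflight_dur_logmu)
  }
})

test_that("sample flight durations are longer in poor habitat for both sexes", {
  cfg <- default_generator_config(n_individuals = 50)  # 200 individuals total
  tracks <- generate_tracks(cfg, seed = 4)
  med_flight <- function(hab, sex) {
    sel <- Filter(function(tr) tr$habitat == hab && tr$sex == sex, tracks)
    stats::median(unlist(lapply(sel, function(tr) bout_durations(tr)$flight_durations_s)))
  }
  expect_gt(med_flight("poor", "F"), med_flight("rich", "F"))
  expect_gt(med_flight("poor", "M"), med_flight("rich", "M"))
})

test_that("behaviour logs tile the observation and respect the proportions", {
  cfg <- config_with(n_individuals = 6)
  tracks <- generate_tracks(cfg, seed = 5)
  tracks <- generate_behaviour_logs(cfg, tracks, seed = 6)
  for (tr in tracks) {
    beh <- tr$behaviour
    expect_equal(beh$start_s[1], 0)
    expect_equal(beh$end_s[nrow(beh)], tr$obs_duration_s)
    if (nrow(beh) > 1) expect_equal(beh$start_s[-1], beh$end_s[-nrow(beh)])
    # flight bouts labelled flying, and conservation of time
    tb <- time_budget(tr)
    expect_equal(sum(tb), 1, tolerance = 1e-9)
    flight_time <- sum(with(tr$bouts, end_s - start_s)[tr$bouts$mode == "flight"])
    expect_equal(tb[["flying"]] * tr$obs_duration_s, flight_time, tolerance = 1e-9)
  }
})

test_that("degenerate behaviour proportions label all non-flight time accordingly", {
  cfg <- config_with(behaviour_proportions = list(nectaring = 1, basking = 0,
                                                  inactive = 0, ovipositing = 0),
                     n_individuals = 3)
  tracks <- generate_tracks(cfg, seed = 7)
  tracks <- generate_behaviour_logs(cfg, tracks, seed = 8)
  for (tr in tracks) {
    nonflight <- tr$behaviour$behaviour[tr$behaviour$behaviour != "flying"]
    expect_true(all(nonflight == "nectaring"))
  }
})

test_that("a zero-flight observation gives a single whole-window interval", {
  cfg <- never_fly_config(n_individuals = 2)
  tracks <- generate_tracks(cfg, seed = 9)
  tracks <- generate_behaviour_logs(cfg, tracks, seed = 10)
  for (tr in tracks) {
    expect_equal(nrow(tr$behaviour), 1L)
    expect_equal(tr$behaviour$start_s, 0)
    expect_equal(tr$behaviour$end_s, cfg$max_obs_duration_s)
    expect_false(tr$behaviour$behaviour == "flying")
  }
})

test_that("males fly a larger fraction of time in poor than in rich habitat", {
  cfg <- default_generator_config(n_individuals = 125)  # 500 tracks in total
  tracks <- generate_tracks(cfg, seed = 11)
  tracks <- generate_behaviour_logs(cfg, tracks, seed = 12)
  frac_fly <- function(hab) {
    sel <- Filter(function(tr) tr$habitat == hab && tr$sex == "M", tracks)
    tot <- sum(vapply(sel, function(tr) tr$obs_duration_s, numeric(1)))
    fly <- sum(vapply(sel, function(tr) time_budget(tr)[["flying"]] * tr$obs_duration_s,
                      numeric(1)))
    fly / tot
  }
  poor <- frac_fly("poor"); rich <- frac_fly("rich")
  expect_gt(poor, rich)
  # calibration targets ~65% / ~45%, checked within Monte-Carlo error
  expect_gt(poor, 0.55); expect_lt(poor, 0.75)
  expect_gt(rich, 0.35); expect_lt(rich, 0.55)
})

test_that("tracks and behaviour logs round-trip through CSV", {
  cfg <- default_generator_config(n_individuals = 3)
  tracks <- generate_tracks(cfg, seed = 13)
  tracks <- generate_behaviour_logs(cfg, tracks, seed = 14)
  tf <- withr::local_tempfile(fileext = ".csv")
  bf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tracks, tf)
  write_behaviour(tracks, bf)
  back <- read_tracks(tf, bf)
  expect_setequal(names(back), names(tracks))
  for (id in names(tracks)) {
    expect_equal(back[[id]]$flags$x_m, tracks[[id]]$flags$x_m, tolerance = 1e-9)
    expect_equal(back[[id]]$sex, tracks[[id]]$sex)
    expect_equal(back[[id]]$habitat, tracks[[id]]$habitat)
    expect_equal(back[[id]]$obs_duration_s, tracks[[id]]$obs_duration_s,
                 tolerance = 1e-9)
    # bout partition reconstructed from the behaviour log matches bookkeeping
    expect_equal(back[[id]]$bouts$mode, tracks[[id]]$bouts$mode)
    expect_equal(back[[id]]$bouts$start_s, tracks[[id]]$bouts$start_s,
                 tolerance = 1e-9)
    expect_equal(back[[id]]$bouts$complete, tracks[[id]]$bouts$complete)
  }
})

test_that("mismatched config is rejected when labelling behaviour", {
  cfg <- default_generator_config(n_individuals = 2)
  tracks <- generate_tracks(cfg, seed = 15)
  other <- config_with(speed_logmu = 3, n_individuals = 2)
  expect_error(generate_behaviour_log(other, tracks[[1]]), "not generated under")
})
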