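test_that("step speed is flag-to-flag distance over time", {
  expect_equal(step_speeds(toy_track(c(0, 3), c(0, 4), c(0, 5))), 1.0)
  expect_equal(step_speeds(toy_track(c(0, 10, 20), c(0, 0, 0), c(0, 10, 20))),
               c(1.0, 1.0))
  expect_error(step_speeds(toy_track(0, 0, 0)), "at least 2 flags")
})

test_that("coincident flag times are rejected as corrupt", {
  tr <- toy_track(c(0, 1), c(0, 0), c(0, 1))
  tr$flags$t_s <- c(0, 0)
  expect_error(step_speeds(tr), "zero time")
})

test_that("turning angles are signed and skip zero-length steps", {
  expect_equal(turning_angles(toy_track(c(0, 1, 1), c(0, 0, 1), 0:2)), pi / 2)
  expect_equal(turning_angles(toy_track(c(0, 1, 1), c(0, 0, -1), 0:2)), -pi / 2)
  # square path closing on itself: three left turns
  sq <- toy_track(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), 0:4)
  expect_equal(turning_angles(sq), rep(pi / 2, 3))
  # a zero-length step in the middle is skipped, leaving one angle between
  # the two surviving collinear steps
  tr <- toy_track(c(0, 1, 1, 2), c(0, 0, 0, 0), 0:3)
  expect_equal(turning_angles(tr), 0)
})

test_that("step speeds and turning angles are invariant under rigid motions", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 8
    x <- cumsum(stats::rnorm(n)); y <- cumsum(stats::rnorm(n))
    t <- seq(0, by = 5, length.out = n)
    tr <- toy_track(x, y, t)
    th <- stats::runif(1, -pi, pi); dx <- stats::rnorm(1, sd = 50); dy <- stats::rnorm(1, sd = 50)
    tr2 <- toy_track(cos(th) * x - sin(th) * y + dx,
                     sin(th) * x + cos(th) * y + dy, t)
    expect_equal(step_speeds(tr2), step_speeds(tr), tolerance = 1e-9)
    expect_equal(turning_angles(tr2), turning_angles(tr), tolerance = 1e-9)
    expect_equal(net_displacement(tr2), net_displacement(tr), tolerance = 1e-9)
  }
})

test_that("net displacement matches Euclidean geometry", {
  expect_equal(net_displacement(toy_track(0, 0, 0)), 0)
  expect_equal(net_displacement(toy_track(c(0, 30), c(0, 40), c(0, 10))), 50)
})

test_that("bout durations partition the observation and match the generator schedule", {
  cfg <- default_generator_config(n_individuals = 8)
  tracks <- generate_tracks(cfg, seed = 21)
  for (tr in tracks) {
    b <- tr$bouts
    expect_equal(sum(b$end_s - b$start_s), tr$obs_duration_s)
    bd <- bout_durations(tr)
    sched_flight <- with(b, (end_s - start_s)[mode == "flight" & complete])
    expect_equal(bd$flight_durations_s, sched_flight)
    expect_true(all(bd$interflight_durations_s >= 0))
  }
})

test_that("a never-flying track contributes one whole-window inter-flight bout", {
  cfg <- never_fly_config(n_individuals = 1)
  tr <- generate_tracks(cfg, seed = 22)[[1]]
  bd <- bout_durations(tr)
  expect_length(bd$flight_durations_s, 0)
  # the single stationary bout is edge-truncated, so no interior inter-flight
  expect_length(bd$interflight_durations_s, 0)
  expect_equal(sum(tr$bouts$end_s - tr$bouts$start_s), cfg$max_obs_duration_s)
})

test_that("bout durations require bout information", {
  tr <- toy_track(c(0, 1), c(0, 0), c(0, 1))
  expect_error(bout_durations(tr), "no bout information")
})

test_that("straight-walker speeds equal the configured speed", {
  cfg <- straight_walker_config(n_individuals = 2)
  tracks <- generate_tracks(cfg, seed = 23)
  for (tr in tracks) {
    expect_equal(step_speeds(tr), rep(1, nrow(tr$flags) - 1), tolerance = 1e-6)
  }
})

test_that("zero-flight individuals are excluded from flight means, not imputed", {
  cfg <- default_generator_config(n_individuals = 6)
  tracks <- generate_tracks(cfg, seed = 24)
  nf <- generate_tracks(never_fly_config(n_individuals = 2), seed = 25)
  names(nf) <- paste0("nf_", names(nf))
  s <- summarise_tracks(c(tracks, nf))
  expect_true(all(is.na(s$mean_flight_duration_s[grepl("^nf_", s$individual_id)])))
  gm_with <- group_means(s)
  gm_without <- group_means(summarise_tracks(tracks))
  for (sex in c("F", "M")) for (hab in c("rich", "poor")) {
    expect_equal(
      gm_with$mean_flight_duration_s[gm_with$sex == sex & gm_with$habitat == hab],
      gm_without$mean_flight_duration_s[gm_without$sex == sex & gm_without$habitat == hab])
  }
})

test_that("group means reproduce the habitat effect direction on defaults", {
  cfg <- default_generator_config(n_individuals = 30)
  tracks <- generate_tracks(cfg, seed = 26)
  gm <- group_means(summarise_tracks(tracks))
  for (sex in c("F", "M")) {
    poor <- gm[gm$sex == sex & gm$habitat == "poor", ]
    rich <- gm[gm$sex == sex & gm$habitat == "rich", ]
    expect_gt(poor$mean_flight_duration_s, rich$mean_flight_duration_s)
    expect_gt(poor$mean_step_speed, rich$mean_step_speed)
    expect_lt(poor$mean_interflight_duration_s, rich$mean_interflight_duration_s)
    expect_gt(poor$net_displacement_m, rich$net_displacement_m)
  }
})
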