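# Track kinematics: hand-computable examples, brute-force oracle
# agreement, closed forms, inclusion-filter semantics, and cohort-level
# properties on simulated tracks.

test_that("step speeds match |dx|/dt", {
  tr <- make_track(c(0, -2.4, -4.8), dt = 3)
  expect_equal(track_step_speeds(tr)$speed_um_s, c(0.8, 0.8))
  expect_equal(track_step_speeds(make_track(rep(5, 6)))$speed_um_s, rep(0, 5))

  withr::with_seed(11, {
    tr <- random_track(50)
    got <- track_step_speeds(tr)$speed_um_s
    expect_equal(got, abs(diff(tr$x_um)) / 3)
  })
})

test_that("non-uniform sampling is rejected, not interpolated", {
  tr <- make_track(c(0, 1, 2, 3))
  tr$t_s[3] <- tr$t_s[3] + 1  # a gap
  expect_error(track_step_speeds(tr), "uniformly sampled",
               class = "motorunit_data_error")
})

test_that("stop detection matches hand cases and the strict-inequality rule", {
  tr <- track_from_speeds(c(0.8, 0.05, 0.05, 0.05, 0.8))
  stops <- detect_stops(tr)
  expect_equal(stops$start_step, 2L)
  expect_equal(stops$n_steps, 3L)

  expect_equal(nrow(detect_stops(track_from_speeds(rep(0.5, 6)))), 0L)
  # two sub-threshold steps are below the minimum stop length
  expect_equal(nrow(detect_stops(track_from_speeds(c(0.5, 0.05, 0.05, 0.5)))), 0L)
  # a step at exactly the threshold is not a stop (strict <)
  expect_equal(nrow(detect_stops(track_from_speeds(rep(0.1, 5)))), 0L)
  expect_error(detect_stops(tr, min_frames = 0), "min_frames",
               class = "motorunit_parameter_error")
})

test_that("stop detection agrees with the brute-force oracle on random tracks", {
  withr::with_seed(21, {
    for (i in 1:300) {
      tr <- random_track(sample(5:200, 1))
      sp <- track_step_speeds(tr)$speed_um_s
      got <- detect_stops(tr)
      want <- oracle_stops(sp)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start_step, want$start_step)
        expect_equal(got$n_steps, want$n_steps)
      }
    }
  })
})

test_that("average velocity is net displacement over elapsed time", {
  tr <- track_from_speeds(rep(0.8, 10))
  expect_equal(average_velocity(tr)$v_avg_um_s, 0.8)
  # out and back to the start
  back <- make_track(c(0, 3, 0), dt = 3)
  expect_equal(average_velocity(back)$v_avg_um_s, 0)
  expect_equal(average_velocity(back, path_length = TRUE)$v_avg_um_s, 1)
  withr::with_seed(31, {
    tr <- random_track(40)
    expect_equal(average_velocity(tr)$v_avg_um_s,
                 abs(tr$x_um[40] - tr$x_um[1]) / (tr$t_s[40] - tr$t_s[1]))
  })
})

test_that("instantaneous velocity excludes paused steps by default", {
  tr <- track_from_speeds(c(0.8, 0.05, 0.05, 0.05, 0.8))
  expect_equal(instantaneous_velocity(tr)$v_inst_um_s, 0.8)
  expect_equal(instantaneous_velocity(tr, include_paused = TRUE)$v_inst_um_s,
               mean(c(0.8, 0.05, 0.05, 0.05, 0.8)))
  # no stops: plain mean of step speeds
  fast <- track_from_speeds(c(0.4, 0.6, 0.8))
  expect_equal(instantaneous_velocity(fast)$v_inst_um_s, 0.6)
  # fully paused track
  still <- track_from_speeds(rep(0.01, 5))
  vi <- instantaneous_velocity(still)
  expect_equal(vi$v_inst_um_s, 0)
  expect_true(vi$stationary)
})

test_that("run lengths are net displacements of stop-free stretches", {
  # two runs separated by one stop, noiseless construction
  speeds <- c(0.8, 0.8, 0.01, 0.01, 0.01, 0.5, 0.5)
  tr <- track_from_speeds(speeds)
  rl <- run_lengths(tr)
  expect_equal(nrow(rl), 2L)
  expect_equal(rl$run_length_um, c(2 * 0.8 * 3, (0.5 + 0.5) * 3))
  # no stops: single run equal to the net displacement
  fast <- track_from_speeds(rep(0.8, 4))
  expect_equal(run_lengths(fast)$run_length_um, 0.8 * 3 * 4)
  # fully paused track has no runs
  expect_equal(nrow(run_lengths(track_from_speeds(rep(0.01, 5)))), 0L)
})

test_that("MSD matches its closed form and the brute-force oracle", {
  tr <- track_from_speeds(rep(0.8, 20))
  msd <- track_msd(tr, 10)
  expect_equal(msd$msd_um2, (0.8 * (1:10) * 3)^2)
  expect_equal(track_msd(make_track(rep(2, 10)), 5)$msd_um2, rep(0, 5))
  expect_error(track_msd(tr, 21), "max_lag",
               class = "motorunit_parameter_error")

  withr::with_seed(41, {
    for (i in 1:200) {
      tr <- random_track(sample(5:100, 1))
      max_lag <- nrow(tr) - 1L
      expect_equal(track_msd(tr, max_lag)$msd_um2,
                   oracle_msd(tr$x_um, max_lag))
    }
  })
})

test_that("ensemble MSD averages tracks and reports SEM", {
  tr1 <- track_from_speeds(rep(0.8, 20))
  single <- ensemble_msd(tr1, 10)
  expect_equal(single$msd_mean_um2, track_msd(tr1, 10)$msd_um2)
  expect_equal(single$msd_sem_um2, rep(0, 10))

  tr2 <- tr1
  tr2$track_id <- "trk2"
  both <- ensemble_msd(dplyr::bind_rows(tr1, tr2), 10)
  expect_equal(both$msd_sem_um2, rep(0, 10))
  expect_equal(both$n_tracks, rep(2L, 10))

  # pure-run cohort: log-log slope of the ensemble MSD is 2
  p <- transport_params(noise_sd_um = 0, pause_entry_prob = 0,
                        run_speed_sd_um_s = 0.2, retrograde_fraction = 1,
                        n_frames = 50)
  ch <- simulate_chamber_tracks(p, 50, seed = 3)
  em <- ensemble_msd(ch, 20)
  alpha <- coef(lm(log(msd_mean_um2) ~ log(lag_s), data = em))[2]
  expect_lt(abs(alpha - 2), 0.05)
})

test_that("pure-noise ensemble MSD converges to 2 sigma^2 at every lag", {
  sigma <- 0.3
  p <- transport_params(noise_sd_um = sigma, run_speed_mean_um_s = 0,
                        run_speed_sd_um_s = 0, pause_entry_prob = 0,
                        n_frames = 10)
  ch <- simulate_chamber_tracks(p, 10000, seed = 13)
  em <- ensemble_msd(ch, 5)
  # x_i = iid N(0, sigma^2), so (x_{i+k} - x_i) ~ N(0, 2 sigma^2) at all k
  expect_equal(em$msd_mean_um2 / (2 * sigma^2), rep(1, 5),
               tolerance = 0.05)
})

test_that("inclusion filter applies the printed thresholds exactly", {
  # 10-frame track is excluded: duration must be strictly greater than 10
  ten <- track_from_speeds(rep(0.8, 9))
  expect_false(passes_inclusion_filter(ten)$passed_filter)
  # 11-frame track at exactly 0.2 um/s is included (inclusive >=)
  eleven <- track_from_speeds(rep(0.2, 10))
  expect_true(passes_inclusion_filter(eleven)$passed_filter)
  fast100 <- track_from_speeds(rep(0.8, 99))
  expect_true(passes_inclusion_filter(fast100)$passed_filter)

  # filtering an already-filtered cohort changes nothing
  ch <- simulate_chamber_tracks(transport_params(), 30, seed = 17)
  once <- apply_inclusion_filter(ch)
  expect_identical(apply_inclusion_filter(once), once)
})

test_that("velocity distribution normalizes and fits polynomials", {
  same <- dplyr::bind_rows(
    track_from_speeds(rep(0.8, 12), id = "a"),
    track_from_speeds(rep(0.8, 12), id = "b")
  )
  expect_warning(vd <- velocity_distribution(same), "reduced")
  expect_equal(nrow(vd$histogram), 1L)
  expect_equal(vd$histogram$fraction, 1)

  ch <- simulate_chamber_tracks(transport_params(), 100, seed = 19)
  vd <- velocity_distribution(ch, bin_width_um_s = 0.1, poly_degree = 3)
  expect_equal(sum(vd$histogram$fraction), 1)
  # degree-0 fit is the mean occupied-bin fraction (least-squares closed form)
  vd0 <- velocity_distribution(ch, bin_width_um_s = 0.1, poly_degree = 0)
  expect_equal(unname(vd0$coefficients), mean(vd0$histogram$fraction))
  expect_error(velocity_distribution(ch[0, ]), class = "motorunit_data_error")
})

test_that("directionality classifies by net displacement with a dead band", {
  expect_equal(as.character(directionality(make_track(c(0, -2.5, -5)))$direction),
               "retrograde")
  expect_equal(as.character(directionality(make_track(c(0, 2.5, 5)))$direction),
               "anterograde")
  expect_equal(as.character(directionality(make_track(c(0, 0.25, 0.5)))$direction),
               "stationary")
})

test_that("co-transport detection matches hand cases and the oracle", {
  a <- make_track(seq(0, -19, length.out = 20), id = "a")
  b <- a; b$track_id <- "b"
  full <- detect_cotransport(a, b, dist_um = 1, min_frames = 3)
  expect_equal(full$start_frame, 1L)
  expect_equal(full$n_frames, 20L)

  far <- b; far$x_um <- far$x_um + 2
  expect_equal(nrow(detect_cotransport(a, far, dist_um = 1, min_frames = 3)), 0L)

  offgrid <- b; offgrid$t_s <- offgrid$t_s + 0.5
  expect_error(detect_cotransport(a, offgrid, dist_um = 1, min_frames = 3),
               "time grid", class = "motorunit_data_error")

  withr::with_seed(51, {
    for (i in 1:200) {
      n <- sample(5:150, 1)
      a <- random_track(n, id = "a")
      b <- random_track(n, id = "b")
      got <- detect_cotransport(a, b, dist_um = 2, min_frames = 3)
      want <- oracle_cotransport(a$x_um, b$x_um, 2, 3)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start_frame, want$start_frame)
        expect_equal(got$n_frames, want$n_frames)
      }
    }
  })
})

test_that("summarize_tracks handles empty and singleton cohorts", {
  empty <- summarize_tracks(make_track(numeric(0))[0, ])
  expect_equal(nrow(empty$per_track), 0L)
  expect_equal(nrow(empty$cohort), 0L)

  one <- track_from_speeds(rep(0.8, 20))
  s <- summarize_tracks(one)
  expect_equal(s$cohort$n_tracks, 1L)
  expect_equal(s$cohort$v_avg_mean, s$per_track$v_avg_um_s[1])
  expect_equal(s$cohort$v_avg_sem, 0)
  expect_identical(tidy(s), s$per_track)
  expect_identical(glance(s), s$cohort)
})

test_that("simulated cohorts satisfy V_inst >= V_avg and recover run speed", {
  p <- transport_params()
  ch <- simulate_chamber_tracks(p, 200, seed = 23)
  s <- summarize_tracks(ch)
  passing <- dplyr::filter(s$per_track, passed_filter)
  expect_true(all(passing$v_inst_um_s >= passing$v_avg_um_s - 1e-12))
  # parameter recovery: mean V_inst within 3 SEM of the run-speed mean
  expect_lt(abs(s$cohort$v_inst_mean - p$run_speed_mean_um_s),
            3 * s$cohort$v_inst_sem + 0.05)
})

test_that("stop counts are zero without pausing and increase with pause rate", {
  mean_stops <- vapply(c(0, 0.05, 0.15), function(pe) {
    p <- transport_params(pause_entry_prob = pe, noise_sd_um = 0.01)
    ch <- simulate_chamber_tracks(p, 500, seed = 29)
    s <- summarize_tracks(ch)
    mean(dplyr::filter(s$per_track, passed_filter)$stop_count)
  }, numeric(1))
  expect_equal(mean_stops[1], 0)
  expect_true(all(diff(mean_stops) > 0))
})
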