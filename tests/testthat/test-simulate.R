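# Synthetic-data generators: determinism, noiseless closed forms,
# large-n frequency calibration, parameter validation, preset round-trip.

test_that("noiseless pure-run track is an exact arithmetic sequence", {
  p <- transport_params(noise_sd_um = 0, pause_entry_prob = 0,
                        run_speed_sd_um_s = 0, run_speed_mean_um_s = 0.8,
                        retrograde_fraction = 1)
  tr <- simulate_track(p, seed = 7)
  expect_equal(nrow(tr), 100L)
  expect_equal(diff(tr$x_um), rep(-2.4, 99))
  expect_equal(tr$t_s, (0:99) * 3)
})

test_that("a frozen pause leaves the noiseless position constant", {
  p <- transport_params(noise_sd_um = 0, pause_exit_prob = 0,
                        run_speed_mean_um_s = 0.8, run_speed_sd_um_s = 0)
  tr <- simulate_track(p, seed = 3, initial_state = "pause")
  expect_equal(tr$x_um, rep(0, 100))
})

test_that("generators are deterministic in (params, seed) and vary with seed", {
  p <- transport_params()
  expect_identical(simulate_track(p, seed = 1), simulate_track(p, seed = 1))
  expect_false(identical(simulate_track(p, seed = 1)$x_um,
                         simulate_track(p, seed = 2)$x_um))
  cp <- contraction_params(fraction_contracting = 0.5)
  expect_identical(simulate_intensity_traces(cp, 5, seed = 9),
                   simulate_intensity_traces(cp, 5, seed = 9))
  expect_identical(simulate_aggregate_counts(10, rep(1, 20), seed = 4),
                   simulate_aggregate_counts(10, rep(1, 20), seed = 4))
  sp <- survival_params()
  expect_identical(simulate_explant_counts(sp, seed = 11),
                   simulate_explant_counts(sp, seed = 11))
  # generators leave the caller's RNG stream untouched
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(simulate_track(p, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("chamber cohorts respect the retrograde fraction", {
  pure <- transport_params(noise_sd_um = 0, pause_entry_prob = 0,
                           run_speed_sd_um_s = 0, retrograde_fraction = 1)
  ch <- simulate_chamber_tracks(pure, 20, seed = 5)
  nets <- directionality(ch)$net_displacement_um
  expect_true(all(nets < 0))
  expect_equal(length(unique(ch$track_id)), 20L)

  one <- simulate_chamber_tracks(pure, 1, seed = 6)
  expect_equal(length(unique(one$track_id)), 1L)

  p <- transport_params(retrograde_fraction = 0.7, noise_sd_um = 0,
                        pause_entry_prob = 0, run_speed_sd_um_s = 0)
  ch <- simulate_chamber_tracks(p, 500, seed = 8)
  n_retro <- sum(directionality(ch)$net_displacement_um < 0)
  expect_within_binom_ci99(n_retro, 500, 0.7)
})

test_that("intensity traces carry bursts only in contractors and label truthfully", {
  cp0 <- contraction_params(fraction_contracting = 0)
  sim <- simulate_intensity_traces(cp0, 10, seed = 2)
  expect_false(any(sim$labels$contracting))
  expect_true(all(abs(sim$traces$intensity - 1) < 6 * cp0$noise_sd_rel))

  # noiseless contractor: deviations occur exactly in burst frames
  cp1 <- contraction_params(fraction_contracting = 1, noise_sd_rel = 0,
                            burst_rate_hz = 2, n_frames = 300)
  sim1 <- simulate_intensity_traces(cp1, 1, seed = 3)
  dev_frames <- sim1$traces$intensity != 1
  expect_true(any(dev_frames))
  expect_true(all(sim1$traces$intensity[dev_frames] >= 1 + cp1$burst_amplitude_rel - 1e-12))

  cp <- contraction_params(fraction_contracting = 0.74, n_frames = 50)
  sim <- simulate_intensity_traces(cp, 1000, seed = 4)
  expect_within_binom_ci99(sum(sim$labels$contracting), 1000, 0.74)
})

test_that("NMJ event generators hit their Bernoulli rates", {
  all_in <- simulate_nmj_events(1, 20, seed = 1)
  expect_true(all(all_in$axon_intact))
  none <- simulate_nmj_events(0, 20, seed = 1)
  expect_false(any(none$axon_intact))
  big <- simulate_nmj_events(0.75, 10000, seed = 2)
  expect_within_binom_ci99(sum(big$axon_intact), 10000, 0.75)
  # in vivo mode: innervation = presynaptic presence
  vivo <- simulate_nmj_events(0.4, 200, seed = 3, assay = "invivo")
  expect_true(all(vivo$post_present))
  expect_identical(vivo$pre_present, vivo$axon_intact)
})

test_that("explant counts thin correctly and never increase", {
  const <- survival_params(surviving_fraction_by_day = rep(1, 5))
  expect_equal(simulate_explant_counts(const, seed = 1)$count, rep(40L, 5))

  exact <- survival_params(initial_count = 40, count_noise = FALSE)
  counts <- simulate_explant_counts(exact, seed = 1)$count
  expect_equal(counts[5], 20L)
  expect_true(all(diff(counts) <= 0))

  sp <- survival_params()
  day16 <- vapply(1:200, function(i) {
    ec <- simulate_explant_counts(sp, seed = 1000 + i)
    expect_true(all(diff(ec$count) <= 0))
    ec$count[5]
  }, numeric(1))
  # total day-16 survivors over 200 explants ~ Binomial(200 * 40, 0.5)
  expect_within_binom_ci99(sum(day16), 200 * 40, 0.5)
})

test_that("aggregate counts are Poisson with the requested density", {
  expect_equal(simulate_aggregate_counts(0, rep(1, 10), seed = 1)$n_aggregates,
               rep(0L, 10))
  sims <- simulate_aggregate_counts(50, rep(1, 1000), seed = 2)
  expect_within_pois_ci99(sum(sims$n_aggregates), 50 * 1000)
})

test_that("fiber diameters are truncated Gaussians", {
  expect_equal(simulate_fiber_diameters(40, 0, 5, seed = 1)$diameter_um,
               rep(40, 5))
  d <- simulate_fiber_diameters(1, 5, 2000, seed = 2)$diameter_um
  expect_true(all(d > 0))
  d2 <- simulate_fiber_diameters(40, 8, 5000, seed = 3)$diameter_um
  # negligible truncation at mean/sd = 5, so the normal CI applies
  expect_lt(abs(mean(d2) - 40), 2.576 * 8 / sqrt(5000))
})

test_that("invalid parameters are rejected with the field named", {
  expect_error(transport_params(frame_interval_s = 0), "frame_interval_s",
               class = "motorunit_parameter_error")
  expect_error(transport_params(pause_entry_prob = 1.2), "pause_entry_prob",
               class = "motorunit_parameter_error")
  expect_error(transport_params(n_frames = 1), "n_frames",
               class = "motorunit_parameter_error")
  expect_error(contraction_params(burst_amplitude_rel = 0.01,
                                  noise_sd_rel = 0.02),
               "undetectable", class = "motorunit_parameter_error")
  expect_error(survival_params(surviving_fraction_by_day = c(1, 0.5, 0.6, 0.4, 0.3)),
               "non-increasing", class = "motorunit_parameter_error")
  expect_error(survival_params(surviving_fraction_by_day = c(0.9, 0.8, 0.7, 0.6, 0.5)),
               "start at 1", class = "motorunit_parameter_error")
  expect_error(simulate_chamber_tracks(transport_params(), 0, seed = 1),
               "n_tracks", class = "motorunit_parameter_error")
  expect_error(simulate_aggregate_counts(-1, 1, seed = 1),
               class = "motorunit_parameter_error")
  expect_error(simulate_aggregate_counts(1, c(1, -2), seed = 1),
               class = "motorunit_parameter_error")
})

test_that("presets pin the published group-level values and round-trip through config", {
  presets <- condition_presets()
  expect_equal(get_preset("contraction", "no_MN")$fraction_contracting, 0.10)
  expect_equal(get_preset("contraction", "WT_cocult")$fraction_contracting, 0.74)
  expect_equal(get_preset("nmj_invitro", "WT_cocult")$p_intact, 0.75)
  sod1 <- get_preset("survival", "SOD1_cocult")
  expect_equal(sod1$surviving_fraction_by_day[length(sod1$surviving_fraction_by_day)], 0.50)
  expect_equal(sod1$observation_days, c(7, 10, 12, 14, 16))
  expect_equal(get_preset("nmj_invivo", "SOD1_vehicle")$p_innervated, 0.40)
  expect_equal(get_preset("nmj_invivo", "SOD1_prido30")$p_innervated, 0.80)
  expect_equal(get_preset("aggregates", "SOD1_prido30")$density_per_mm2,
               get_preset("aggregates", "SOD1_vehicle")$density_per_mm2 / 2)
  expect_equal(get_preset("fibers", "SOD1_prido30")$mean_um,
               get_preset("fibers", "SOD1_vehicle")$mean_um + 4)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_preset_config(presets, path)
  back <- read_preset_config(path)
  expect_equal(back, presets)

  expect_error(get_preset("contraction", "nope"), "unknown preset",
               class = "motorunit_parameter_error")
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(fibers = list(X = list(mean_um = 1, wat = 2))), bad)
  expect_error(read_preset_config(bad), "unknown key",
               class = "motorunit_schema_error")
})
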