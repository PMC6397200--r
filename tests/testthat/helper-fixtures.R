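# Fixture builders used across test files.

make_track <- function(positions, dt = 3, id = "trk", condition = "WT",
                       channel = "QdotBDNF") {
  tibble::tibble(
    track_id = id,
    frame = seq_along(positions) - 1L,
    t_s = (seq_along(positions) - 1L) * dt,
    x_um = positions,
    channel = channel,
    condition = condition
  )
}

# A track with given per-step speeds (all steps in the same direction).
track_from_speeds <- function(speeds, dt = 3, id = "trk") {
  make_track(c(0, cumsum(speeds * dt)), dt = dt, id = id)
}

# Random jittery track mixing slow and fast stretches, for oracle tests.
random_track <- function(n_frames, dt = 3, id = "trk") {
  steps <- sample(c(
    runif(n_frames - 1L, 0, 0.05),      # sub-threshold speeds
    runif(n_frames - 1L, 0.1, 1.5)      # supra-threshold speeds
  ), n_frames - 1L) * dt * sample(c(-1, 1), n_frames - 1L, replace = TRUE)
  make_track(c(0, cumsum(steps)), dt = dt, id = id)
}

# Toy 20-track cohort: exactly 7 tracks violate "duration > 10 frames",
# 4 violate "V_avg >= 0.2 um/s", one of which violates both, so exactly
# 10 tracks pass the inclusion filter.
toy_filter_cohort <- function() {
  dt <- 3
  fast <- function(n) rep(0.8 * dt, n - 1L)   # V_avg = 0.8 um/s
  slow <- function(n) rep(0.05 * dt, n - 1L)  # V_avg = 0.05 um/s
  specs <- list()
  for (i in 1:6)  specs[[length(specs) + 1L]] <- list(n = 8L, v = "fast")
  specs[[length(specs) + 1L]] <- list(n = 10L, v = "slow")  # violates both
  for (i in 1:3)  specs[[length(specs) + 1L]] <- list(n = 50L, v = "slow")
  for (i in 1:10) specs[[length(specs) + 1L]] <- list(n = 50L, v = "fast")
  purrr::map_dfr(seq_along(specs), function(i) {
    s <- specs[[i]]
    steps <- if (s$v == "fast") fast(s$n) else slow(s$n)
    make_track(c(0, cumsum(-steps)), dt = dt, id = sprintf("toy_%02d", i))
  })
}
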