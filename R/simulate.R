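# Seeded synthetic-data generators. Every generator is a pure function of
# (params, seed): identical inputs give bit-identical outputs, and the
# caller's RNG state is left untouched.

#' Simulate one axonal cargo track
#'
#' Two-state (run/pause) Markov dynamics along a 1-D axon axis: the state
#' switches by per-frame Bernoulli trials; in a run the true position
#' advances by `direction * speed * frame_interval_s` per frame, in a
#' pause it stays put. The reported position adds iid Gaussian
#' localization noise (`noise_sd_um`) to every frame, so a paused
#' particle's measured position fluctuates by noise only and its mean
#' squared displacement converges to `2 * noise_sd_um^2` at every lag.
#' The direction is fixed per track (negative = retrograde, towards the
#' soma) and the run speed is drawn once per track from N(mean, sd)
#' truncated at 0.
#'
#' @param params A [transport_params()] object.
#' @param seed Integer seed.
#' @param track_id,channel,condition Labels carried into the output.
#' @param initial_state Starting motility state, `"run"` (default) or
#'   `"pause"`.
#' @return A tibble with columns `track_id`, `frame` (0-based), `t_s`,
#'   `x_um`, `channel`, `condition`; exactly `n_frames` rows.
#' @export
simulate_track <- function(params, seed, track_id = "trk_1",
                           channel = "QdotBDNF", condition = "WT",
                           initial_state = c("run", "pause")) {
  if (!inherits(params, "transport_params")) {
    stop_parameter("`params` must be a transport_params object")
  }
  initial_state <- match.arg(initial_state)
  check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    n <- params$n_frames
    dt <- params$frame_interval_s
    direction <- if (stats::runif(1) < params$retrograde_fraction) -1 else 1
    speed <- max(0, stats::rnorm(1, params$run_speed_mean_um_s,
                                 params$run_speed_sd_um_s))
    # state[i] governs the step from frame i-1 to frame i
    state <- logical(n - 1L)  # TRUE = run
    s <- initial_state == "run"
    u <- stats::runif(n - 1L)
    for (i in seq_len(n - 1L)) {
      state[i] <- s
      p_switch <- if (s) params$pause_entry_prob else params$pause_exit_prob
      if (u[i] < p_switch) s <- !s
    }
    steps <- ifelse(state, direction * speed * dt, 0)
    x <- c(0, cumsum(steps))
    if (params$noise_sd_um > 0) {
      x <- x + stats::rnorm(n, 0, params$noise_sd_um)
    }
    tibble::tibble(
      track_id = track_id,
      frame = seq_len(n) - 1L,
      t_s = (seq_len(n) - 1L) * dt,
      x_um = x,
      channel = channel,
      condition = condition
    )
  })
}

#' Simulate a chamber's worth of independent tracks
#'
#' @param params A [transport_params()] object.
#' @param n_tracks Number of tracks (>= 1).
#' @param seed Integer seed; per-track sub-seeds are derived from it.
#' @param channel,condition Labels carried into the output.
#' @return A tibble of `n_tracks` stacked tracks (see [simulate_track()]).
#' @export
simulate_chamber_tracks <- function(params, n_tracks, seed,
                                    channel = "QdotBDNF", condition = "WT") {
  n_tracks <- check_count(n_tracks, "n_tracks", min = 1L)
  seeds <- derive_seeds(seed, n_tracks)
  ids <- sprintf("trk_%04d", seq_len(n_tracks))
  purrr::map2_dfr(seeds, ids, function(s, id) {
    simulate_track(params, seed = s, track_id = id,
                   channel = channel, condition = condition)
  })
}

#' Simulate myofiber intensity-over-time traces
#'
#' Non-contractors are baseline 1.0 plus Gaussian noise; contractors carry
#' a Poisson number of fixed-amplitude burst deflections at random onsets.
#' Ground-truth contractor labels are returned alongside the traces.
#'
#' @param params A [contraction_params()] object.
#' @param n_fibers Number of fibers (>= 1).
#' @param seed Integer seed.
#' @param chamber_id,condition Labels carried into the output.
#' @return A list with `traces` (tibble: `fiber_id`, `chamber_id`,
#'   `condition`, `frame`, `intensity`) and `labels` (tibble: `fiber_id`,
#'   `chamber_id`, `condition`, `contracting`).
#' @export
simulate_intensity_traces <- function(params, n_fibers, seed,
                                      chamber_id = "chamber_1",
                                      condition = "WT") {
  if (!inherits(params, "contraction_params")) {
    stop_parameter("`params` must be a contraction_params object")
  }
  n_fibers <- check_count(n_fibers, "n_fibers", min = 1L)
  check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    n <- params$n_frames
    duration_s <- n / params$fps
    contracting <- stats::runif(n_fibers) < params$fraction_contracting
    # one column per fiber
    intensity <- matrix(1, nrow = n, ncol = n_fibers)
    if (params$noise_sd_rel > 0) {
      intensity <- intensity + stats::rnorm(n * n_fibers, 0,
                                            params$noise_sd_rel)
    }
    dur <- params$burst_duration_frames
    for (i in which(contracting)) {
      n_events <- stats::rpois(1, params$burst_rate_hz * duration_s)
      if (n_events > 0L) {
        starts <- sample.int(n - dur + 1L, n_events, replace = TRUE)
        for (s in starts) {
          idx <- s:(s + dur - 1L)
          intensity[idx, i] <- intensity[idx, i] + params$burst_amplitude_rel
        }
      }
    }
    traces <- tibble::tibble(
      fiber_id = rep(sprintf("fib_%04d", seq_len(n_fibers)), each = n),
      chamber_id = chamber_id,
      condition = condition,
      frame = rep(seq_len(n) - 1L, n_fibers),
      intensity = as.vector(intensity)
    )
    labels <- tibble::tibble(
      fiber_id = sprintf("fib_%04d", seq_len(n_fibers)),
      chamber_id = chamber_id,
      condition = condition,
      contracting = contracting
    )
    list(traces = traces, labels = labels)
  })
}

#' Simulate NMJ colocalization events
#'
#' In the in vitro assay every event is a pre/post colocalization site and
#' is intact (non-degenerated axon) with probability `p`. In the in vivo
#' assay every event is a postsynaptic (AChR) site and is innervated
#' (presynaptic marker present) with probability `p`.
#'
#' @param p Probability of an intact (in vitro) or innervated (in vivo)
#'   event.
#' @param n_events Number of events (>= 1).
#' @param seed Integer seed.
#' @param unit_id,condition Labels (chamber or muscle).
#' @param assay `"invitro"` or `"invivo"`.
#' @return A tibble with columns `event_id`, `unit_id`, `condition`,
#'   `pre_present`, `post_present`, `axon_intact`.
#' @export
simulate_nmj_events <- function(p, n_events, seed, unit_id = "unit_1",
                                condition = "WT",
                                assay = c("invitro", "invivo")) {
  check_probability(p, "p")
  n_events <- check_count(n_events, "n_events", min = 1L)
  check_count(seed, "seed", min = 0L)
  assay <- match.arg(assay)
  withr::with_seed(seed, {
    hit <- stats::runif(n_events) < p
    if (assay == "invitro") {
      tibble::tibble(
        event_id = sprintf("%s_ev_%05d", unit_id, seq_len(n_events)),
        unit_id = unit_id,
        condition = condition,
        pre_present = TRUE,
        post_present = TRUE,
        axon_intact = hit
      )
    } else {
      tibble::tibble(
        event_id = sprintf("%s_ev_%05d", unit_id, seq_len(n_events)),
        unit_id = unit_id,
        condition = condition,
        pre_present = hit,
        post_present = TRUE,
        axon_intact = hit
      )
    }
  })
}

#' Simulate one explant's motor-neuron counts over observation days
#'
#' With `count_noise = TRUE` the count at each day is a sequential
#' binomial thinning of the previous day's count (so counts are
#' non-increasing and the expectation at day d is `initial_count *
#' fraction[d]`); with noise off the expectation is rounded exactly.
#'
#' @param params A [survival_params()] object.
#' @param seed Integer seed.
#' @param explant_id,condition Labels carried into the output.
#' @return A tibble with columns `explant_id`, `condition`, `day`, `count`.
#' @export
simulate_explant_counts <- function(params, seed, explant_id = "expl_1",
                                    condition = "WT") {
  if (!inherits(params, "survival_params")) {
    stop_parameter("`params` must be a survival_params object")
  }
  check_count(seed, "seed", min = 0L)
  f <- params$surviving_fraction_by_day
  n_days <- length(f)
  counts <- integer(n_days)
  counts[1] <- params$initial_count
  if (params$count_noise) {
    withr::with_seed(seed, {
      for (d in seq_len(n_days)[-1]) {
        keep_p <- if (f[d - 1] > 0) f[d] / f[d - 1] else 0
        counts[d] <- stats::rbinom(1, counts[d - 1], keep_p)
      }
    })
  } else {
    counts <- as.integer(round(params$initial_count * f))
  }
  tibble::tibble(
    explant_id = explant_id,
    condition = condition,
    day = params$observation_days,
    count = counts
  )
}

#' Simulate per-section aggregate counts
#'
#' Counts are independent Poisson draws with mean `density_per_mm2 *
#' area_mm2`, emulating puncta counted on spinal-cord sections.
#'
#' @param density_per_mm2 Aggregate density (>= 0).
#' @param areas_mm2 Vector of section areas in mm^2 (all > 0).
#' @param seed Integer seed.
#' @param group,compartment Labels carried into the output.
#' @return A tibble with columns `section_id`, `group`, `compartment`,
#'   `area_mm2`, `n_aggregates`.
#' @export
simulate_aggregate_counts <- function(density_per_mm2, areas_mm2, seed,
                                      group = "group_1",
                                      compartment = "gray") {
  check_scalar_number(density_per_mm2, "density_per_mm2", min = 0)
  if (length(areas_mm2) < 1L || any(!is.finite(areas_mm2)) || any(areas_mm2 <= 0)) {
    stop_parameter("`areas_mm2` must be positive finite areas")
  }
  check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    counts <- stats::rpois(length(areas_mm2), density_per_mm2 * areas_mm2)
    tibble::tibble(
      section_id = sprintf("sec_%04d", seq_along(areas_mm2)),
      group = group,
      compartment = compartment,
      area_mm2 = as.numeric(areas_mm2),
      n_aggregates = counts
    )
  })
}

#' Simulate muscle-fiber diameters
#'
#' Gaussian draws truncated at zero (negative or zero draws are rejected
#' and redrawn).
#'
#' @param mean_um,sd_um Mean and SD of the untruncated normal, um.
#' @param n Number of fibers (>= 1).
#' @param seed Integer seed.
#' @param group Label carried into the output.
#' @return A tibble with columns `group`, `diameter_um`.
#' @export
simulate_fiber_diameters <- function(mean_um, sd_um, n, seed,
                                     group = "group_1") {
  check_scalar_number(mean_um, "mean_um", min = 0, strict_min = TRUE)
  check_scalar_number(sd_um, "sd_um", min = 0)
  n <- check_count(n, "n", min = 1L)
  check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    if (sd_um == 0) {
      d <- rep(mean_um, n)
    } else {
      d <- stats::rnorm(n, mean_um, sd_um)
      while (any(d <= 0)) {
        bad <- d <= 0
        d[bad] <- stats::rnorm(sum(bad), mean_um, sd_um)
      }
    }
    tibble::tibble(group = group, diameter_um = d)
  })
}
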