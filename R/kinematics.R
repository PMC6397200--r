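# Single-particle track kinematics: step speeds, stop detection,
# velocities, run lengths, MSD, inclusion filtering, directionality,
# velocity histograms and co-transport.
#
# Conventions, stated once and used everywhere:
#   * position x_um is 1-D along the axon axis; retrograde (towards the
#     soma) = negative increments, anterograde = positive.
#   * "step i" (1-based) is the displacement between frames i and i+1; a
#     track of n frames has n - 1 steps.
#   * tracks must be uniformly sampled (relative tolerance 1e-6); gappy
#     tracks are rejected, never interpolated, because interpolation would
#     silently alter stop statistics.

FRAME_INTERVAL_RTOL <- 1e-6

# Validate one track's time base; returns the frame interval.
check_uniform_dt <- function(t_s, track_id) {
  if (length(t_s) < 2L) {
    stop_data(sprintf("track '%s' has fewer than 2 frames", track_id))
  }
  dts <- diff(t_s)
  if (any(dts <= 0)) {
    stop_data(sprintf("track '%s' has non-increasing timestamps", track_id))
  }
  dt <- mean(dts)
  if (max(abs(dts - dt)) > FRAME_INTERVAL_RTOL * dt) {
    stop_data(sprintf(
      "track '%s' is not uniformly sampled (frame gaps present); gappy tracks are rejected, not interpolated",
      track_id
    ))
  }
  dt
}

check_track_cols <- function(tracks) {
  required <- c("track_id", "t_s", "x_um")
  missing <- setdiff(required, names(tracks))
  if (length(missing) > 0L) {
    stop_schema(sprintf("track table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  invisible(tracks)
}

# Split a (possibly multi-track) table into validated per-track pieces,
# each sorted by time. Preserves first-seen track order.
split_tracks <- function(tracks) {
  check_track_cols(tracks)
  ids <- unique(tracks$track_id)
  pieces <- split(tracks, factor(tracks$track_id, levels = ids))
  lapply(pieces, function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    check_uniform_dt(tr$t_s, tr$track_id[1])
    tr
  })
}

#' Per-step speeds of each track
#'
#' The speed of step i is `|x_{i+1} - x_i| / dt`, the basis of the
#' instantaneous-velocity statistic.
#'
#' @param tracks Track table with columns `track_id`, `t_s`, `x_um`
#'   (extra columns such as `frame`, `channel`, `condition`, `y_um` are
#'   tolerated; any `y_um` is ignored).
#' @return A tibble with columns `track_id`, `step` (1-based index of the
#'   inter-frame step), `speed_um_s`.
#' @export
track_step_speeds <- function(tracks) {
  pieces <- split_tracks(tracks)
  purrr::map_dfr(pieces, function(tr) {
    dt <- mean(diff(tr$t_s))
    tibble::tibble(
      track_id = tr$track_id[1],
      step = seq_len(nrow(tr) - 1L),
      speed_um_s = abs(diff(tr$x_um)) / dt
    )
  })
}

#' Detect stop segments in tracks
#'
#' A stop is a maximal run of at least `min_frames` consecutive
#' inter-frame steps whose speed is strictly below `stop_speed_um_s`
#' (a step at exactly the threshold is not a stop). Segments are disjoint
#' and reported in order.
#'
#' @inheritParams track_step_speeds
#' @param stop_speed_um_s Speed threshold in um/s (default 0.1).
#' @param min_frames Minimum number of consecutive sub-threshold steps
#'   (default 3).
#' @return A tibble with columns `track_id`, `start_step` (1-based index
#'   of the first step in the segment), `n_steps`.
#' @export
detect_stops <- function(tracks, stop_speed_um_s = 0.1, min_frames = 3) {
  check_scalar_number(stop_speed_um_s, "stop_speed_um_s", min = 0)
  min_frames <- check_count(min_frames, "min_frames", min = 1L)
  speeds <- track_step_speeds(tracks)
  purrr::map_dfr(split(speeds, factor(speeds$track_id,
                                      levels = unique(speeds$track_id))),
                 function(sp) {
    r <- runs_of(sp$speed_um_s < stop_speed_um_s, min_frames)
    if (nrow(r) == 0L) {
      return(tibble::tibble(track_id = character(), start_step = integer(),
                            n_steps = integer()))
    }
    tibble::tibble(track_id = sp$track_id[1], start_step = r$start,
                   n_steps = r$length)
  })
}

#' Average velocity of each track
#'
#' Net displacement magnitude over elapsed time,
#' `|x_last - x_first| / (t_last - t_first)`. This is the processive-rate
#' definition used by the inclusion filter; see [summarize_tracks()] for
#' the path-length alternative.
#'
#' @inheritParams track_step_speeds
#' @param path_length Use total path length instead of net displacement?
#' @return A tibble with columns `track_id`, `v_avg_um_s`.
#' @export
average_velocity <- function(tracks, path_length = FALSE) {
  pieces <- split_tracks(tracks)
  purrr::map_dfr(pieces, function(tr) {
    elapsed <- tr$t_s[nrow(tr)] - tr$t_s[1]
    dist <- if (path_length) {
      sum(abs(diff(tr$x_um)))
    } else {
      abs(tr$x_um[nrow(tr)] - tr$x_um[1])
    }
    tibble::tibble(track_id = tr$track_id[1], v_avg_um_s = dist / elapsed)
  })
}

# Logical mask (one element per step) marking steps inside stop segments.
stop_mask <- function(n_steps, stops_one) {
  mask <- logical(n_steps)
  if (nrow(stops_one) > 0L) {
    for (i in seq_len(nrow(stops_one))) {
      idx <- stops_one$start_step[i]:(stops_one$start_step[i] + stops_one$n_steps[i] - 1L)
      mask[idx] <- TRUE
    }
  }
  mask
}

#' Instantaneous velocity of each track
#'
#' Mean per-step speed, by default excluding steps inside detected stop
#' segments so that speed while moving and pausing behaviour are measured
#' on separate axes. With `include_paused = TRUE` all steps contribute.
#' A track whose steps are all inside stops gets velocity 0 and is
#' flagged stationary.
#'
#' @inheritParams detect_stops
#' @param stops Optional precomputed stop table from [detect_stops()];
#'   computed at the default thresholds when `NULL`.
#' @param include_paused Include steps inside stop segments?
#' @return A tibble with columns `track_id`, `v_inst_um_s`, `stationary`.
#' @export
instantaneous_velocity <- function(tracks, stops = NULL,
                                   include_paused = FALSE,
                                   stop_speed_um_s = 0.1, min_frames = 3) {
  speeds <- track_step_speeds(tracks)
  if (is.null(stops)) {
    stops <- detect_stops(tracks, stop_speed_um_s, min_frames)
  }
  purrr::map_dfr(split(speeds, factor(speeds$track_id,
                                      levels = unique(speeds$track_id))),
                 function(sp) {
    id <- sp$track_id[1]
    mask <- stop_mask(nrow(sp), stops[stops$track_id == id, , drop = FALSE])
    use <- if (include_paused) rep(TRUE, nrow(sp)) else !mask
    if (!any(use)) {
      tibble::tibble(track_id = id, v_inst_um_s = 0, stationary = TRUE)
    } else {
      tibble::tibble(track_id = id, v_inst_um_s = mean(sp$speed_um_s[use]),
                     stationary = FALSE)
    }
  })
}

#' Run lengths of each track
#'
#' For every maximal stop-free stretch of steps, the absolute net
#' displacement over that stretch. A fully paused track contributes no
#' runs.
#'
#' @inheritParams instantaneous_velocity
#' @return A tibble with columns `track_id`, `run` (1-based run index),
#'   `start_step`, `n_steps`, `run_length_um`.
#' @export
run_lengths <- function(tracks, stops = NULL,
                        stop_speed_um_s = 0.1, min_frames = 3) {
  pieces <- split_tracks(tracks)
  if (is.null(stops)) {
    stops <- detect_stops(tracks, stop_speed_um_s, min_frames)
  }
  purrr::map_dfr(pieces, function(tr) {
    id <- tr$track_id[1]
    n_steps <- nrow(tr) - 1L
    mask <- stop_mask(n_steps, stops[stops$track_id == id, , drop = FALSE])
    r <- runs_of(!mask, 1L)
    if (nrow(r) == 0L) {
      return(tibble::tibble(track_id = character(), run = integer(),
                            start_step = integer(), n_steps = integer(),
                            run_length_um = numeric()))
    }
    tibble::tibble(
      track_id = id,
      run = seq_len(nrow(r)),
      start_step = r$start,
      n_steps = r$length,
      # positions spanned by steps start..start+len-1 are x[start]..x[start+len]
      run_length_um = abs(tr$x_um[r$start + r$length] - tr$x_um[r$start])
    )
  })
}

#' Time-averaged mean squared displacement per track
#'
#' Overlapping-window estimator: `MSD(k) = mean_i (x_{i+k} - x_i)^2` over
#' all window starts i, for lags k = 1..max_lag. Lag 0 is omitted.
#'
#' @inheritParams track_step_speeds
#' @param max_lag Largest lag in frames; must be smaller than the number
#'   of frames of every track.
#' @return A tibble with columns `track_id`, `lag` (frames), `lag_s`,
#'   `msd_um2`.
#' @export
track_msd <- function(tracks, max_lag) {
  max_lag <- check_count(max_lag, "max_lag", min = 1L)
  pieces <- split_tracks(tracks)
  purrr::map_dfr(pieces, function(tr) {
    n <- nrow(tr)
    if (max_lag >= n) {
      stop_parameter(sprintf(
        "`max_lag` (%d) must be smaller than the number of frames of track '%s' (%d)",
        max_lag, tr$track_id[1], n
      ))
    }
    dt <- mean(diff(tr$t_s))
    x <- tr$x_um
    msd <- vapply(seq_len(max_lag), function(k) {
      mean((x[(1 + k):n] - x[1:(n - k)])^2)
    }, numeric(1))
    tibble::tibble(
      track_id = tr$track_id[1],
      lag = seq_len(max_lag),
      lag_s = seq_len(max_lag) * dt,
      msd_um2 = msd
    )
  })
}

#' Ensemble mean squared displacement over a track cohort
#'
#' Per-track time-averaged MSD curves ([track_msd()]) are averaged across
#' tracks at each lag; tracks shorter than a lag simply do not contribute
#' to it. All tracks must share the frame interval.
#'
#' @inheritParams track_step_speeds
#' @param max_lag Largest lag in frames; capped per track at its length
#'   minus one.
#' @return A tibble with columns `lag`, `lag_s`, `msd_mean_um2`,
#'   `msd_sem_um2`, `n_tracks`.
#' @export
ensemble_msd <- function(tracks, max_lag) {
  max_lag <- check_count(max_lag, "max_lag", min = 1L)
  pieces <- split_tracks(tracks)
  if (length(pieces) == 0L) {
    stop_data("no tracks supplied")
  }
  dts <- vapply(pieces, function(tr) mean(diff(tr$t_s)), numeric(1))
  dt <- dts[1]
  if (max(abs(dts - dt)) > FRAME_INTERVAL_RTOL * dt) {
    stop_data("tracks do not share a common frame interval")
  }
  per_track <- purrr::map_dfr(pieces, function(tr) {
    track_msd(tr, min(max_lag, nrow(tr) - 1L))
  })
  per_track |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      lag_s = .data$lag[1] * dt,
      msd_mean_um2 = mean(.data$msd_um2),
      msd_sem_um2 = if (dplyr::n() > 1L) {
        stats::sd(.data$msd_um2) / sqrt(dplyr::n())
      } else 0,
      n_tracks = dplyr::n(),
      .groups = "drop"
    )
}

#' Inclusion-filter flags per track
#'
#' A track is analyzable when its duration is strictly greater than
#' `min_duration_frames` frames and its average velocity is at least
#' `min_vavg_um_s` (inclusive), exactly as the upstream tracking protocol
#' prescribes.
#'
#' @inheritParams track_step_speeds
#' @param min_duration_frames Duration threshold, strict (default 10).
#' @param min_vavg_um_s Average-velocity threshold, inclusive
#'   (default 0.2 um/s).
#' @return A tibble with columns `track_id`, `n_frames`, `v_avg_um_s`,
#'   `passed_filter`.
#' @export
passes_inclusion_filter <- function(tracks, min_duration_frames = 10,
                                    min_vavg_um_s = 0.2) {
  pieces <- split_tracks(tracks)
  vavg <- average_velocity(tracks)
  n_frames <- vapply(pieces, nrow, integer(1))
  tibble::tibble(
    track_id = vapply(pieces, function(tr) tr$track_id[1], character(1)),
    n_frames = n_frames,
    v_avg_um_s = vavg$v_avg_um_s,
    passed_filter = n_frames > min_duration_frames &
      vavg$v_avg_um_s >= min_vavg_um_s
  )
}

#' Apply the inclusion filter to a track table
#'
#' @inheritParams passes_inclusion_filter
#' @return The rows of `tracks` belonging to passing tracks.
#' @export
apply_inclusion_filter <- function(tracks, min_duration_frames = 10,
                                   min_vavg_um_s = 0.2) {
  flags <- passes_inclusion_filter(tracks, min_duration_frames, min_vavg_um_s)
  keep <- flags$track_id[flags$passed_filter]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Distribution of per-track average velocities with a polynomial fit
#'
#' Histograms the per-track average velocities into bins of
#' `bin_width_um_s`, normalizes occupied-bin fractions to sum to 1, and
#' fits an ordinary least-squares polynomial of `poly_degree` to fraction
#' versus bin center (degree is reduced with a warning when there are too
#' few occupied bins).
#'
#' @inheritParams track_step_speeds
#' @param bin_width_um_s Histogram bin width in um/s.
#' @param poly_degree Polynomial degree (default 3).
#' @return A `velocity_distribution` object: list with `histogram`
#'   (tibble: `bin_center_um_s`, `n`, `fraction`), `coefficients`
#'   (intercept first), `degree`, `bin_width_um_s`.
#' @export
velocity_distribution <- function(tracks, bin_width_um_s = 0.1,
                                  poly_degree = 3) {
  check_scalar_number(bin_width_um_s, "bin_width_um_s", min = 0,
                      strict_min = TRUE)
  poly_degree <- check_count(poly_degree, "poly_degree", min = 0L)
  if (nrow(tracks) == 0L) {
    stop_data("empty track list: cannot histogram velocities")
  }
  v <- average_velocity(tracks)$v_avg_um_s
  bin <- floor(v / bin_width_um_s)
  tab <- table(bin)
  centers <- (as.numeric(names(tab)) + 0.5) * bin_width_um_s
  fractions <- as.numeric(tab) / sum(tab)
  hist_tbl <- tibble::tibble(
    bin_center_um_s = centers,
    n = as.integer(tab),
    fraction = fractions
  )
  degree <- poly_degree
  if (degree > nrow(hist_tbl) - 1L) {
    degree <- nrow(hist_tbl) - 1L
    warning(sprintf(
      "poly_degree reduced to %d (only %d occupied bins)", degree,
      nrow(hist_tbl)
    ))
  }
  coefs <- if (degree == 0L) {
    c(`(Intercept)` = mean(fractions))
  } else {
    stats::coef(stats::lm(
      fraction ~ stats::poly(bin_center_um_s, degree, raw = TRUE),
      data = hist_tbl
    ))
  }
  names(coefs) <- paste0("b", seq_along(coefs) - 1L)
  structure(
    list(histogram = hist_tbl, coefficients = coefs, degree = degree,
         bin_width_um_s = bin_width_um_s),
    class = "velocity_distribution"
  )
}

#' @export
print.velocity_distribution <- function(x, ...) {
  cat("<velocity_distribution> ", nrow(x$histogram), " occupied bins (width ",
      x$bin_width_um_s, " um/s), degree-", x$degree, " polynomial fit\n",
      sep = "")
  print(x$histogram)
  invisible(x)
}

#' Net transport direction of each track
#'
#' Retrograde if the net displacement is below `-min_net_um`, anterograde
#' if above `+min_net_um`, stationary otherwise.
#'
#' @inheritParams track_step_speeds
#' @param min_net_um Net-displacement dead band in um (default 1).
#' @return A tibble with columns `track_id`, `net_displacement_um`,
#'   `direction` (factor: retrograde/anterograde/stationary).
#' @export
directionality <- function(tracks, min_net_um = 1) {
  check_scalar_number(min_net_um, "min_net_um", min = 0)
  pieces <- split_tracks(tracks)
  purrr::map_dfr(pieces, function(tr) {
    net <- tr$x_um[nrow(tr)] - tr$x_um[1]
    dir <- if (net < -min_net_um) {
      "retrograde"
    } else if (net > min_net_um) {
      "anterograde"
    } else {
      "stationary"
    }
    tibble::tibble(
      track_id = tr$track_id[1],
      net_displacement_um = net,
      direction = factor(dir, levels = c("retrograde", "anterograde",
                                         "stationary"))
    )
  })
}

#' Detect co-transport intervals between two tracks
#'
#' Two cargoes are co-transported over a maximal interval of at least
#' `min_frames` consecutive frames in which their positions differ by
#' strictly less than `dist_um`. The two tracks must share the frame grid.
#'
#' @param track_a,track_b Single-track tables (columns `track_id`, `t_s`,
#'   `x_um`).
#' @param dist_um Colocalization distance threshold in um.
#' @param min_frames Minimum interval length in frames.
#' @return A tibble with columns `start_frame` (1-based), `n_frames`.
#' @export
detect_cotransport <- function(track_a, track_b, dist_um, min_frames) {
  check_scalar_number(dist_um, "dist_um", min = 0, strict_min = TRUE)
  min_frames <- check_count(min_frames, "min_frames", min = 1L)
  a <- split_tracks(track_a)
  b <- split_tracks(track_b)
  if (length(a) != 1L || length(b) != 1L) {
    stop_parameter("`track_a` and `track_b` must each contain exactly one track")
  }
  a <- a[[1]]; b <- b[[1]]
  if (nrow(a) != nrow(b)) {
    stop_data("tracks have different lengths: time grids cannot be aligned")
  }
  dt <- mean(diff(a$t_s))
  if (max(abs(a$t_s - b$t_s)) > FRAME_INTERVAL_RTOL * dt) {
    stop_data("tracks are not aligned on a common time grid")
  }
  close_enough <- abs(a$x_um - b$x_um) < dist_um
  r <- runs_of(close_enough, min_frames)
  tibble::tibble(start_frame = as.integer(r$start),
                 n_frames = as.integer(r$length))
}

#' Summarize a track cohort
#'
#' Applies the inclusion filter, computes every kinematic statistic for
#' passing tracks, and returns per-track, per-step and per-cohort tables.
#' Excluded tracks appear in the per-track table with `passed_filter =
#' FALSE` and `NA` statistics.
#'
#' @inheritParams track_step_speeds
#' @param stop_speed_um_s,stop_min_frames Stop-detection thresholds.
#' @param min_duration_frames,min_vavg_um_s Inclusion-filter thresholds.
#' @param include_paused Include paused steps in the instantaneous
#'   velocity? Default `FALSE`.
#' @param min_net_um Directionality dead band in um.
#' @return A `transport_summary` object: list with `per_track`, `per_step`
#'   and `cohort` tibbles plus the thresholds used. [generics::tidy()]
#'   returns the per-track table, [generics::glance()] the cohort table.
#' @export
summarize_tracks <- function(tracks, stop_speed_um_s = 0.1,
                             stop_min_frames = 3, min_duration_frames = 10,
                             min_vavg_um_s = 0.2, include_paused = FALSE,
                             min_net_um = 1) {
  empty <- structure(
    list(
      per_track = tibble::tibble(
        track_id = character(), condition = character(),
        channel = character(), n_frames = integer(),
        v_avg_um_s = numeric(), v_inst_um_s = numeric(),
        stop_count = integer(), n_runs = integer(),
        mean_run_length_um = numeric(), net_displacement_um = numeric(),
        direction = factor(character(), levels = c("retrograde",
                                                   "anterograde",
                                                   "stationary")),
        passed_filter = logical()
      ),
      per_step = tibble::tibble(
        track_id = character(), condition = character(),
        channel = character(), step = integer(), speed_um_s = numeric(),
        in_stop = logical()
      ),
      cohort = tibble::tibble(
        condition = character(), n_tracks = integer(),
        v_inst_mean = numeric(), v_inst_sem = numeric(),
        v_avg_mean = numeric(), v_avg_sem = numeric(),
        stop_count_mean = numeric(), stop_count_sem = numeric(),
        run_length_mean = numeric(), run_length_sem = numeric(),
        retrograde_fraction = numeric()
      ),
      thresholds = list(stop_speed_um_s = stop_speed_um_s,
                        stop_min_frames = stop_min_frames,
                        min_duration_frames = min_duration_frames,
                        min_vavg_um_s = min_vavg_um_s,
                        include_paused = include_paused,
                        min_net_um = min_net_um)
    ),
    class = "transport_summary"
  )
  if (nrow(tracks) == 0L) {
    return(empty)
  }
  if (!"condition" %in% names(tracks)) tracks$condition <- "all"
  if (!"channel" %in% names(tracks)) tracks$channel <- "default"
  flags <- passes_inclusion_filter(tracks, min_duration_frames, min_vavg_um_s)
  meta <- tracks |>
    dplyr::distinct(.data$track_id, .data$condition, .data$channel)
  kept <- apply_inclusion_filter(tracks, min_duration_frames, min_vavg_um_s)

  if (nrow(kept) > 0L) {
    stops <- detect_stops(kept, stop_speed_um_s, stop_min_frames)
    vinst <- instantaneous_velocity(kept, stops,
                                    include_paused = include_paused)
    vavg <- average_velocity(kept)
    runs <- run_lengths(kept, stops)
    dirs <- directionality(kept, min_net_um)
    speeds <- track_step_speeds(kept)
    stop_counts <- stops |>
      dplyr::count(.data$track_id, name = "stop_count")
    run_stats <- runs |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(n_runs = dplyr::n(),
                       mean_run_length_um = mean(.data$run_length_um),
                       .groups = "drop")
    n_frames_kept <- purrr::map_dfr(split_tracks(kept), function(tr) {
      tibble::tibble(track_id = tr$track_id[1], n_frames = nrow(tr))
    })
    per_track_kept <- n_frames_kept |>
      dplyr::left_join(vavg, by = "track_id") |>
      dplyr::left_join(vinst[c("track_id", "v_inst_um_s")], by = "track_id") |>
      dplyr::left_join(stop_counts, by = "track_id") |>
      dplyr::left_join(run_stats, by = "track_id") |>
      dplyr::left_join(dirs, by = "track_id") |>
      dplyr::mutate(
        stop_count = dplyr::coalesce(.data$stop_count, 0L),
        n_runs = dplyr::coalesce(.data$n_runs, 0L),
        passed_filter = TRUE
      )
    in_stop_tbl <- purrr::map_dfr(
      split(speeds, factor(speeds$track_id, levels = unique(speeds$track_id))),
      function(sp) {
        id <- sp$track_id[1]
        tibble::tibble(
          track_id = id, step = sp$step, speed_um_s = sp$speed_um_s,
          in_stop = stop_mask(nrow(sp),
                              stops[stops$track_id == id, , drop = FALSE])
        )
      })
    per_step <- in_stop_tbl |>
      dplyr::left_join(meta, by = "track_id") |>
      dplyr::select("track_id", "condition", "channel", "step",
                    "speed_um_s", "in_stop")
  } else {
    per_track_kept <- empty$per_track |>
      dplyr::select(-"condition", -"channel")
    per_step <- empty$per_step
  }

  excluded_ids <- flags$track_id[!flags$passed_filter]
  per_track_excl <- tibble::tibble(
    track_id = excluded_ids,
    n_frames = flags$n_frames[!flags$passed_filter],
    v_avg_um_s = NA_real_,
    v_inst_um_s = NA_real_,
    stop_count = NA_integer_,
    n_runs = NA_integer_,
    mean_run_length_um = NA_real_,
    net_displacement_um = NA_real_,
    direction = factor(NA, levels = c("retrograde", "anterograde",
                                      "stationary")),
    passed_filter = FALSE
  )
  per_track <- dplyr::bind_rows(per_track_kept, per_track_excl) |>
    dplyr::left_join(meta, by = "track_id") |>
    dplyr::select("track_id", "condition", "channel", "n_frames",
                  "v_avg_um_s", "v_inst_um_s", "stop_count", "n_runs",
                  "mean_run_length_um", "net_displacement_um", "direction",
                  "passed_filter")

  passing <- per_track |> dplyr::filter(.data$passed_filter)
  cohort <- if (nrow(passing) == 0L) {
    empty$cohort
  } else {
    passing |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        n_tracks = dplyr::n(),
        v_inst_mean = mean(.data$v_inst_um_s),
        v_inst_sem = sem0(.data$v_inst_um_s),
        v_avg_mean = mean(.data$v_avg_um_s),
        v_avg_sem = sem0(.data$v_avg_um_s),
        stop_count_mean = mean(.data$stop_count),
        stop_count_sem = sem0(.data$stop_count),
        run_length_mean = mean(.data$mean_run_length_um, na.rm = TRUE),
        run_length_sem = sem0(.data$mean_run_length_um[
          is.finite(.data$mean_run_length_um)]),
        retrograde_fraction = mean(.data$direction == "retrograde"),
        .groups = "drop"
      )
  }
  structure(
    list(per_track = per_track, per_step = per_step, cohort = cohort,
         thresholds = empty$thresholds),
    class = "transport_summary"
  )
}

sem0 <- function(x) {
  n <- length(x)
  if (n > 1L) stats::sd(x) / sqrt(n) else 0
}

#' @export
print.transport_summary <- function(x, ...) {
  cat("<transport_summary> ", nrow(x$per_track), " tracks (",
      sum(x$per_track$passed_filter), " passing the inclusion filter)\n",
      sep = "")
  print(x$cohort)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.transport_summary <- function(x, ...) x$per_track

#' @export
glance.transport_summary <- function(x, ...) x$cohort
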