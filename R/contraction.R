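# Contraction calling from myofiber intensity-over-time traces:
# robust normalization, MAD-thresholded burst detection, and the
# contracting / non-contracting call with per-chamber percentages.

# Absolute relative-deviation threshold used when the MAD of a trace is
# zero but deviations are present (e.g. a noiseless synthetic trace).
BURST_FALLBACK_ABS_THRESHOLD <- 0.1

#' Normalize intensity traces to relative deviations
#'
#' Each fiber's trace is converted to `(value - baseline) / baseline`
#' with the baseline taken as the median of the trace, which is robust to
#' the bursts themselves.
#'
#' @param traces Trace table with columns `fiber_id`, `frame`,
#'   `intensity` (extra columns such as `chamber_id`, `condition` are
#'   carried through).
#' @return The input tibble with an added `deviation` column.
#' @export
normalize_trace <- function(traces) {
  required <- c("fiber_id", "frame", "intensity")
  missing <- setdiff(required, names(traces))
  if (length(missing) > 0L) {
    stop_schema(sprintf("trace table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(traces$intensity))) {
    stop_data("trace intensities must be finite")
  }
  baseline <- stats::ave(traces$intensity, traces$fiber_id,
                         FUN = stats::median)
  if (any(baseline <= 0)) {
    bad <- unique(traces$fiber_id[baseline <= 0])
    stop_data(sprintf("fiber '%s' has non-positive baseline", bad[1]))
  }
  traces$deviation <- (traces$intensity - baseline) / baseline
  traces
}

#' Detect burst events in normalized traces
#'
#' A burst is a maximal run of at least `min_frames` consecutive frames
#' whose absolute relative deviation exceeds `k_mad` robust standard
#' deviations, where the robust SD is `1.4826 * MAD` of the fiber's
#' deviation series. If the MAD is zero while nonzero deviations exist,
#' an absolute threshold of 0.1 relative deviation is used instead, with
#' a warning.
#'
#' @param norm Normalized trace table (from [normalize_trace()]) with
#'   columns `fiber_id`, `frame`, `deviation`.
#' @param k_mad Threshold in robust-SD units (default 5).
#' @param min_frames Minimum burst length in frames (default 2).
#' @return A tibble with columns `fiber_id`, `event` (1-based index),
#'   `start_frame` (1-based within the trace), `n_frames`,
#'   `peak_deviation` (signed deviation of largest magnitude).
#' @export
detect_bursts <- function(norm, k_mad = 5, min_frames = 2) {
  check_scalar_number(k_mad, "k_mad", min = 0, strict_min = TRUE)
  min_frames <- check_count(min_frames, "min_frames", min = 1L)
  required <- c("fiber_id", "frame", "deviation")
  missing <- setdiff(required, names(norm))
  if (length(missing) > 0L) {
    stop_schema(sprintf("normalized trace table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  ord <- order(match(norm$fiber_id, unique(norm$fiber_id)), norm$frame)
  norm <- norm[ord, , drop = FALSE]
  devs <- split(norm$deviation, factor(norm$fiber_id,
                                       levels = unique(norm$fiber_id)))
  out <- lapply(names(devs), function(id) {
    dev <- devs[[id]]
    sigma <- stats::mad(dev)  # already scaled by 1.4826
    if (sigma == 0 && any(dev != 0)) {
      warning(sprintf(
        "fiber '%s': MAD is zero with nonzero deviations; falling back to absolute threshold %.2f",
        id, BURST_FALLBACK_ABS_THRESHOLD
      ))
      threshold <- BURST_FALLBACK_ABS_THRESHOLD
    } else {
      threshold <- k_mad * sigma
    }
    r <- runs_of(abs(dev) > threshold, min_frames)
    if (nrow(r) == 0L) return(NULL)
    peaks <- vapply(seq_len(nrow(r)), function(i) {
      idx <- r$start[i]:(r$start[i] + r$length[i] - 1L)
      dev[idx][which.max(abs(dev[idx]))]
    }, numeric(1))
    tibble::tibble(
      fiber_id = id,
      event = seq_len(nrow(r)),
      start_frame = as.integer(r$start),
      n_frames = as.integer(r$length),
      peak_deviation = peaks
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(fiber_id = character(), event = integer(),
                          start_frame = integer(), n_frames = integer(),
                          peak_deviation = numeric())
  }
  out
}

#' Call fibers contracting or non-contracting
#'
#' Runs the full calling pipeline (normalize, burst-detect, count events)
#' and labels a fiber contracting when it shows at least `min_events`
#' burst events — by default two, reflecting the repeated bursting that
#' distinguishes a contracting myotube from a one-off artefact. The event
#' count is reported so single-event fibers remain auditable.
#'
#' @param traces Trace table with columns `fiber_id`, `frame`,
#'   `intensity` and optionally `chamber_id`, `condition`.
#' @inheritParams detect_bursts
#' @param min_events Events required for a contracting call (default 2).
#' @return A tibble with columns `fiber_id` (plus `chamber_id`,
#'   `condition` when present), `n_events`, `contracting`.
#' @export
classify_contracting <- function(traces, k_mad = 5, min_frames = 2,
                                 min_events = 2) {
  min_events <- check_count(min_events, "min_events", min = 1L)
  norm <- normalize_trace(traces)
  events <- detect_bursts(norm, k_mad = k_mad, min_frames = min_frames)
  meta_cols <- intersect(c("fiber_id", "chamber_id", "condition"),
                         names(traces))
  roster <- traces |> dplyr::distinct(dplyr::across(dplyr::all_of(meta_cols)))
  counts <- events |> dplyr::count(.data$fiber_id, name = "n_events")
  roster |>
    dplyr::left_join(counts, by = "fiber_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      contracting = .data$n_events >= min_events
    )
}

#' Percentage of contracting myotubes per chamber
#'
#' The number of contracting fibers in a chamber divided by the number of
#' fibers analyzed in that chamber, times 100.
#'
#' @param calls Call table from [classify_contracting()] with columns
#'   `fiber_id`, `chamber_id`, `contracting` (plus optional `condition`).
#' @return A tibble with columns `chamber_id` (plus `condition` when
#'   present), `n_fibers`, `n_contracting`, `percent_contracting`.
#' @export
percent_contracting <- function(calls) {
  required <- c("fiber_id", "chamber_id", "contracting")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0L) {
    stop_schema(sprintf("call table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  group_cols <- intersect(c("chamber_id", "condition"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_fibers = dplyr::n(),
      n_contracting = sum(.data$contracting),
      percent_contracting = 100 * mean(.data$contracting),
      .groups = "drop"
    )
}
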